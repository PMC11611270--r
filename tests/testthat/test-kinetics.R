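test_that("profiled transcription rate matches the closed form", {
    # two cells, unit p and t, gamma fixed at 1:
    # alpha = mean(l) / mean(p (1 - e^-1)) = 3 / (2 (1 - e^-1))
    l <- c(1, 2); p <- c(1, 1); t <- c(1, 1)
    ap <- t * (1 - exp(-1 * t)) / (1 * t)
    expect_equal(mean(l) / mean(p * ap), 3 / (2 * (1 - exp(-1))))
    # profile identity at the optimum, for baseline and splicing
    le <- make_csp_experiment(nGenes = 1, seed = 3)
    ll <- SummarizedExperiment::assay(le, "new")[1, ]
    tt <- labelingTime(le); pp <- rep(1, length(tt))
    f <- fitKineticsBaseline(ll, pp, tt)
    apg <- tt * (1 - exp(-f$gamma_t * tt)) / (f$gamma_t * tt)
    expect_equal(f$alpha, mean(ll) / mean(pp * apg), tolerance = 1e-6)
})

test_that("baseline profiled optimum equals a brute-force 2-D grid argmax",
{
    withr::with_seed(13, {
        dur <- c(0.5, 1, 2)
        t <- rep(dur, each = 150)
        p <- runif(length(t), 0.5, 2)
        for (i in 1:3) {
            al <- runif(1, 1, 4); ga <- runif(1, 0.3, 1)
            l <- rcsp(length(t), p, meanNewBaseline(al, ga, t))
            f <- fitKineticsBaseline(l, p, t)
            ag <- seq(0.5 * al, 2 * al, length.out = 60)
            gg <- seq(0.3 * ga, 3 * ga, length.out = 60)
            ll <- outer(ag, gg, Vectorize(function(a, g)
                sum(dpois(l, p * meanNewBaseline(a, g, t), log = TRUE))))
            best <- arrayInd(which.max(ll), dim(ll))
            expect_lt(abs(ag[best[1]] - f$alpha), 1.5 * diff(ag)[1])
            expect_lt(abs(gg[best[2]] - f$gamma_t), 1.5 * diff(gg)[1])
        }
    })
})

test_that("baseline MLE recovers simulated rates (fixed-parameter panel)",
{
    dur <- c(0.25, 0.5, 0.75, 1, 2, 3)
    t <- rep(dur, each = 500)
    p <- rep(1, length(t))
    err <- vapply(1:15, function(g) {
        l <- rcsp(length(t), p, meanNewBaseline(1, 0.5, t), seed = 500 + g)
        f <- fitKineticsBaseline(l, p, t)
        abs(f$gamma_t - 0.5) / 0.5
    }, numeric(1))
    expect_lt(median(err), 0.1)
})

test_that("splicing MLE: noiseless forward-inverse and degenerate
           contracts", {
    dur <- c(0.5, 1, 2, 3)
    t <- rep(dur, each = 25)
    p <- rep(1, length(t))
    bc <- meanNewSplicing(2, 1, 0.5, t)
    f <- fitKineticsSplicing(bc$b, bc$c, p, t)
    expect_lt(abs(f$alpha - 2), 1e-4)
    expect_lt(abs(f$beta - 1), 1e-4)
    expect_lt(abs(f$gamma_s - 0.5), 1e-4)
    expect_equal(f$r2, 1, tolerance = 1e-6)  # D = 0 at a perfect fit
    # spliced layer identically zero: gamma_s pinned at a bound, flagged
    ul <- rcsp(length(t), p, meanNewBaseline(2, 1, t), seed = 9)
    f0 <- fitKineticsSplicing(ul, rep(0, length(t)), p, t)
    expect_false(f0$converged)
    expect_equal(f0$flag, "boundary")
    fz <- fitKineticsSplicing(rep(0, 8), rep(0, 8), rep(1, 8),
                              rep(c(1, 2), 4))
    expect_equal(fz$flag, "all-zero")
})

test_that("switching MLE reduces to baseline at p_off = 0 and recovers
           p_off", {
    dur <- c(0.25, 0.5, 0.75, 1, 2, 3)
    t <- rep(dur, each = 250)
    p <- rep(1, length(t))
    l <- rcsp(length(t), p, meanNewBaseline(2, 0.5, t), seed = 21)
    fb <- fitKineticsBaseline(l, p, t)
    expect_warning(fs <- fitKineticsSwitching(l, p, t), "clipped")
    expect_lte(fs$p_off, 0.05)
    expect_lt(abs(fs$alpha - fb$alpha) / fb$alpha, 0.05)
    expect_lt(abs(fs$gamma_t - fb$gamma_t) / fb$gamma_t, 0.05)
    # CSZIP recovery at the documented design point
    lz <- rcszip(length(t), p, meanNewBaseline(2, 0.5, t), 0.3, seed = 22)
    fz <- fitKineticsSwitching(lz, p, t)
    expect_lt(abs(fz$p_off - 0.3), 0.05)
    # all-zero boundary
    f0 <- fitKineticsSwitching(rep(0, 10), rep(1, 10), rep(c(1, 2), 5))
    expect_equal(f0$p_off, 1)
    expect_equal(f0$flag, "all-zero")
})

test_that("adjusted deviance R2 identities hold", {
    t <- rep(c(0.5, 1, 2), each = 20); N <- length(t)
    p <- rep(1, N)
    a <- meanNewBaseline(2, 0.5, t)
    # counts exactly at the model means: D = 0, R2 = 1
    dev <- adjustedDevianceR2("baseline", list(l = a * p, p = p, t = t),
                              list(alpha = 2, gamma_t = 0.5))
    expect_equal(dev$D, 0, tolerance = 1e-10)
    expect_equal(dev$r2, 1)
    # fitted model identical to the null: R2 = 1 - d_D0 / d_D
    l <- rcsp(N, p, 3, seed = 7)
    a0 <- mean(l) / mean(p)
    # gamma -> 0 makes a(t) = alpha t; choose alpha so p a == p a0 for all
    # cells is impossible unless t constant, so emulate the null directly
    devn <- adjustedDevianceR2("baseline",
                               list(l = l, p = p, t = rep(1, N)),
                               list(alpha = a0 / (1 - exp(-1e-9)) * 1e-9,
                                    gamma_t = 1e-9))
    expect_equal(devn$r2, 1 - (N - 1) / (N - 2), tolerance = 1e-4)
    # deviance equals the brute-force cell-wise saturated comparison
    f <- fitKineticsBaseline(l, p, t)
    dev2 <- adjustedDevianceR2("baseline", list(l = l, p = p, t = t),
                               list(alpha = f$alpha, gamma_t = f$gamma_t))
    mu <- p * meanNewBaseline(f$alpha, f$gamma_t, t)
    brute <- -2 * sum(dpois(l, mu, log = TRUE) -
                          dpois(l, pmax(l, 0), log = TRUE))
    expect_equal(dev2$D, brute, tolerance = 1e-8)
    # likelihood ordering l_s >= l(theta) >= l_0
    expect_gte(dev2$logLikSat, dev2$logLik)
    expect_gte(dev2$logLik, dev2$logLik0 - 1e-8)
})

test_that("gene selection ranks by R2 with missing values last", {
    expect_equal(selectGenes(c(0.9, 0.5, 0.1), 1 / 3), 1L)
    expect_equal(selectGenes(c(0.9, 0.5, 0.1), 1), 1:3)
    withr::with_seed(2, r2 <- runif(100))
    sel <- selectGenes(r2, 0.4)
    expect_length(sel, 40)
    expect_true(all(r2[sel] >= sort(r2, decreasing = TRUE)[40]))
    r2[c(3, 7)] <- NA
    sel2 <- selectGenes(r2, 0.98)
    expect_false(any(c(3, 7) %in% sel2))
    expect_error(selectGenes(r2, 0), "fraction")
})

test_that("robustness measure is non-negative, quadrature-accurate, and
           separates flat from identified genes", {
    p <- rep(1, 400)
    # linear regime: durations short against every half-life in the
    # integration range, counts exactly alpha * t -- any gamma fits after
    # re-profiling alpha, so the likelihood is flat and the measure ~ 0
    t_short <- rep(c(0.025, 0.05, 0.1, 0.2), each = 100)
    m_flat <- robustnessMeasure(5 * t_short, p, t_short)
    # well-identified gene: durations commensurate with 1/gamma
    t <- rep(c(0.25, 0.5, 1, 2), each = 100)
    l_id <- rcsp(length(t), p, meanNewBaseline(5, 1, t), seed = 32)
    m_id <- robustnessMeasure(l_id, p, t)
    expect_gte(m_flat, 0)
    expect_gt(m_id, 10 * m_flat)
    # adaptive quadrature agrees with a brute-force midpoint Riemann sum
    h <- 1.5 / 2e4
    gs <- seq(h / 2, 1.5 - h / 2, by = h)
    integrand <- function(g) {
        ap <- t * (1 - exp(-g * t)) / (g * t)
        al <- mean(l_id) / mean(p * ap)
        da <- al * ((t * exp(-g * t)) / g - ap / g)
        abs(sum(ifelse(l_id > 0, l_id / (al * ap), 0) * da) - sum(p * da))
    }
    riemann <- sum(vapply(gs, integrand, numeric(1))) * h
    expect_equal(m_id, riemann, tolerance = 1e-4)
})

test_that("per-gene fits are independent of gene processing order", {
    le <- make_csp_experiment(nGenes = 4, seed = 51)
    f1 <- fitKinetics(le, "baseline")
    perm <- c(3, 1, 4, 2)
    f2 <- fitKinetics(le[perm, ], "baseline")
    expect_equal(f2$gamma_t, f1$gamma_t[perm])
    expect_equal(f2$alpha, f1$alpha[perm])
    expect_equal(f2$r2, f1$r2[perm])
})
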