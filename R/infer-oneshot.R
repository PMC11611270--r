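#' Closed-form steady-state estimator for one-shot labeling data
#'
#' For a single labeling duration \eqn{t} with only new (\eqn{l}) and total
#' (\eqn{r}) counts, assuming the total-RNA distribution is stationary, the
#' maximum-likelihood estimates have the closed form
#' \deqn{\hat{\gamma}_t = -\frac{1}{t}\log\left(1 -
#'   \frac{\langle l \rangle}{\langle r \rangle}\right), \qquad
#'   \hat{\alpha} = \hat{\gamma}_t \frac{\langle r \rangle}
#'   {\langle p \rangle},}
#' where \eqn{\langle\cdot\rangle} is the raw-count population mean. The
#' new counts follow the CSP law with mean \eqn{p_j a(t)} and the old
#' counts (total minus new) an independent CSP with mean
#' \eqn{p_j (\alpha/\gamma_t) e^{-\gamma_t t}}; these estimates maximize
#' the corresponding joint Poisson likelihood.
#'
#' @param l per-cell new counts.
#' @param r per-cell total counts.
#' @param p per-cell size factors.
#' @param t labeling duration (hours, scalar).
#' @return List with \code{alpha}, \code{gamma_t}.
#' @examples
#' fitOneshotSteady(l = 10 * (1 - exp(-1)), r = 10, p = 1, t = 1)
#' @export
fitOneshotSteady <- function(l, r, p, t) {
    if (t <= 0) stop("t must be > 0", call. = FALSE)
    ml <- mean(l); mr <- mean(r)
    if (ml == 0) {
        warning("mean new count is 0; gamma_t at the 0 boundary")
        return(list(alpha = 0, gamma_t = 0))
    }
    if (ml >= mr)
        stop("mean new count >= mean total count; gamma_t not identifiable",
             call. = FALSE)
    gamma_t <- -log(1 - ml / mr) / t
    alpha <- gamma_t * mr / mean(p)
    list(alpha = alpha, gamma_t = gamma_t)
}

# Exact one-shot steady-state log-likelihood: new ~ Pois(p a(t)),
# old = r - l ~ Pois(p (alpha/gamma_t) e^{-gamma_t t}) (negatives clipped
# to 0 with a warning). Used by tests to check the closed form against a
# numeric argmax.
#' One-shot steady-state log-likelihood
#'
#' Joint Poisson log-likelihood of new and old counts under the stationary
#' baseline model; the closed form of \code{\link{fitOneshotSteady}}
#' maximizes this surface.
#'
#' @inheritParams fitOneshotSteady
#' @param alpha,gamma_t parameter values at which to evaluate.
#' @return scalar log-likelihood.
#' @export
oneshotSteadyLogLik <- function(alpha, gamma_t, l, r, p, t) {
    old <- r - l
    if (any(old < 0)) {
        warning("negative old counts clipped to 0")
        old <- pmax(old, 0)
    }
    a <- meanNewBaseline(alpha, gamma_t, t)
    mo <- (alpha / gamma_t) * exp(-gamma_t * t)
    sum(dpois(l, p * a, log = TRUE)) + sum(dpois(old, p * mo, log = TRUE))
}

#' Minimal relative-dynamics fitter for unspliced/spliced phase portraits
#'
#' Stage one of the two-stage one-shot method: fits the deterministic
#' induction-then-repression trajectory of the splicing ODE system
#' \eqn{du/dt = \alpha 1_{t < t_s} - \beta u}, \eqn{ds/dt = \beta u -
#' \gamma_s s} to per-cell (unspliced, spliced) = (uu + ul, su + sl)
#' expression, assigning each cell a latent time by its nearest point on
#' the trajectory. Absolute time is not identifiable from the phase
#' portrait, so the switching time is gauge-fixed to 1 and only the rate
#' ratio \eqn{\beta/\gamma_s}, the on-state cell set \eqn{S_{on} = \{j :
#' t_{obs,j} < t_s\}} and the fit quality are meaningful. \eqn{R^2} is one
#' minus the ratio of the residual to the total sum of squared distances,
#' computed on cells passing the low-expression filter (cells with both
#' coordinates below max/5 are excluded).
#'
#' Any external dynamical-model implementation can replace this fitter:
#' downstream only consumes \code{ratio} and \code{S_on}.
#'
#' Fitting is two-pass: a coarse trajectory discretization for the global
#' search, then one refinement pass on a fine grid, which removes the
#' discretization bias that otherwise flattens the loss in the rate ratio.
#' Populations above \code{maxFitCells} cells are thinned deterministically
#' (every k-th cell by index) for the loss only; latent times are assigned
#' to all cells at the end.
#'
#' @param u per-cell unspliced expression (uu + ul).
#' @param s per-cell spliced expression (su + sl).
#' @param nGrid fine-pass trajectory discretization (default 600 points
#'   per phase; the coarse pass uses a quarter of this).
#' @param maxit Nelder-Mead iteration budget for the coarse pass.
#' @param maxFitCells cap on cells entering the loss (default 500).
#' @return List with \code{alpha_rel}, \code{beta_rel}, \code{gamma_s_rel},
#'   \code{ratio} (= beta/gamma_s), \code{t_s} (gauge-fixed, = 1),
#'   \code{t_obs} per cell, \code{S_on} (logical), \code{r2},
#'   \code{converged}.
#' @export
fitDynamicalRelative <- function(u, s, nGrid = 600, maxit = 400,
                                 maxFitCells = 500) {
    n <- length(u)
    if (n < 50) stop("need >= 50 cells", call. = FALSE)
    umax <- max(u); smax <- max(s)
    if (umax == 0 || smax == 0 || (stats::var(u) == 0 && stats::var(s) == 0))
        return(list(alpha_rel = NA, beta_rel = NA, gamma_s_rel = NA,
                    ratio = NA, t_s = 1, t_obs = rep(NA_real_, n),
                    S_on = rep(FALSE, n), r2 = -Inf, converged = FALSE))
    keep <- !(u < umax / 5 & s < smax / 5)
    sub <- seq(1, n, by = max(1L, ceiling(n / maxFitCells)))

    traj <- function(th, nGrid) {
        # th = (log alpha, log beta, log gamma_s); t_s = 1 (gauge)
        al <- exp(th[1]); be <- exp(th[2]); ga <- exp(th[3])
        t_on <- seq(0, 1, length.out = nGrid)
        bc <- meanNewSplicing(al, be, ga, t_on)
        u1 <- bc$b; s1 <- bc$c
        # repression: decay from the switching point for up to 5 slowest
        # half-lives
        t_rep <- seq(0, 5 / min(be, ga), length.out = nGrid)[-1]
        u0 <- u1[nGrid]; s0 <- s1[nGrid]
        u2 <- u0 * exp(-be * t_rep)
        if (abs(be - ga) > 1e-10 * max(be, ga)) {
            s2 <- s0 * exp(-ga * t_rep) +
                be * u0 * (exp(-ga * t_rep) - exp(-be * t_rep)) / (be - ga)
        } else {
            s2 <- (s0 + be * u0 * t_rep) * exp(-be * t_rep)
        }
        list(t = c(t_on, 1 + t_rep), u = c(u1, u2), s = c(s1, s2))
    }
    # squared distance of every cell to its nearest trajectory point
    # (||x||^2 + ||y||^2 - 2 x.y expansion so BLAS does the heavy lifting)
    assign_cells <- function(tr, uu, ss) {
        cross <- tcrossprod(cbind(uu, ss), cbind(tr$u, tr$s))
        d2 <- (uu^2 + ss^2) - 2 * cross
        d2 <- sweep(d2, 2, tr$u^2 + tr$s^2, "+")
        j <- max.col(-d2, ties.method = "first")
        list(idx = j, d2 = pmax(d2[cbind(seq_along(uu), j)], 0))
    }
    kf <- keep[sub]
    loss_at <- function(th, ng) {
        if (any(!is.finite(th)) || any(abs(th) > 30)) return(1e300)
        tr <- traj(th, ng)
        sum(assign_cells(tr, u[sub][kf], s[sub][kf])$d2)
    }
    # init: alpha from max u (u* ~ alpha/beta near switching), gamma_s from
    # the high-expression u/s balance beta*u ~ gamma_s*s
    hi <- u > umax / 2 | s > smax / 2
    be0 <- 1
    ga0 <- be0 * max(mean(u[hi]), 1e-8) / max(mean(s[hi]), 1e-8)
    al0 <- max(umax * be0, 1e-8)
    starts <- list(log(c(al0, be0, ga0)),
                   log(c(al0, be0 * 3, ga0 / 3)),
                   log(c(al0, be0 / 3, ga0 * 3)))
    ngCoarse <- max(50L, nGrid %/% 4L)
    best <- NULL
    for (st in starts) {
        op <- optim(st, loss_at, ng = ngCoarse, method = "Nelder-Mead",
                    control = list(maxit = maxit %/% 2L, reltol = 1e-9))
        if (is.null(best) || op$value < best$value) best <- op
    }
    # refinement passes on the fine grid; Nelder-Mead simplices collapse
    # prematurely on this flat loss, so restart until the value stabilizes
    for (pass in 1:3) {
        op <- optim(best$par, loss_at, ng = nGrid, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = 1e-12))
        improved <- op$value < best$value * (1 - 1e-8)
        best <- op
        if (!improved) break
    }
    th <- best$par
    tr <- traj(th, nGrid)
    asg <- assign_cells(tr, u, s)
    t_obs <- tr$t[asg$idx]
    tss <- sum(((u - mean(u[keep]))^2 + (s - mean(s[keep]))^2)[keep])
    r2 <- if (tss > 0) 1 - sum(asg$d2[keep]) / tss else -Inf
    list(alpha_rel = exp(th[1]), beta_rel = exp(th[2]),
         gamma_s_rel = exp(th[3]), ratio = exp(th[2] - th[3]), t_s = 1,
         t_obs = t_obs, S_on = t_obs < 1, r2 = r2,
         converged = best$convergence == 0 && is.finite(r2))
}

#' Absolute rates from one-shot labeling given a relative splicing ratio
#'
#' Stage two of the two-stage one-shot method. Among on-state cells, the
#' labeled unspliced and spliced counts satisfy
#' \deqn{b_{obs} = \frac{\sum_{S_{on}} u_l}{\sum_{S_{on}} p} = b(t), \qquad
#'       c_{obs} = \frac{\sum_{S_{on}} s_l}{\sum_{S_{on}} p} = c(t),}
#' which together with the relative ratio \eqn{\rho = \beta/\gamma_s}
#' pins down absolute \eqn{(\alpha, \beta, \gamma_s)}: \eqn{\alpha} is
#' substituted by \eqn{b_{obs}\beta/(1 - e^{-\beta t})} and the remaining
#' scalar equation in \eqn{\beta} is solved by bracketed root-finding on
#' \code{[1e-4, 50]/t}.
#'
#' @param ul,sl per-cell labeled unspliced/spliced counts.
#' @param p per-cell size factors.
#' @param t labeling duration (hours).
#' @param S_on logical or index vector of on-state cells.
#' @param ratio relative ratio \eqn{\beta/\gamma_s} from stage one.
#' @param tol root residual tolerance.
#' @return List with \code{alpha}, \code{beta}, \code{gamma_s},
#'   \code{b_obs}, \code{c_obs}.
#' @export
fitOneshotSplicing <- function(ul, sl, p, t, S_on, ratio, tol = 1e-10) {
    if (ratio <= 0) stop("ratio must be > 0", call. = FALSE)
    ul <- ul[S_on]; sl <- sl[S_on]; ps <- p[S_on]
    if (!length(ul) || sum(ps) <= 0)
        stop("S_on is empty or has non-positive size-factor mass",
             call. = FALSE)
    b_obs <- sum(ul) / sum(ps)
    c_obs <- sum(sl) / sum(ps)
    f <- function(beta) {
        alpha <- b_obs * beta / (1 - exp(-beta * t))
        meanNewSplicing(alpha, beta, beta / ratio, t)$c - c_obs
    }
    lo <- 1e-4 / t; hi <- 50 / t
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
        stop(sprintf(paste0("no root in bracket [%.3g, %.3g]: b_obs=%.4g, ",
                            "c_obs=%.4g, ratio=%.4g"), lo, hi, b_obs, c_obs,
                     ratio), call. = FALSE)
    beta <- uniroot(f, c(lo, hi), tol = tol)$root
    alpha <- b_obs * beta / (1 - exp(-beta * t))
    list(alpha = alpha, beta = beta, gamma_s = beta / ratio,
         b_obs = b_obs, c_obs = c_obs)
}

#' Two-stage one-shot inference over all genes of an experiment
#'
#' Runs \code{\link{fitDynamicalRelative}} on each gene's unspliced/spliced
#' phase portrait (stage one) and, for genes passing convergence, converts
#' to absolute rates with \code{\link{fitOneshotSplicing}} (stage two).
#'
#' @param x \code{LabelingExperiment} with layers uu, ul, su, sl and size
#'   factors; a single labeling duration.
#' @param genes optional gene subset.
#' @param smoothed if \code{TRUE} (default) stage one uses kNN-smoothed
#'   expression when the smoothed layers are present.
#' @param nGrid trajectory discretization for stage one (default 300 for
#'   whole-experiment runs; single-gene calls may want the finer
#'   \code{\link{fitDynamicalRelative}} default).
#' @return \code{data.frame}: gene, alpha, beta, gamma_s, ratio, r2,
#'   n_on_cells, converged.
#' @export
fitOneshot <- function(x, genes = NULL, smoothed = TRUE,
                       nGrid = 300) {
    p <- sizeFactors(x)
    if (is.null(p)) stop("run computeSizeFactors() first", call. = FALSE)
    tt <- labelingTimes(x)
    if (length(tt) != 1)
        stop("one-shot inference needs a single labeling duration",
             call. = FALSE)
    pick <- function(nm) {
        sm <- paste0(nm, "_smoothed")
        if (smoothed && sm %in% SummarizedExperiment::assayNames(x))
            .get_layer(x, sm) else
            sweep(.get_layer(x, nm), 2, p, "/")
    }
    U <- pick("uu") + pick("ul")
    S <- pick("su") + pick("sl")
    UL <- .get_layer(x, "ul"); SL <- .get_layer(x, "sl")
    if (is.null(genes)) genes <- seq_len(nrow(U))
    res <- lapply(genes, function(g) {
        st1 <- fitDynamicalRelative(U[g, ], S[g, ], nGrid = nGrid)
        row <- data.frame(gene = if (is.null(rownames(U))) g else
                              rownames(U)[g],
                          alpha = NA_real_, beta = NA_real_,
                          gamma_s = NA_real_, ratio = st1$ratio,
                          r2 = st1$r2, n_on_cells = sum(st1$S_on),
                          converged = FALSE, stringsAsFactors = FALSE)
        if (!st1$converged || !any(st1$S_on)) return(row)
        st2 <- tryCatch(fitOneshotSplicing(UL[g, ], SL[g, ], p, tt,
                                           st1$S_on, st1$ratio),
                        error = function(e) NULL)
        if (is.null(st2)) return(row)
        row$alpha <- st2$alpha; row$beta <- st2$beta
        row$gamma_s <- st2$gamma_s; row$converged <- TRUE
        row
    })
    do.call(rbind, res)
}
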