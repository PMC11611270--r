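#' Adaptive count binning for heterogeneous-cell goodness-of-fit tests
#'
#' Partitions the count range into contiguous classes \code{[0]}, \code{[1]},
#' ..., \code{[m, Inf)}, merging rightward from zero until every class has
#' total expected count \eqn{\sum_i p_{ij} \ge 0.25} under the per-cell
#' fitted distributions; the final class absorbs the tail. Because each cell
#' has its own distribution, the class probabilities are a matrix with one
#' row per cell.
#'
#' @param observed integer vector of per-cell observed counts.
#' @param pmf function taking a vector of count values and returning a
#'   cells x values matrix of per-cell probabilities \eqn{P_i(X = v)}.
#' @param minExpected minimum total expected count per class (default 0.25).
#' @return An object of class \code{"Binning"}: list with \code{starts}
#'   (first count value of each class; the last class is open-ended),
#'   \code{classProb} (cells x classes probability matrix, rows summing to
#'   1), and \code{nClasses}.
#' @export
makeBinning <- function(observed, pmf, minExpected = 0.25) {
    n <- length(observed)
    if (n < 2) stop("need at least 2 cells", call. = FALSE)
    vmax <- max(observed)
    P <- pmf(0:vmax)
    if (!is.matrix(P)) P <- matrix(P, nrow = n)
    tail <- pmax(0, 1 - rowSums(P))
    ex <- colSums(P)
    exTail <- sum(tail)
    # greedy left-to-right merge over singleton values 0..vmax
    starts <- integer(0)
    acc <- 0; open <- FALSE
    for (v in 0:vmax) {
        if (!open) { starts <- c(starts, v); open <- TRUE }
        acc <- acc + ex[v + 1]
        if (acc >= minExpected) { acc <- 0; open <- FALSE }
    }
    # the open-ended tail [vmax + 1, Inf) joins the last class if either the
    # last class or the tail itself is below threshold
    if (open || exTail < minExpected) {
        # tail merges into the last started class
    } else {
        starts <- c(starts, vmax + 1L)
    }
    # ensure the final (tail-absorbing) class meets the threshold by merging
    # leftward
    repeat {
        c0 <- length(starts)
        if (c0 < 2) break
        lastExp <- sum(ex[seq(starts[c0] + 1L, vmax + 1L)]) + exTail
        if (starts[c0] > vmax) lastExp <- exTail
        if (lastExp >= minExpected) break
        starts <- starts[-c0]
    }
    c0 <- length(starts)
    classProb <- matrix(0, n, c0)
    for (j in seq_len(c0)) {
        lo <- starts[j]
        hi <- if (j < c0) starts[j + 1] - 1L else vmax
        if (lo <= vmax)
            classProb[, j] <- rowSums(P[, seq(lo, min(hi, vmax)) + 1L,
                                        drop = FALSE])
        if (j == c0) classProb[, j] <- classProb[, j] + tail
    }
    structure(list(starts = starts, classProb = classProb, nClasses = c0),
              class = "Binning")
}

.assign_class <- function(binning, counts) {
    findInterval(counts, binning$starts)
}

.gof_result <- function(statistic, df, p.value, verdict, n_cells, n_classes) {
    structure(list(statistic = statistic, df = df, p.value = p.value,
                   verdict = verdict, n_cells = n_cells,
                   n_classes = n_classes),
              class = "GOFTestResult")
}

#' @export
print.GOFTestResult <- function(x, ...) {
    cat("Goodness-of-fit test for cell-specific distributions\n")
    cat("  chi-square =", format(x$statistic, digits = 5),
        " df =", x$df,
        " p-value =", format(x$p.value, digits = 4), "\n")
    cat("  cells =", x$n_cells, " classes =", x$n_classes,
        " verdict:", x$verdict, "\n")
    invisible(x)
}

#' Modified chi-square test for cell-specific distributions
#'
#' Tests whether counts drawn from \emph{different} distributions per cell
#' (common family, cell-specific parameters) are consistent with those
#' fitted distributions. With per-cell class-probability vectors
#' \eqn{p_i} and class indicators \eqn{X_i}, the statistic
#' \deqn{\chi^2 = n (\bar{X}^* - \bar{p}^*)^\top (\bar{\Sigma}^*)^{-1}
#'   (\bar{X}^* - \bar{p}^*)}
#' uses the truncated (first \eqn{c - 1}) coordinates and the averaged
#' multinomial covariance \eqn{\bar{\Sigma}^* = \mathrm{mean}_i
#' [\mathrm{diag}(p_i^*) - p_i^* (p_i^*)^\top]}; it is asymptotically
#' chi-square with \eqn{c - 1} degrees of freedom, from which the number of
#' parameters fitted to the same cells is subtracted. When all cells share
#' one distribution it reduces to the classical Pearson statistic. A
#' near-singular covariance is ridge-regularized
#' (\code{1e-10 * trace/(c-1)}). If the corrected degrees of freedom are
#' non-positive the verdict is \code{"UTD"} (unable to determine).
#'
#' @param binning a \code{\link{makeBinning}} result.
#' @param observed per-cell observed counts (same cells, same order as the
#'   binning).
#' @param nFittedParams number of parameters fitted on these cells (1 for
#'   CSP, 2 for ICSP or CSZIP).
#' @param level significance level (default 0.05).
#' @param drop which category to drop in the truncation (default the last);
#'   the statistic is invariant to this choice.
#' @return A \code{"GOFTestResult"}: statistic, df, p-value, verdict in
#'   \code{c("accept", "reject", "UTD")}, n_cells, n_classes.
#' @export
cellSpecificChi2 <- function(binning, observed, nFittedParams,
                             level = 0.05, drop = NULL) {
    c0 <- binning$nClasses
    n <- nrow(binning$classProb)
    if (length(observed) != n)
        stop("observed length does not match binning", call. = FALSE)
    if (c0 < 2)
        return(.gof_result(NA_real_, 0L, NA_real_, "UTD", n, c0))
    if (is.null(drop)) drop <- c0
    cls <- .assign_class(binning, observed)
    keep <- setdiff(seq_len(c0), drop)
    freq <- tabulate(cls, c0) / n
    Pstar <- binning$classProb[, keep, drop = FALSE]
    xbar <- freq[keep]
    pbar <- colMeans(Pstar)
    Sigma <- diag(pbar, nrow = length(pbar)) - crossprod(Pstar) / n
    d <- xbar - pbar
    sol <- tryCatch(solve(Sigma, d), error = function(e) NULL)
    if (is.null(sol) || !all(is.finite(sol))) {
        ridge <- 1e-10 * sum(diag(Sigma)) / (c0 - 1)
        sol <- solve(Sigma + diag(ridge, nrow(Sigma)), d)
    }
    stat <- n * sum(d * sol)
    df <- c0 - 1L - as.integer(nFittedParams)
    if (df <= 0)
        return(.gof_result(stat, df, NA_real_, "UTD", n, c0))
    p <- pchisq(stat, df, lower.tail = FALSE)
    verdict <- if (p < level) "reject" else "accept"
    .gof_result(stat, df, p, verdict, n, c0)
}

#' Chi-square independence test of total counts across labeling durations
#'
#' Bins per-cell total mRNA counts and tests independence between the
#' binned count and the labeling-duration label with the standard K x c
#' contingency chi-square, merging count values from the left until every
#' table cell has expected count at least \code{minExpected}. An accepting
#' verdict supports treating the total-RNA distribution as stationary
#' across durations.
#'
#' @param totals per-cell total counts (vector).
#' @param duration per-cell duration labels (same length).
#' @param level significance level.
#' @param minExpected minimum expected count per table cell.
#' @return A \code{"GOFTestResult"} with verdict \code{"accept"} (same
#'   distribution), \code{"reject"} (different) or \code{"UTD"}.
#' @export
testTotalIndependence <- function(totals, duration, level = 0.05,
                                  minExpected = 0.25) {
    duration <- as.factor(duration)
    K <- nlevels(duration)
    nk <- table(duration)
    n <- length(totals)
    if (K < 2 || any(nk < 2))
        stop("need >= 2 durations with >= 2 cells each", call. = FALSE)
    vmax <- max(totals)
    pooled <- tabulate(totals + 1L, vmax + 1L) / n
    # merge values left-to-right so min_k n_k * p_class >= minExpected
    starts <- integer(0); acc <- 0; open <- FALSE
    for (v in 0:vmax) {
        if (!open) { starts <- c(starts, v); open <- TRUE }
        acc <- acc + pooled[v + 1]
        if (min(nk) * acc >= minExpected) { acc <- 0; open <- FALSE }
    }
    if (open && length(starts) > 1) starts <- starts[-length(starts)]
    c0 <- length(starts)
    if (c0 < 2)
        return(.gof_result(NA_real_, 0L, NA_real_, "UTD", n, c0))
    cls <- findInterval(totals, starts)
    O <- table(duration, factor(cls, levels = seq_len(c0)))
    E <- outer(rowSums(O), colSums(O)) / n
    stat <- sum((O - E)^2 / E)
    df <- (K - 1L) * (c0 - 1L)
    p <- pchisq(stat, df, lower.tail = FALSE)
    verdict <- if (p < level) "reject" else "accept"
    .gof_result(stat, df, p, verdict, n, c0)
}

# bounded MLE of a cell-specific ZIP at fixed labeling time:
# counts ~ ZIP(p_j * a, p_off). Moment initializer with a(t) == a, clipped.
.fit_zip_fixed <- function(l, p) {
    ml <- mean(l); ml2 <- mean(l^2)
    mp <- mean(p); mp2 <- mean(p^2)
    den <- mp^2 * (ml2 - ml)
    poff0 <- if (den > 0) 1 - ml^2 * mp2 / den else 0.5
    poff0 <- min(max(poff0, 1e-6), 1 - 1e-6)
    a0 <- ml / ((1 - poff0) * mp)
    if (!is.finite(a0) || a0 <= 0) a0 <- max(ml / mp, 1e-6)
    nll <- function(th) -sum(dcszip(l, p, th[1], th[2]))
    opt <- optim(c(a0, poff0), nll, method = "L-BFGS-B",
                 lower = c(1e-8, 1e-6), upper = c(10 * a0, 1 - 1e-6))
    list(a = opt$par[1], p_off = opt$par[2], logLik = -opt$value,
         converged = opt$convergence == 0)
}

#' Per-gene goodness-of-fit tests on a LabelingExperiment
#'
#' For each gene, at one labeling duration, fits the cell-specific
#' distribution (CSP: one mean parameter; CSZIP: mean and off-probability)
#' by maximum likelihood on the tested cells, then applies
#' \code{\link{cellSpecificChi2}} with the matching degrees-of-freedom
#' correction.
#'
#' @param x a \code{LabelingExperiment} with size factors and a
#'   \code{"new"} layer.
#' @param model \code{"csp"} or \code{"cszip"}.
#' @param duration which labeling duration to test (default: first).
#' @param genes optional subset of gene indices/names.
#' @param level significance level.
#' @return \code{data.frame} with columns gene, chi2, df, pvalue, verdict.
#' @export
testCellDistribution <- function(x, model = c("csp", "cszip"),
                                 duration = NULL, genes = NULL,
                                 level = 0.05) {
    model <- match.arg(model)
    p <- sizeFactors(x)
    if (is.null(p)) stop("run computeSizeFactors() first", call. = FALSE)
    if (is.null(duration)) duration <- labelingTimes(x)[1]
    sel <- labelingTime(x) == duration
    L <- .get_layer(x, "new")[, sel, drop = FALSE]
    p <- p[sel]
    if (is.null(genes)) genes <- seq_len(nrow(L))
    res <- lapply(genes, function(g) {
        l <- L[g, ]
        if (model == "csp") {
            a <- sum(l) / sum(p)
            pmf <- function(v) {
                lam <- p * a
                vapply(v, function(vv) dpois(vv, lam), numeric(length(p)))
            }
            k <- 1L
        } else {
            fit <- .fit_zip_fixed(l, p)
            pmf <- function(v) {
                vapply(v, function(vv)
                    dcszip(rep(vv, length(p)), p, fit$a, fit$p_off,
                           log = FALSE), numeric(length(p)))
            }
            k <- 2L
        }
        b <- makeBinning(l, pmf)
        r <- cellSpecificChi2(b, l, k, level = level)
        data.frame(gene = if (is.null(rownames(L))) g else rownames(L)[g],
                   chi2 = r$statistic, df = r$df, pvalue = r$p.value,
                   verdict = r$verdict, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}
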