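#' Total RNA velocity
#'
#' Deterministic-mean reduction of the stochastic models gives affine
#' velocity formulas in the smoothed expressions:
#' baseline \eqn{v_j = \alpha_j - \gamma_t \bar{r}_j};
#' splicing \eqn{v_j = \alpha_j - \gamma_s \bar{s}_j} (default) or, behind
#' \code{useTotal = TRUE}, \eqn{v_j = \alpha_j - \gamma_t \bar{r}_j} with
#' \eqn{\gamma_t} derived via \code{\link{gammaTotalFromSpliced}};
#' switching \eqn{v_j = \alpha_j(1 - p_{off,j}) - \gamma_t \bar{r}_j}
#' (pass the product as \code{alpha}).
#'
#' @param model \code{"baseline"}, \code{"splicing"} or
#'   \code{"switching"}.
#' @param alpha cell-specific transcription rates (for the switching model
#'   the product \eqn{\alpha_j(1 - p_{off,j})}); vector or gene x cell
#'   matrix.
#' @param gamma gene-wise degradation rate: \eqn{\gamma_t} (baseline,
#'   switching, or splicing with \code{useTotal}) or \eqn{\gamma_s}
#'   (splicing default). Scalar or one value per gene.
#' @param r_bar smoothed total expression (needed unless splicing
#'   default).
#' @param s_bar smoothed spliced expression (splicing default form).
#' @param useTotal for the splicing model, use the \eqn{\gamma_t \bar{r}}
#'   form instead of the default \eqn{\gamma_s \bar{s}} form.
#' @return Velocities (molecules/hour), same shape as \code{alpha}.
#' @export
velocityTotal <- function(model = c("baseline", "splicing", "switching"),
                          alpha, gamma, r_bar = NULL, s_bar = NULL,
                          useTotal = FALSE) {
    model <- match.arg(model)
    expr <- if (model == "splicing" && !useTotal) {
        if (is.null(s_bar)) stop("s_bar required for the splicing form",
                                 call. = FALSE)
        s_bar
    } else {
        if (is.null(r_bar)) stop("r_bar required for this model",
                                 call. = FALSE)
        r_bar
    }
    if (is.matrix(alpha)) alpha - expr * gamma else alpha - gamma * expr
}

#' Spliced RNA velocity
#'
#' \eqn{v_{s,j} = \beta_j \bar{u}_j - \gamma_s \bar{s}_j}: net flux into
#' the spliced pool.
#'
#' @param beta cell-specific splicing rates (vector or gene x cell
#'   matrix).
#' @param gamma_s gene-wise spliced degradation rate.
#' @param u_bar,s_bar smoothed unspliced/spliced expression.
#' @return Velocities, same shape as the inputs.
#' @export
velocitySpliced <- function(beta, gamma_s, u_bar, s_bar) {
    beta * u_bar - gamma_s * s_bar
}

#' Derive the total-mRNA degradation rate from the spliced one
#'
#' Because total mRNA includes unspliced molecules, \eqn{\gamma_t \le
#' \gamma_s}; the mean dynamics give \eqn{\gamma_s/\gamma_t =
#' \langle r\rangle/\langle s\rangle}. The ratio is estimated by the
#' zero-intercept least-squares slope \eqn{k = \sum \bar{r}\bar{s} /
#' \sum \bar{s}^2} of total on spliced expression, and
#' \eqn{\gamma_t = \gamma_s / k}.
#'
#' @param r_bar,s_bar smoothed total/spliced expression (vectors over
#'   cells, one gene).
#' @param gamma_s spliced degradation rate.
#' @return List with the slope \code{k} and \code{gamma_t}.
#' @export
gammaTotalFromSpliced <- function(r_bar, s_bar, gamma_s) {
    ss <- sum(s_bar^2)
    if (ss == 0) stop("spliced expression is identically zero",
                      call. = FALSE)
    k <- sum(r_bar * s_bar) / ss
    list(k = k, gamma_t = gamma_s / k)
}

#' Correctness of a velocity field against a temporal ordering
#'
#' A cell's velocity is correct if the cell nearest to its one-step
#' extrapolation \eqn{x_i + v_i} (excluding the cell itself) ranks after
#' it in the temporal ordering. The average over cells is the fraction of
#' correct velocities.
#'
#' @param positions cells x d matrix.
#' @param velocities cells x d matrix in the same space.
#' @param order per-cell temporal rank (larger = later).
#' @return List with per-cell 0/1 \code{correct} and the \code{average}.
#' @export
velocityCorrectness <- function(positions, velocities, order) {
    positions <- as.matrix(positions); velocities <- as.matrix(velocities)
    n <- nrow(positions)
    if (n < 2) stop("need >= 2 cells", call. = FALSE)
    target <- positions + velocities
    sq <- rowSums(positions^2)
    correct <- integer(n)
    d2 <- outer(rowSums(target^2), sq, "+") - 2 * tcrossprod(target,
                                                             positions)
    diag(d2) <- Inf
    j <- max.col(-d2, ties.method = "first")
    correct <- as.integer(order[j] > order)
    list(correct = correct, average = mean(correct))
}

#' Consistency of a velocity field over neighborhoods
#'
#' Per-cell Pearson correlation (over genes) between the cell's velocity
#' vector and the mean velocity of its kNN neighbors, averaged over cells;
#' the neighborhood-coherence score used in the spliced/unspliced velocity
#' literature. Cells whose velocity vector has zero variance are excluded
#' from the average.
#'
#' @param velocities gene x cell velocity matrix (>= 2 genes).
#' @param neighborhoods list from \code{\link{buildKNN}} (first element of
#'   each set is the cell itself and is excluded from the neighbor mean).
#' @return List with per-cell \code{score} (NA where undefined) and the
#'   \code{average} over defined cells.
#' @export
velocityConsistency <- function(velocities, neighborhoods) {
    velocities <- as.matrix(velocities)
    if (nrow(velocities) < 2) stop("need >= 2 genes", call. = FALSE)
    n <- ncol(velocities)
    score <- rep(NA_real_, n)
    for (j in seq_len(n)) {
        nb <- setdiff(neighborhoods[[j]], j)
        if (!length(nb)) next
        vm <- rowMeans(velocities[, nb, drop = FALSE])
        vj <- velocities[, j]
        if (stats::sd(vj) == 0 || stats::sd(vm) == 0) next
        score[j] <- cor(vj, vm)
    }
    list(score = score, average = mean(score, na.rm = TRUE))
}

#' Durations of ordered phases from a velocity field
#'
#' Integrates the velocity field through the data cloud to time a cyclic
#' or ordered process: starting from the \code{k} cells with smallest
#' relative position, the group state is extrapolated by \eqn{x \leftarrow
#' x + v\,dt}; at each step the \code{k} cells nearest the state vote on
#' the phase label and contribute their mean velocity, and the walk stops
#' once the group's mean relative position exceeds the given quantile of
#' all positions. The duration of a phase is (steps carrying that majority
#' label) x \code{dt}. Working with k-cell groups rather than single cells
#' averages out noise.
#'
#' @param positions cells x d matrix.
#' @param velocities cells x d matrix (same space; molecules/hour, so
#'   durations come out in hours).
#' @param phase per-cell phase labels.
#' @param relPosition per-cell relative position in [0, 1).
#' @param k group size (default 300).
#' @param dt step size in hours (default 0.01).
#' @param stopQuantile stop when the group mean relative position exceeds
#'   this quantile of all relative positions (default 0.88).
#' @param maxSteps safety cap on steps.
#' @return Named numeric vector of phase durations (hours).
#' @export
phaseDurations <- function(positions, velocities, phase, relPosition,
                           k = 300, dt = 0.01, stopQuantile = 0.88,
                           maxSteps = 1e5) {
    positions <- as.matrix(positions); velocities <- as.matrix(velocities)
    n <- nrow(positions)
    if (k > n) stop("k exceeds the number of cells", call. = FALSE)
    phase <- as.character(phase)
    thr <- quantile(relPosition, stopQuantile)
    grp <- order(relPosition)[seq_len(k)]
    x <- colMeans(positions[grp, , drop = FALSE])
    v <- colMeans(velocities[grp, , drop = FALSE])
    steps <- setNames(numeric(0), character(0))
    sq <- rowSums(positions^2)
    for (m in seq_len(maxSteps)) {
        if (sqrt(sum(v^2)) < 1e-12) {
            warning("trajectory stalled (velocity ~ 0); returning partial ",
                    "durations")
            break
        }
        x <- x + v * dt
        d2 <- sq - 2 * drop(positions %*% x) + sum(x^2)
        grp <- order(d2)[seq_len(k)]
        lab <- names(which.max(table(phase[grp])))
        steps[lab] <- if (lab %in% names(steps)) steps[lab] + 1 else 1
        v <- colMeans(velocities[grp, , drop = FALSE])
        if (mean(relPosition[grp]) > thr) break
    }
    steps * dt
}

#' Compute velocity layers on a LabelingExperiment
#'
#' Convenience wrapper: runs the cell-specific post-processing for the
#' chosen model with the supplied gene-wise degradation rates, multiplies
#' out the velocity formula, and stores the result as assay
#' \code{"velocity_T"} (and \code{"velocity_S"} for the splicing model).
#'
#' @param x \code{LabelingExperiment} with size factors and the smoothed
#'   layers from \code{\link{knnSmooth}}.
#' @param model one of \code{"baseline"}, \code{"splicing"},
#'   \code{"switching"}.
#' @param fit per-gene fit table from \code{\link{fitKinetics}} (columns
#'   \code{gamma_t} or \code{gamma_s}/\code{beta}).
#' @param neighborhoods list from \code{\link{buildKNN}}.
#' @return \code{x} with velocity assays added.
#' @export
computeVelocity <- function(x, model = c("baseline", "splicing",
                                         "switching"),
                            fit, neighborhoods) {
    model <- match.arg(model)
    p <- sizeFactors(x)
    t <- labelingTime(x)
    if (model %in% c("baseline", "switching")) {
        L <- .get_layer(x, "new")
        R <- .get_layer(x, "total_smoothed")
        ok <- which(is.finite(fit$gamma_t) & fit$gamma_t > 0)
        V <- matrix(NA_real_, nrow(L), ncol(L), dimnames = dimnames(L))
        A <- cellwiseBaseline(L[ok, , drop = FALSE], p, t, neighborhoods,
                              fit$gamma_t[ok])
        V[ok, ] <- A - R[ok, , drop = FALSE] * fit$gamma_t[ok]
        SummarizedExperiment::assay(x, "velocity_T") <- V
        AA <- matrix(NA_real_, nrow(L), ncol(L), dimnames = dimnames(L))
        AA[ok, ] <- A
        SummarizedExperiment::assay(
            x, if (model == "switching") "alpha_pon" else "alpha") <- AA
    } else {
        UL <- .get_layer(x, "ul"); SL <- .get_layer(x, "sl")
        U <- .get_layer(x, "uu_smoothed") + .get_layer(x, "ul_smoothed")
        S <- .get_layer(x, "su_smoothed") + .get_layer(x, "sl_smoothed")
        G <- nrow(UL); n <- ncol(UL)
        A <- B <- matrix(NA_real_, G, n, dimnames = dimnames(UL))
        ok <- which(is.finite(fit$gamma_s) & fit$gamma_s > 0 &
                        is.finite(fit$beta) & fit$beta > 0)
        for (g in ok) {
            cw <- cellwiseSplicing(UL[g, ], SL[g, ], p, t, neighborhoods,
                                   fit$gamma_s[g], fit$beta[g])
            A[g, ] <- cw$alpha; B[g, ] <- cw$beta
        }
        VT <- A - S * fit$gamma_s
        VS <- B * U - S * fit$gamma_s
        SummarizedExperiment::assay(x, "alpha") <- A
        SummarizedExperiment::assay(x, "beta") <- B
        SummarizedExperiment::assay(x, "velocity_T") <- VT
        SummarizedExperiment::assay(x, "velocity_S") <- VS
    }
    x
}
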