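#' Compute per-cell size factors from total counts
#'
#' The size factor of cell \eqn{j} is \eqn{p_j = n_j / n_0}, where
#' \eqn{n_j = \sum_i r_{ij}} is the cell's total molecule count and
#' \eqn{n_0} is the median (default) or the maximum of the \eqn{n_j}.
#' Under the cell-specific Poisson models \eqn{p_j} plays the role of the
#' per-cell capture probability, so measured counts have mean
#' \eqn{p_j a(t)}. Under the median convention some \eqn{p_j} exceed 1;
#' switching to the max convention rescales every \eqn{p_j} by a common
#' constant, which leaves degradation and splicing estimates untouched and
#' rescales transcription rates by that constant.
#'
#' @param x a \code{LabelingExperiment} with a \code{"total"} layer, or a
#'   gene x cell count matrix.
#' @param reference \code{"median"} (default) or \code{"max"}.
#' @param strict if \code{TRUE} (default) cells with zero total count are an
#'   error; if \code{FALSE} they are dropped with a warning (only possible
#'   when \code{x} is a \code{LabelingExperiment}).
#' @return For a matrix, the numeric vector \eqn{p_j}. For a
#'   \code{LabelingExperiment}, the object with \code{sizeFactors(x)} filled
#'   in (and zero-count cells dropped when \code{strict = FALSE}).
#' @examples
#' computeSizeFactors(rbind(c(40, 80, 120), c(60, 120, 180)))
#' @export
computeSizeFactors <- function(x, reference = c("median", "max"),
                               strict = TRUE) {
    reference <- match.arg(reference)
    if (is(x, "LabelingExperiment")) {
        cnt <- .get_layer(x, "total")
        n <- colSums(cnt)
        if (any(n == 0)) {
            off <- which(n == 0)
            if (strict)
                stop("cells with zero total count: ",
                     paste(head(off, 10), collapse = ", "), call. = FALSE)
            warning("dropping ", length(off),
                    " cell(s) with zero total count")
            x <- x[, -off]
            n <- n[-off]
        }
        n0 <- if (reference == "median") median(n) else max(n)
        x$size_factor <- n / n0
        return(x)
    }
    if (!length(x) || ncol(x) < 1)
        stop("empty count matrix", call. = FALSE)
    n <- colSums(as.matrix(x))
    if (any(n == 0))
        stop("cells with zero total count: ",
             paste(head(which(n == 0), 10), collapse = ", "), call. = FALSE)
    n0 <- if (reference == "median") median(n) else max(n)
    n / n0
}

#' Low-dimensional representation for neighbor search
#'
#' Builds the default space in which cell-cell distances are measured for
#' kNN smoothing: the top principal components of log1p-transformed,
#' depth-normalized total counts. The choice of space is a documented
#' default; any cells x d matrix can be supplied to \code{\link{buildKNN}}
#' instead.
#'
#' @param x a \code{LabelingExperiment} with size factors, or a gene x cell
#'   matrix plus \code{sizeFactor}.
#' @param nPCs number of principal components (default 30, capped at the
#'   data dimensions).
#' @param sizeFactor per-cell size factors when \code{x} is a matrix.
#' @return cells x nPCs numeric matrix.
#' @export
pcaRepresentation <- function(x, nPCs = 30, sizeFactor = NULL) {
    if (is(x, "LabelingExperiment")) {
        sizeFactor <- sizeFactors(x)
        if (is.null(sizeFactor))
            stop("run computeSizeFactors() first", call. = FALSE)
        x <- .get_layer(x, "total")
    }
    y <- log1p(sweep(as.matrix(x), 2, sizeFactor, "/"))
    nPCs <- min(nPCs, nrow(y) - 1L, ncol(y) - 1L)
    pc <- prcomp(t(y), center = TRUE, scale. = FALSE, rank. = nPCs)
    pc$x
}

#' Duration-stratified k-nearest-neighbor sets
#'
#' For each cell, finds the cell itself plus its \code{k - 1} nearest
#' neighbors by Euclidean distance in \code{representation}, restricted to
#' cells sharing the same labeling duration. Neighborhoods never cross
#' labeling durations because every cell-specific estimator averages counts
#' at a single duration. Ties are broken by cell index, so the result is
#' deterministic. If a duration stratum has fewer than \code{k} cells,
#' \code{k} is clipped to the stratum size with a warning.
#'
#' @param representation cells x d numeric matrix.
#' @param labelingTime per-cell labeling durations (any vector with one
#'   value per cell); a single duration may be given for one-shot data.
#' @param k neighborhood size including the cell itself (default 30).
#' @return A list of integer vectors, one per cell, each starting with the
#'   cell's own index.
#' @examples
#' reps <- cbind(c(0, 1, 10))
#' buildKNN(reps, labelingTime = c(1, 1, 1), k = 2)
#' @export
buildKNN <- function(representation, labelingTime, k = 30) {
    representation <- as.matrix(representation)
    n <- nrow(representation)
    labelingTime <- rep(labelingTime, length.out = n)
    if (k < 1) stop("k must be >= 1", call. = FALSE)
    out <- vector("list", n)
    for (t in unique(labelingTime)) {
        idx <- which(labelingTime == t)
        kk <- k
        if (length(idx) < k) {
            warning("duration ", t, " has ", length(idx),
                    " cells < k = ", k, "; clipping k")
            kk <- length(idx)
        }
        sub <- representation[idx, , drop = FALSE]
        # brute-force Euclidean distances within the stratum
        sq <- rowSums(sub^2)
        d2 <- outer(sq, sq, "+") - 2 * tcrossprod(sub)
        for (a in seq_along(idx)) {
            ord <- order(d2[a, ], seq_along(idx))  # ties by index
            nb <- idx[ord[seq_len(kk)]]
            out[[idx[a]]] <- c(idx[a], setdiff(nb, idx[a]))[seq_len(kk)]
        }
    }
    out
}

#' kNN-smoothed, depth-normalized expression
#'
#' Computes the neighborhood mean of depth-normalized counts,
#' \deqn{\bar{x}_j = \frac{1}{|N_j|} \sum_{i \in N_j} x_i / p_i,}
#' for each requested layer. With \code{k = 1} this reduces exactly to
#' per-cell depth normalization \eqn{x_j / p_j}. These smoothed values
#' (\eqn{\bar{l}, \bar{u}, \bar{s}, \bar{r}}) are the expressions entering
#' the velocity formulas; they differ from the pooled local estimators
#' \eqn{\hat{l}_j = \sum x_i / \sum p_i} used in cell-specific parameter
#' inference.
#'
#' @param x a \code{LabelingExperiment} with size factors.
#' @param neighborhoods list from \code{\link{buildKNN}}.
#' @param layers character vector of layer names to smooth (default: all
#'   count layers present).
#' @return \code{x} with an added assay \code{"<layer>_smoothed"} per input
#'   layer.
#' @export
knnSmooth <- function(x, neighborhoods, layers = NULL) {
    p <- sizeFactors(x)
    if (is.null(p)) stop("run computeSizeFactors() first", call. = FALSE)
    if (is.null(layers))
        layers <- intersect(SummarizedExperiment::assayNames(x), .LAYER_NAMES)
    nmax <- max(unlist(neighborhoods))
    if (nmax > ncol(x))
        stop("neighborhood references cell ", nmax, " outside the experiment",
             call. = FALSE)
    for (l in layers) {
        norm <- sweep(.get_layer(x, l), 2, p, "/")
        sm <- vapply(neighborhoods, function(nb)
            rowMeans(norm[, nb, drop = FALSE]), numeric(nrow(x)))
        if (nrow(x) == 1L) sm <- matrix(sm, nrow = 1L)
        dimnames(sm) <- dimnames(norm)
        SummarizedExperiment::assay(x, paste0(l, "_smoothed")) <- sm
    }
    x
}

#' Pooled local estimators over neighborhoods
#'
#' The maximum-likelihood local estimator used by the cell-specific
#' parameter post-processing: \eqn{\hat{x}_j = \sum_{i \in N_j} x_i /
#' \sum_{i \in N_j} p_i}. Internal building block, exported for
#' completeness.
#'
#' @param counts gene x cell matrix (one layer).
#' @param p per-cell size factors.
#' @param neighborhoods list from \code{\link{buildKNN}}.
#' @return gene x cell matrix of pooled estimates.
#' @export
knnPooled <- function(counts, p, neighborhoods) {
    counts <- as.matrix(counts)
    out <- vapply(neighborhoods, function(nb)
        rowSums(counts[, nb, drop = FALSE]) / sum(p[nb]),
        numeric(nrow(counts)))
    if (nrow(counts) == 1L) out <- matrix(out, nrow = 1L)
    dimnames(out) <- dimnames(counts)
    out
}

#' Read a LabelingExperiment from delimited files
#'
#' Reads a directory holding one matrix per layer -- either MatrixMarket
#' (\code{<layer>.mtx}) or CSV (\code{<layer>.csv}, genes in rows) -- plus a
#' \code{cells.csv} metadata table with columns \code{cell_id} and
#' \code{labeling_duration}.
#'
#' @param dir directory path.
#' @param timeUnit \code{"hours"} or \code{"minutes"}.
#' @return A \code{LabelingExperiment}.
#' @export
readLabelingExperiment <- function(dir, timeUnit = c("hours", "minutes")) {
    timeUnit <- match.arg(timeUnit)
    meta <- read.csv(file.path(dir, "cells.csv"))
    if (!all(c("cell_id", "labeling_duration") %in% names(meta)))
        stop("cells.csv must have columns cell_id, labeling_duration",
             call. = FALSE)
    assays <- list()
    for (l in .LAYER_NAMES) {
        fm <- file.path(dir, paste0(l, ".mtx"))
        fc <- file.path(dir, paste0(l, ".csv"))
        if (file.exists(fm)) {
            assays[[l]] <- as.matrix(Matrix::readMM(fm))
        } else if (file.exists(fc)) {
            assays[[l]] <- as.matrix(read.csv(fc, row.names = 1,
                                              check.names = FALSE))
        }
    }
    if (!length(assays)) stop("no layer files found in ", dir, call. = FALSE)
    le <- LabelingExperiment(assays, labelingTime = meta$labeling_duration,
                             timeUnit = timeUnit)
    colnames(le) <- meta$cell_id
    le
}
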