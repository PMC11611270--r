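#' @importFrom methods is new validObject callNextMethod setValidity as
#' @importFrom stats dpois rpois rbinom runif rnorm median optim optimize
#'   uniroot integrate pchisq prcomp quantile setNames cor rexp
#' @importFrom utils head read.csv write.csv
NULL

.LAYER_NAMES <- c("new", "total", "uu", "ul", "su", "sl")

#' LabelingExperiment: container for metabolic-labeling scRNA-seq counts
#'
#' An S4 class extending \linkS4class{SingleCellExperiment} that stores the
#' count layers produced by metabolic-labeling (e.g. 4sU) single-cell RNA-seq
#' protocols, together with the per-cell labeling duration. Genes are rows and
#' cells are columns, following Bioconductor convention. Recognised assay
#' names are \code{"new"} (new/labeled mRNA), \code{"total"} (total mRNA),
#' and the four splicing-resolved layers \code{"uu"}, \code{"ul"},
#' \code{"su"}, \code{"sl"} (unspliced/spliced x unlabeled/labeled).
#'
#' Validity requires all counts to be non-negative and, where layers coexist,
#' \code{new <= total}, \code{ul <= new} and \code{sl <= new}: a labeled
#' molecule cannot outnumber the pool it belongs to. Each cell carries exactly
#' one labeling duration (hours, > 0) in \code{colData(x)$labeling_time}.
#'
#' @param assays named list of gene x cell count matrices using the layer
#'   names above (at least one required).
#' @param labelingTime numeric vector of per-cell labeling durations.
#' @param timeUnit either \code{"hours"} (default) or \code{"minutes"};
#'   minutes are converted to hours on construction so that all rates are
#'   per hour.
#' @param ... further arguments (e.g. \code{colData}, \code{rowData}) passed
#'   to \code{\link[SingleCellExperiment]{SingleCellExperiment}}.
#'
#' @return A \code{LabelingExperiment} object.
#' @examples
#' le <- LabelingExperiment(
#'   assays = list(new = matrix(1:4, 2), total = matrix(5:8, 2)),
#'   labelingTime = c(1, 1))
#' labelingTime(le)
#' @export
#' @aliases LabelingExperiment-class
#' @import SingleCellExperiment
#' @import SummarizedExperiment
setClass("LabelingExperiment", contains = "SingleCellExperiment")

.validLabelingExperiment <- function(object) {
    msg <- NULL
    a <- SummarizedExperiment::assays(object)
    nm <- names(a)
    bad <- setdiff(nm, c(.LAYER_NAMES, paste0(.LAYER_NAMES, "_smoothed"),
                         "velocity_T", "velocity_S",
                         "alpha", "beta", "alpha_pon"))
    if (length(bad))
        msg <- c(msg, paste0("unknown layer name(s): ",
                             paste(bad, collapse = ", ")))
    for (l in intersect(nm, .LAYER_NAMES)) {
        m <- a[[l]]
        if (any(m < 0))
            msg <- c(msg, paste0("layer '", l, "' has negative entries"))
        if (any(m != round(m)))
            msg <- c(msg, paste0("layer '", l, "' has non-integer entries"))
    }
    pair_le <- function(small, big) {
        if (all(c(small, big) %in% nm) &&
            any(as.matrix(a[[small]]) > as.matrix(a[[big]])))
            paste0("layer '", small, "' exceeds layer '", big, "'")
    }
    msg <- c(msg, pair_le("new", "total"), pair_le("ul", "new"),
             pair_le("sl", "new"))
    lt <- object$labeling_time
    if (is.null(lt)) {
        msg <- c(msg, "colData must contain 'labeling_time'")
    } else if (any(!is.finite(lt)) || any(lt <= 0)) {
        msg <- c(msg, "labeling_time must be finite and > 0")
    }
    sf <- object$size_factor
    if (!is.null(sf) && (any(!is.finite(sf)) || any(sf <= 0)))
        msg <- c(msg, "size factors must be finite and > 0")
    if (is.null(msg)) TRUE else msg
}

setValidity("LabelingExperiment", .validLabelingExperiment)

#' @rdname LabelingExperiment-class
#' @export
LabelingExperiment <- function(assays, labelingTime,
                               timeUnit = c("hours", "minutes"), ...) {
    timeUnit <- match.arg(timeUnit)
    if (timeUnit == "minutes") labelingTime <- labelingTime / 60
    sce <- SingleCellExperiment::SingleCellExperiment(assays = assays, ...)
    sce$labeling_time <- rep(labelingTime, length.out = ncol(sce))
    new("LabelingExperiment", sce)
}

#' Per-cell labeling duration
#'
#' @param x a \code{LabelingExperiment}.
#' @return Numeric vector of labeling durations in hours, one per cell.
#' @export
labelingTime <- function(x) x$labeling_time

#' Labeling duration set
#'
#' @param x a \code{LabelingExperiment}.
#' @return Sorted unique labeling durations \eqn{t_1 < \dots < t_K}.
#' @export
labelingTimes <- function(x) sort(unique(labelingTime(x)))

#' @describeIn LabelingExperiment-class per-cell size factors (capture
#'   probabilities \eqn{p_j}), or \code{NULL} before
#'   \code{\link{computeSizeFactors}} has been run.
#' @param object a \code{LabelingExperiment}.
#' @importFrom BiocGenerics sizeFactors
#' @export
setMethod("sizeFactors", "LabelingExperiment", function(object) {
    object$size_factor
})

#' @importFrom BiocGenerics "sizeFactors<-"
#' @param value replacement size-factor vector.
#' @rdname LabelingExperiment-class
#' @export
setReplaceMethod("sizeFactors", "LabelingExperiment", function(object, value) {
    object$size_factor <- value
    validObject(object)
    object
})

#' @importFrom methods show
setMethod("show", "LabelingExperiment", function(object) {
    callNextMethod()
    tt <- labelingTimes(object)
    cat("labeling durations (h):", paste(signif(tt, 4), collapse = ", "),
        "\n")
    if (!is.null(sizeFactors(object)))
        cat("size factors: computed (median ",
            signif(median(sizeFactors(object)), 4), ")\n", sep = "")
})

.get_layer <- function(x, layer) {
    if (!layer %in% SummarizedExperiment::assayNames(x))
        stop("layer '", layer, "' is not present", call. = FALSE)
    as.matrix(SummarizedExperiment::assay(x, layer))
}
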