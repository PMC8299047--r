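#' ProteinAbundanceSet: a protein x sample quantification matrix with batches
#'
#' Thin extension of \link[SummarizedExperiment]{SummarizedExperiment} holding
#' one assay (\code{"abundance"}), a per-sample \code{batch} factor in
#' \code{colData}, and a scale flag (\code{"linear"} or \code{"log2"}) in
#' \code{metadata}. Missing measurements are \code{NA}. On the linear scale
#' all present values must be non-negative.
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}.
#'
#' @seealso [ProteinAbundanceSet()] for the constructor,
#'   [abundanceScale()], [batchOf()], [abundances()] for accessors.
#' @export
setClass("ProteinAbundanceSet", contains = "SummarizedExperiment")

setValidity("ProteinAbundanceSet", function(object) {
    msg <- character()
    if (!"abundance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'abundance' is required")
    if (!"batch" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'batch' column")
    sc <- S4Vectors::metadata(object)$scale
    if (is.null(sc) || !sc %in% c("linear", "log2"))
        msg <- c(msg, "metadata()$scale must be 'linear' or 'log2'")
    else if (identical(sc, "linear")) {
        a <- SummarizedExperiment::assay(object, "abundance")
        if (any(a < 0, na.rm = TRUE))
            msg <- c(msg, "linear-scale abundances must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ProteinAbundanceSet
#'
#' @param values numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns (colnames = sample ids); \code{NA} marks a missing
#'   (undetected) measurement.
#' @param batch per-sample batch labels (length \code{ncol(values)}).
#' @param scale \code{"linear"} (raw intensities, non-negative) or
#'   \code{"log2"}.
#'
#' @return A [ProteinAbundanceSet-class] object.
#' @examples
#' m <- matrix(2^rnorm(12, 10), 4, 3,
#'             dimnames = list(paste0("P", 1:4), paste0("S", 1:3)))
#' pas <- ProteinAbundanceSet(m, batch = c("b1", "b1", "b2"))
#' abundanceScale(pas)
#' @export
ProteinAbundanceSet <- function(values, batch, scale = c("linear", "log2")) {
    scale <- match.arg(scale)
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("P%05d", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
    if (length(batch) != ncol(values))
        stop("'batch' must have one label per sample column")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = values),
        colData = S4Vectors::DataFrame(batch = factor(batch),
                                       row.names = colnames(values)),
        metadata = list(scale = scale))
    methods::new("ProteinAbundanceSet", se)
}

#' @describeIn ProteinAbundanceSet the abundance matrix.
#' @param object,x a \code{ProteinAbundanceSet}.
#' @export
abundances <- function(object)
    SummarizedExperiment::assay(object, "abundance")

#' @describeIn ProteinAbundanceSet scale flag ("linear" or "log2").
#' @export
abundanceScale <- function(object) S4Vectors::metadata(object)$scale

#' @describeIn ProteinAbundanceSet per-sample batch factor.
#' @export
batchOf <- function(object) SummarizedExperiment::colData(object)$batch

#' @export
setMethod("show", "ProteinAbundanceSet", function(object) {
    a <- abundances(object)
    cat("ProteinAbundanceSet:", nrow(a), "proteins x", ncol(a), "samples\n")
    cat("  scale:", abundanceScale(object),
        "| batches:", nlevels(batchOf(object)),
        "| missing:", sprintf("%.1f%%", 100 * mean(is.na(a))), "\n")
})

#' ReferenceSet: proteins anchoring inter-batch correction
#'
#' Result of [selectReferenceProteins()]: the proteins detected in every
#' sample whose per-batch coefficient of variation (linear scale) stays below
#' the threshold in every batch, with the audited CV matrix.
#'
#' @slot proteinIds character vector of member protein ids.
#' @slot perBatchCV numeric matrix (member protein x batch) of CVs in percent.
#' @slot cvThreshold the CV threshold (%) used for selection.
#' @export
setClass("ReferenceSet",
    representation(proteinIds = "character",
                   perBatchCV = "matrix",
                   cvThreshold = "numeric"))

setValidity("ReferenceSet", function(object) {
    if (length(object@proteinIds) != nrow(object@perBatchCV) &&
        length(object@proteinIds) > 0)
        "perBatchCV must have one row per member protein" else TRUE
})

#' @describeIn ReferenceSet member protein ids.
#' @param object a \code{ReferenceSet}.
#' @export
referenceIds <- function(object) object@proteinIds

#' @describeIn ReferenceSet audited per-batch CV matrix (%).
#' @export
perBatchCV <- function(object) object@perBatchCV

#' @export
setMethod("show", "ReferenceSet", function(object) {
    cat("ReferenceSet:", length(object@proteinIds), "proteins",
        sprintf("(CV < %g%% in every batch, detected in all samples)\n",
                object@cvThreshold))
    if (length(object@proteinIds))
        cat("  max per-batch CV:",
            sprintf("%.1f%%", max(object@perBatchCV)), "\n")
})

#' @export
setMethod("length", "ReferenceSet", function(x) length(x@proteinIds))
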