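#' Coefficient of variation in percent
#'
#' \code{100 * sd(x) / mean(x)} with the sample (n-1) standard deviation,
#' computed on linear-scale values. Used both for reference-protein selection
#' and for auditing batch homogeneity.
#'
#' @param values numeric vector of linear-scale measurements (>= 2 values,
#'   positive mean).
#' @return CV as a percentage.
#' @examples
#' cvPercent(c(10, 10, 10))  # 0
#' cvPercent(c(1, 3))        # 100 * sqrt(2) / 2
#' @export
cvPercent <- function(values) {
    values <- values[!is.na(values)]
    if (length(values) < 2L)
        stop("CV undefined for fewer than 2 values")
    m <- mean(values)
    if (m <= 0)
        stop("CV undefined for non-positive mean")
    100 * stats::sd(values) / m
}

#' Log2-transform and median-center each sample
#'
#' First normalization stage: protein intensities are log2 transformed and
#' each sample (column) is standardized by subtracting its median over the
#' values present in that sample. Missing entries stay missing.
#'
#' @param pas a linear-scale [ProteinAbundanceSet-class]; all present values
#'   must be strictly positive.
#' @return A log2-scale \code{ProteinAbundanceSet} whose per-sample medians
#'   (over detected proteins) are 0.
#' @export
log2MedianCenter <- function(pas) {
    stopifnot(methods::is(pas, "ProteinAbundanceSet"))
    if (abundanceScale(pas) != "linear")
        stop("log2MedianCenter() expects a linear-scale matrix")
    a <- abundances(pas)
    bad <- which(!is.na(a) & a <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
        stop(sprintf(
            "non-positive abundance at protein '%s', sample '%s' (%g)",
            rownames(a)[bad[1, 1]], colnames(a)[bad[1, 2]],
            a[bad[1, 1], bad[1, 2]]))
    }
    la <- log2(a)
    med <- apply(la, 2L, stats::median, na.rm = TRUE)
    la <- sweep(la, 2L, med, "-")
    out <- ProteinAbundanceSet(la, batch = batchOf(pas), scale = "log2")
    S4Vectors::metadata(out)$sample_medians_log2 <- med
    out
}

#' Select low-variability reference proteins
#'
#' Returns the proteins identified in 100% of the samples (no missing value
#' anywhere, or more generally in at least \code{detectionFraction} of the
#' samples) whose per-batch coefficient of variation, computed on the
#' linear-scale intensities, is below \code{cvThreshold} in every batch.
#' These act as housekeeping anchors for [interbatchCorrect()].
#'
#' @param pas a linear-scale [ProteinAbundanceSet-class] with batch labels.
#' @param cvThreshold CV threshold in percent (default 60); the comparison is
#'   strict (\code{CV < cvThreshold}).
#' @param detectionFraction required fraction of samples with a measurement
#'   (default 1 = all samples of the whole cohort).
#' @return A [ReferenceSet-class]; empty (with a warning) when no protein
#'   qualifies, in which case inter-batch correction degenerates to a no-op.
#' @export
selectReferenceProteins <- function(pas, cvThreshold = 60,
                                    detectionFraction = 1.0) {
    stopifnot(methods::is(pas, "ProteinAbundanceSet"))
    if (abundanceScale(pas) != "linear")
        stop("reference selection uses linear-scale intensities")
    a <- abundances(pas)
    batch <- batchOf(pas)
    detected <- rowMeans(!is.na(a)) >= detectionFraction - 1e-12
    bl <- levels(batch)
    cvm <- matrix(NA_real_, nrow(a), length(bl),
                  dimnames = list(rownames(a), bl))
    for (b in bl) {
        sub <- a[, batch == b, drop = FALSE]
        cvm[, b] <- apply(sub, 1L, function(v) {
            v <- v[!is.na(v)]
            if (length(v) < 2L || mean(v) <= 0) return(NA_real_)
            100 * stats::sd(v) / mean(v)
        })
    }
    lowcv <- apply(cvm, 1L, function(v) all(!is.na(v)) && all(v < cvThreshold))
    keep <- detected & lowcv
    ids <- rownames(a)[keep]
    if (!length(ids))
        warning("no protein qualifies as reference; ",
                "inter-batch correction will be a no-op")
    methods::new("ReferenceSet", proteinIds = ids,
                 perBatchCV = cvm[keep, , drop = FALSE],
                 cvThreshold = cvThreshold)
}

#' Inter-batch correction anchored on reference proteins
#'
#' Second normalization stage: within each batch, every value is shifted by
#' minus the median log2 abundance of the reference proteins in that batch,
#' so the reference-protein median becomes 0 in (hence equal across) all
#' batches.
#'
#' @param pas a log2-scale, median-centered [ProteinAbundanceSet-class].
#' @param refset a [ReferenceSet-class] from [selectReferenceProteins()].
#' @return The corrected \code{ProteinAbundanceSet}; per-batch offsets that
#'   were subtracted are stored in \code{metadata()$batch_offsets}. An empty
#'   reference set passes the matrix through with a warning.
#' @export
interbatchCorrect <- function(pas, refset) {
    stopifnot(methods::is(pas, "ProteinAbundanceSet"),
              methods::is(refset, "ReferenceSet"))
    if (abundanceScale(pas) != "log2")
        stop("interbatchCorrect() expects a log2-scale matrix")
    if (length(refset) == 0L) {
        warning("empty reference set: returning input unchanged")
        return(pas)
    }
    a <- abundances(pas)
    ids <- intersect(referenceIds(refset), rownames(a))
    if (!length(ids))
        stop("no reference protein present in the matrix")
    batch <- batchOf(pas)
    offs <- vapply(levels(batch), function(b) {
        stats::median(a[ids, batch == b, drop = FALSE], na.rm = TRUE)
    }, numeric(1))
    for (b in levels(batch))
        a[, batch == b] <- a[, batch == b] - offs[[b]]
    out <- ProteinAbundanceSet(a, batch = batch, scale = "log2")
    S4Vectors::metadata(out)$batch_offsets <- offs
    out
}

#' Ranked relative-abundance map
#'
#' After normalization, each protein's relative abundance is the median of
#' its log2 values over the samples where it was detected. Proteins are
#' ranked by descending abundance; ties are broken by protein id so the
#' ranking is a reproducible permutation.
#'
#' @param pas a normalized log2-scale [ProteinAbundanceSet-class].
#' @return \code{data.frame} with columns \code{protein_id},
#'   \code{median_abundance} (log2), \code{n_samples_detected}, \code{rank},
#'   ordered by rank.
#' @export
relativeAbundance <- function(pas) {
    stopifnot(methods::is(pas, "ProteinAbundanceSet"))
    a <- abundances(pas)
    med <- apply(a, 1L, stats::median, na.rm = TRUE)
    n <- rowSums(!is.na(a))
    ord <- order(-med, rownames(a))
    out <- data.frame(protein_id = rownames(a)[ord],
                      median_abundance = med[ord],
                      n_samples_detected = n[ord],
                      rank = seq_along(ord),
                      row.names = NULL)
    out
}

#' Full two-stage normalization pipeline
#'
#' Convenience wrapper: median centering, reference-protein selection on the
#' original linear matrix, inter-batch correction, and the ranked map.
#'
#' @inheritParams selectReferenceProteins
#' @return list with elements \code{normalized} (ProteinAbundanceSet),
#'   \code{refset} (ReferenceSet) and \code{map} (relative-abundance
#'   data.frame).
#' @export
normalizeProteome <- function(pas, cvThreshold = 60, detectionFraction = 1.0) {
    centered <- log2MedianCenter(pas)
    refset <- selectReferenceProteins(pas, cvThreshold, detectionFraction)
    corrected <- if (length(refset)) interbatchCorrect(centered, refset)
                 else centered
    list(normalized = corrected, refset = refset,
         map = relativeAbundance(corrected))
}
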