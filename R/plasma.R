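#' Normalized spectral abundance factor (NSAF)
#'
#' \eqn{NSAF_i = (SpC_i / L_i) / \sum_j (SpC_j / L_j)}: spectral counts are
#' length-normalized and then rescaled so the abundances sum to 1.
#'
#' @param counts \code{data.frame} with columns \code{protein_id},
#'   \code{spectral_count} (>= 0) and \code{length} (>= 1), or vectors via
#'   the other two arguments.
#' @param lengths optional named vector of protein lengths taken from a
#'   FASTA; when given it overrides the \code{length} column (mismatches are
#'   warned).
#' @return named numeric vector of NSAF values summing to 1.
#' @examples
#' nsaf(data.frame(protein_id = c("A", "B"),
#'                 spectral_count = c(10, 5), length = c(100, 50)))
#' @export
nsaf <- function(counts, lengths = NULL) {
    stopifnot(is.data.frame(counts),
              all(c("protein_id", "spectral_count") %in% names(counts)))
    L <- counts$length
    if (!is.null(lengths)) {
        fromFasta <- unname(lengths[counts$protein_id])
        if (!is.null(L) && any(!is.na(L) & !is.na(fromFasta) &
                               L != fromFasta))
            warning("length column disagrees with FASTA lengths; ",
                    "FASTA values used")
        L <- fromFasta
    }
    if (is.null(L) || any(is.na(L)))
        stop("protein lengths missing")
    if (any(L < 1) || any(counts$spectral_count < 0))
        stop("lengths must be >= 1 and spectral counts >= 0")
    sl <- counts$spectral_count / L
    if (sum(sl) <= 0)
        stop("all spectral counts are zero")
    stats::setNames(sl / sum(sl), counts$protein_id)
}

#' Classify plasma proteins as blood-origin or tissue-expressed
#'
#' A plasma protein is called blood-origin when there is no transcript
#' evidence for its gene in the tumor-tissue RNA data; otherwise it is
#' tissue-expressed. Evidence flags record membership in the tissue proteome
#' and transcriptome.
#'
#' @param plasmaProteins genes/proteins identified in plasma (one gene
#'   namespace across all three sets).
#' @param tissueProteinGenes genes identified in tissue proteomics.
#' @param tissueTranscriptGenes genes detected in tissue RNA-seq.
#' @return \code{data.frame} with columns \code{protein_id}, \code{origin}
#'   (\code{"blood"} / \code{"tissue-expressed"}), \code{in_tissue_proteome},
#'   \code{in_tissue_transcriptome}.
#' @export
classifyOrigin <- function(plasmaProteins, tissueProteinGenes,
                           tissueTranscriptGenes) {
    p <- unique(plasmaProteins)
    inTP <- p %in% tissueProteinGenes
    inTT <- p %in% tissueTranscriptGenes
    data.frame(protein_id = p,
               origin = ifelse(inTT, "tissue-expressed", "blood"),
               in_tissue_proteome = inTP,
               in_tissue_transcriptome = inTT)
}

#' Per-sample fraction of identifications originating from blood
#'
#' For each tissue sample, \code{100 * |identified proteins in blood set| /
#' |identified proteins|}.
#'
#' @param perSampleIdentifications named list: sample -> character vector of
#'   identified proteins.
#' @param bloodSet blood-origin proteins (e.g. from [classifyOrigin()]).
#' @return named numeric vector of percentages; \code{NA} (with a warning)
#'   for samples with an empty identification set.
#' @export
tissueBloodFraction <- function(perSampleIdentifications, bloodSet) {
    if (!length(perSampleIdentifications))
        stop("no samples")
    out <- vapply(perSampleIdentifications, function(ids) {
        ids <- unique(ids)
        if (!length(ids)) return(NA_real_)
        100 * length(intersect(ids, bloodSet)) / length(ids)
    }, numeric(1))
    if (anyNA(out))
        warning(sum(is.na(out)), " sample(s) with empty identification set")
    out
}

#' Overlap of identified proteins with a marker panel
#'
#' @param identified identified proteins/genes.
#' @param panel non-empty marker panel (character vector, e.g. one set from
#'   [readGmt()]).
#' @return list with \code{fraction_pct} = \code{100 * |identified ∩ panel| /
#'   |panel|} and the \code{members} found.
#' @export
panelOverlap <- function(identified, panel) {
    panel <- unique(panel)
    if (!length(panel))
        stop("empty panel")
    members <- intersect(unique(identified), panel)
    list(fraction_pct = 100 * length(members) / length(panel),
         members = members)
}

#' Flag immunoglobulin genes by symbol prefix
#'
#' Documented heuristic: gene symbols starting with IGH, IGK or IGL.
#'
#' @param genes character vector of gene symbols.
#' @return logical vector.
#' @export
isImmunoglobulin <- function(genes) {
    grepl("^IG[HKL]", genes)
}
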