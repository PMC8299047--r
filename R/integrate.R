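#' Filter transcripts by read support and collapse to genes
#'
#' Keeps transcripts whose maximum read count over samples reaches
#' \code{minReads} (default 10), then collapses multiple transcripts of one
#' gene by the per-sample maximum. The "at least n reads" rule is applied to
#' the per-transcript maximum; pass \code{statistic = "total"} to threshold
#' the summed counts instead.
#'
#' @param transcripts \code{data.frame} with columns \code{transcript_id},
#'   \code{gene}, and numeric per-sample count columns (all remaining
#'   columns).
#' @param minReads read-count threshold (default 10, inclusive).
#' @param statistic \code{"max"} (default) or \code{"total"}.
#' @return \code{data.frame} with \code{gene} plus the sample columns, one
#'   row per retained gene.
#' @export
filterTranscripts <- function(transcripts, minReads = 10,
                              statistic = c("max", "total")) {
    statistic <- match.arg(statistic)
    stopifnot(is.data.frame(transcripts),
              all(c("transcript_id", "gene") %in% names(transcripts)))
    cnt <- as.matrix(transcripts[, setdiff(names(transcripts),
                                           c("transcript_id", "gene")),
                                 drop = FALSE])
    if (any(cnt < 0, na.rm = TRUE))
        stop("read counts must be non-negative")
    stat <- if (statistic == "max") apply(cnt, 1L, max, na.rm = TRUE)
            else rowSums(cnt, na.rm = TRUE)
    keep <- stat >= minReads
    cnt <- cnt[keep, , drop = FALSE]
    gene <- transcripts$gene[keep]
    if (!nrow(cnt))
        return(data.frame(gene = character()))
    agg <- do.call(rbind, lapply(split(seq_along(gene), gene), function(i)
        apply(cnt[i, , drop = FALSE], 2L, max, na.rm = TRUE)))
    out <- data.frame(gene = rownames(agg), agg, row.names = NULL,
                      check.names = FALSE)
    out
}

#' Three-way gene-set overlap with human-proteome coverage
#'
#' Venn bookkeeping for identified protein-coding genes, transcriptome genes,
#' and the annotated human proteome, with coverage of the predicted human
#' proteome (all annotated genes) and, when a PE1 subset is supplied, of the
#' identified (protein-level-evidence) human proteome.
#'
#' @param proteinGenes,transcriptGenes,humanGenes character vectors in one
#'   gene-symbol namespace (duplicates ignored).
#' @param humanIdentifiedGenes optional PE1 subset of \code{humanGenes}.
#' @return list of counts (\code{n_protein_only}, \code{n_transcript_only},
#'   \code{n_both}, \code{n_neither_of_human}) and coverage percentages
#'   (\code{coverage_predicted_pct}, \code{coverage_identified_pct}).
#' @examples
#' overlapSets(letters[1:3], letters[2:4], letters[1:5])
#' @export
overlapSets <- function(proteinGenes, transcriptGenes, humanGenes,
                        humanIdentifiedGenes = NULL) {
    p <- unique(proteinGenes); t <- unique(transcriptGenes)
    h <- unique(humanGenes)
    if (!length(h))
        stop("empty human gene set")
    res <- list(
        n_protein_only = length(setdiff(p, t)),
        n_transcript_only = length(setdiff(t, p)),
        n_both = length(intersect(p, t)),
        n_neither_of_human = length(setdiff(h, union(p, t))),
        coverage_predicted_pct = 100 * length(intersect(p, h)) / length(h),
        coverage_identified_pct = NA_real_)
    if (!is.null(humanIdentifiedGenes)) {
        hi <- unique(humanIdentifiedGenes)
        res$coverage_identified_pct <-
            100 * length(intersect(p, hi)) / length(hi)
    }
    res
}

#' Affine min-max scaling to a fixed range
#'
#' Maps the minimum to \code{lo} and the maximum to \code{hi} (defaults 10
#' and 35, the range used when plotting protein against transcript
#' abundances); being affine, it preserves order and Pearson correlations.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @param lo,hi target range endpoints.
#' @return The rescaled vector (\code{NA}s propagate).
#' @export
minmaxScale <- function(values, lo = 10, hi = 35) {
    r <- range(values, na.rm = TRUE, finite = TRUE)
    if (!is.finite(r[1]) || r[1] == r[2])
        stop("minmaxScale() requires at least two distinct values")
    lo + (values - r[1]) / (r[2] - r[1]) * (hi - lo)
}

#' Protein-transcript Pearson correlation on the gene intersection
#'
#' @param proteinMedians named numeric vector (gene -> relative protein
#'   abundance, log2).
#' @param transcriptMedians named numeric vector (gene -> transcript summary,
#'   e.g. log2 median intensity).
#' @param detectionFraction optional filter: keep only genes whose
#'   \code{transcriptDetected} fraction reaches this value (e.g. 0.99).
#' @param transcriptDetected named numeric vector (gene -> fraction of
#'   samples where the transcript was detected); required when
#'   \code{detectionFraction} is given.
#' @return list with \code{r}, \code{n}, \code{p_value}.
#' @export
correlateOmics <- function(proteinMedians, transcriptMedians,
                           detectionFraction = NULL,
                           transcriptDetected = NULL) {
    genes <- intersect(names(proteinMedians), names(transcriptMedians))
    if (!is.null(detectionFraction)) {
        if (is.null(transcriptDetected))
            stop("'transcriptDetected' required with a detection filter")
        ok <- names(transcriptDetected)[
            transcriptDetected >= detectionFraction - 1e-12]
        genes <- intersect(genes, ok)
    }
    x <- proteinMedians[genes]; y <- transcriptMedians[genes]
    keep <- is.finite(x) & is.finite(y)
    if (sum(keep) < 3L)
        stop("fewer than 3 gene pairs after filtering")
    ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
    list(r = unname(ct$estimate), n = sum(keep), p_value = ct$p.value)
}

# Rank-based enrichment score for one term: 2 * (mean member rank - overall
# mean rank) / (n - n_in); +1 when members hold the n_in largest ranks, -1
# when they hold the smallest, 0 in expectation under exchangeability.
enrichmentScore1D <- function(ranks, isMember) {
    n <- length(ranks)
    nIn <- sum(isMember)
    2 * (mean(ranks[isMember]) - (n + 1) / 2) / (n - nIn)
}

#' 1D annotation enrichment over a single ranked score list
#'
#' For each annotation term, tests whether member genes shift systematically
#' within the ranked scores (two-sided Mann-Whitney test, mid-ranks for
#' ties), and reports a rank-based enrichment score in [-1, 1] (positive =
#' members concentrated at high scores). P-values are Benjamini-Hochberg
#' adjusted across terms. Typical input scores are protein-minus-transcript
#' abundance differences after scaling both data sets to a common range.
#'
#' @param scores named numeric vector (gene -> score).
#' @param annotations named list of character vectors (term -> member genes),
#'   e.g. from [readGmt()].
#' @param minMembers minimum member genes present in \code{scores} for a
#'   term to be tested (default 5).
#' @return \code{data.frame} with columns \code{term}, \code{score},
#'   \code{p_raw}, \code{p_adjusted}, \code{n_members}, ordered by
#'   \code{p_raw}. Terms with all or no genes in the score list are skipped.
#' @export
enrichment1D <- function(scores, annotations, minMembers = 5L) {
    stopifnot(is.numeric(scores), !is.null(names(scores)))
    ranks <- rank(scores, ties.method = "average")
    rows <- list()
    for (term in names(annotations)) {
        isMember <- names(scores) %in% annotations[[term]]
        nIn <- sum(isMember)
        if (nIn < minMembers || nIn == length(scores))
            next
        s <- enrichmentScore1D(ranks, isMember)
        p <- suppressWarnings(stats::wilcox.test(
            scores[isMember], scores[!isMember],
            alternative = "two.sided", exact = FALSE)$p.value)
        rows[[term]] <- data.frame(term = term, score = s, p_raw = p,
                                   n_members = nIn)
    }
    if (!length(rows))
        return(data.frame(term = character(), score = numeric(),
                          p_raw = numeric(), p_adjusted = numeric(),
                          n_members = integer()))
    out <- do.call(rbind, rows)
    out$p_adjusted <- stats::p.adjust(out$p_raw, method = "BH")
    out <- out[order(out$p_raw),
               c("term", "score", "p_raw", "p_adjusted", "n_members")]
    rownames(out) <- NULL
    out
}
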