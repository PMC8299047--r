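#' TOP3 label-free protein roll-up
#'
#' Protein abundance is the mean of the three largest peptide areas among the
#' protein's unique and razor peptides. With fewer than three eligible
#' peptides, the mean of all available areas is used. Proteins with no
#' eligible peptide are omitted from the output.
#'
#' @param peptides \code{data.frame} with columns \code{protein_id},
#'   \code{sequence}, \code{area} (non-negative), \code{is_unique},
#'   \code{is_razor} (logical).
#' @return \code{data.frame} with columns \code{protein_id},
#'   \code{abundance}, \code{n_peptides_used}.
#' @examples
#' pep <- data.frame(protein_id = "P1", sequence = letters[1:4],
#'                   area = c(10, 20, 30, 40),
#'                   is_unique = TRUE, is_razor = FALSE)
#' top3Rollup(pep)$abundance  # mean(20, 30, 40) = 30
#' @export
top3Rollup <- function(peptides) {
    checkPeptideTable(peptides, c("protein_id", "area"))
    elig <- peptides[peptides$is_unique | peptides$is_razor, , drop = FALSE]
    if (!nrow(elig))
        return(data.frame(protein_id = character(), abundance = numeric(),
                          n_peptides_used = integer()))
    sp <- split(elig$area, elig$protein_id)
    ab <- vapply(sp, function(a) {
        top <- sort(a, decreasing = TRUE)[seq_len(min(3L, length(a)))]
        mean(top)
    }, numeric(1))
    n <- vapply(sp, function(a) min(3L, length(a)), integer(1))
    data.frame(protein_id = names(sp), abundance = unname(ab),
               n_peptides_used = unname(n), row.names = NULL)
}

#' TMT reporter-ion protein roll-up
#'
#' Per-channel protein abundance is the sum of reporter-ion intensities over
#' the protein's unique peptides only; razor peptides are excluded.
#' Zero-intensity channels contribute 0, not missing.
#'
#' @param peptides \code{data.frame} with columns \code{protein_id},
#'   \code{is_unique}, and one or more reporter intensity columns named in
#'   \code{channels}.
#' @param channels character vector of reporter channel column names;
#'   defaults to all columns matching \code{"^channel"}.
#' @return \code{data.frame} with \code{protein_id}, one summed column per
#'   channel, and \code{n_peptides_used}.
#' @export
tmtRollup <- function(peptides, channels = grep("^channel",
                                                names(peptides),
                                                value = TRUE)) {
    checkPeptideTable(peptides, "protein_id")
    if (!length(channels))
        stop("no reporter channel columns found")
    if (!all(channels %in% names(peptides)))
        stop("missing channel columns: ",
             paste(setdiff(channels, names(peptides)), collapse = ", "))
    elig <- peptides[as.logical(peptides$is_unique), , drop = FALSE]
    if (!nrow(elig)) {
        out <- data.frame(protein_id = character())
        for (ch in channels) out[[ch]] <- numeric()
        out$n_peptides_used <- integer()
        return(out)
    }
    for (ch in channels)
        if (any(elig[[ch]] < 0, na.rm = TRUE))
            stop("negative reporter intensity in column '", ch, "'")
    ids <- sort(unique(elig$protein_id))
    out <- data.frame(protein_id = ids)
    for (ch in channels) {
        s <- tapply(elig[[ch]], elig$protein_id, sum, na.rm = TRUE)
        out[[ch]] <- as.numeric(s[ids])
    }
    out$n_peptides_used <-
        as.integer(table(factor(elig$protein_id, levels = ids)))
    out
}

checkPeptideTable <- function(peptides, cols) {
    stopifnot(is.data.frame(peptides))
    miss <- setdiff(cols, names(peptides))
    if (length(miss))
        stop("peptide table lacks column(s): ", paste(miss, collapse = ", "))
    if ("area" %in% cols && any(peptides$area < 0, na.rm = TRUE))
        stop("peptide areas must be non-negative")
    invisible(TRUE)
}
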