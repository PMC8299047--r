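#' In-silico proteolytic digestion
#'
#' Enumerates tryptic (cleavage after K/R) or Arg-C-like (cleavage after R
#' only; the effective specificity of trypsin on fully lysine-acetylated
#' proteins) peptides. Cleavage is suppressed when the following residue is
#' proline. Peptides carrying 0 to \code{maxMissed} missed cleavages are
#' reported; at 0 missed cleavages the peptides tile the protein exactly.
#'
#' @param sequence protein sequence (single uppercase amino-acid string, or
#'   an \code{AAString}).
#' @param enzyme \code{"trypsin"} or \code{"argc"}.
#' @param maxMissed maximum number of missed cleavages (default 0).
#' @return \code{data.frame} with columns \code{sequence}, \code{start},
#'   \code{end} (1-based inclusive), \code{missed_cleavages}.
#' @examples
#' digestProtein("PEPTIDEKAAA")$sequence           # PEPTIDEK, AAA
#' digestProtein("PEPTIDEKPAA")$sequence           # proline suppresses cleavage
#' @export
digestProtein <- function(sequence, enzyme = c("trypsin", "argc"),
                          maxMissed = 0L) {
    enzyme <- match.arg(enzyme)
    sequence <- as.character(sequence)
    if (length(sequence) != 1L || !nzchar(sequence))
        stop("'sequence' must be one non-empty string")
    if (maxMissed < 0)
        stop("'maxMissed' must be >= 0")
    res <- strsplit(sequence, "")[[1]]
    n <- length(res)
    cutAfter <- if (enzyme == "trypsin") c("K", "R") else "R"
    # cleavage boundaries: after residue i when res[i] in cutAfter and
    # res[i+1] != "P"; 0 and n are implicit termini
    sites <- which(res %in% cutAfter)
    sites <- sites[sites < n & res[sites + 1L] != "P"]
    bounds <- c(0L, sites, n)
    starts0 <- bounds[-length(bounds)] + 1L
    ends0 <- bounds[-1L]
    out <- list()
    nseg <- length(starts0)
    for (mc in 0:min(maxMissed, nseg - 1L)) {
        i <- seq_len(nseg - mc)
        st <- starts0[i]
        en <- ends0[i + mc]
        out[[mc + 1L]] <- data.frame(
            sequence = substring(sequence, st, en),
            start = st, end = en, missed_cleavages = mc)
    }
    do.call(rbind, out)
}

#' Apply a single amino-acid substitution
#'
#' @param sequence protein sequence string (or \code{AAString}).
#' @param position 1-based residue index.
#' @param wt expected wild-type residue at \code{position}; the call fails if
#'   the sequence disagrees.
#' @param mut replacement residue (must differ from \code{wt}).
#' @return The mutated sequence string.
#' @export
applyMutation <- function(sequence, position, wt, mut) {
    sequence <- as.character(sequence)
    if (position < 1L || position > nchar(sequence))
        stop("position ", position, " outside sequence of length ",
             nchar(sequence))
    if (identical(wt, mut))
        stop("wild-type and mutant residues are identical")
    found <- substring(sequence, position, position)
    if (found != wt)
        stop(sprintf("wild-type mismatch at position %d: expected '%s', found '%s'",
                     position, wt, found))
    paste0(substring(sequence, 1L, position - 1L), mut,
           substring(sequence, position + 1L))
}

# Cleavage positions (residue indices cleaved after) for one sequence.
cleavageSites <- function(sequence, enzyme = "trypsin") {
    res <- strsplit(as.character(sequence), "")[[1]]
    n <- length(res)
    cutAfter <- if (enzyme == "trypsin") c("K", "R") else "R"
    sites <- which(res %in% cutAfter)
    sites[sites < n & res[sites + 1L] != "P"]
}

#' Mutation-specific peptides from a driver mutation
#'
#' Digests the mutated protein and reports the peptides that carry evidence
#' for the mutation: peptides covering the mutated residue
#' (\code{evidence = "direct"}) and peptides whose start or end is a cleavage
#' site gained or lost through the mutation (\code{evidence = "indirect"};
#' e.g. a substitution to lysine creates a new tryptic site whose downstream
#' peptide does not contain the mutated residue, yet exists only in the
#' mutant). Each peptide is flagged \code{distinguishable} when its sequence
#' is absent from the wild-type digest at the same missed-cleavage limit.
#'
#' @param sequence wild-type protein sequence.
#' @param position,wt,mut the substitution, as in [applyMutation()].
#' @param enzyme,maxMissed digestion settings (default trypsin, 2 missed
#'   cleavages).
#' @return \code{data.frame} with columns \code{peptide}, \code{start},
#'   \code{end}, \code{missed_cleavages}, \code{distinguishable},
#'   \code{cleavage_change} (\code{"none"}, \code{"gained"}, \code{"lost"}
#'   for the mutation as a whole), \code{evidence}.
#' @export
mutantSpecificPeptides <- function(sequence, position, wt, mut,
                                   enzyme = "trypsin", maxMissed = 2L) {
    mutSeq <- applyMutation(sequence, position, wt, mut)
    wtDig <- digestProtein(sequence, enzyme, maxMissed)
    mutDig <- digestProtein(mutSeq, enzyme, maxMissed)
    wtSites <- cleavageSites(sequence, enzyme)
    mutSites <- cleavageSites(mutSeq, enzyme)
    gained <- setdiff(mutSites, wtSites)
    lost <- setdiff(wtSites, mutSites)
    change <- if (length(gained) && length(lost)) "gained+lost"
              else if (length(gained)) "gained"
              else if (length(lost)) "lost"
              else "none"
    covers <- mutDig$start <= position & mutDig$end >= position
    abuts <- rep(FALSE, nrow(mutDig))
    if (length(gained))
        abuts <- mutDig$start %in% (gained + 1L) | mutDig$end %in% gained
    keep <- covers | abuts
    out <- mutDig[keep, , drop = FALSE]
    names(out)[names(out) == "sequence"] <- "peptide"
    out$distinguishable <- !(out$peptide %in% wtDig$sequence)
    out$cleavage_change <- change
    out$evidence <- ifelse(covers[keep], "direct", "indirect")
    rownames(out) <- NULL
    out
}

#' Infer candidate mutations from an unexpected cleavage boundary
#'
#' When an observed peptide starts right after a residue that is neither
#' lysine nor arginine, the observation is only explainable (under fully
#' specific digestion) if that preceding residue was mutated into a cleavable
#' one. Candidates substituting it to K and to R are emitted as indirect
#' evidence; they are never auto-promoted to confirmed calls.
#'
#' @param observedPeptide peptide sequence observed in the data.
#' @param sequence wild-type protein sequence in which it occurs.
#' @return \code{data.frame} with columns \code{position}, \code{wt},
#'   \code{mut}, \code{label}, \code{evidence}; zero rows when every
#'   occurrence is canonically cleavable or N-terminal.
#' @export
inferIndirectCleavage <- function(observedPeptide, sequence) {
    sequence <- as.character(sequence)
    hits <- gregexpr(observedPeptide, sequence, fixed = TRUE)[[1]]
    if (hits[1] == -1L)
        stop("peptide '", observedPeptide, "' not found in the sequence")
    out <- list()
    for (st in as.integer(hits)) {
        if (st == 1L) next                        # protein N-terminus
        prev <- substring(sequence, st - 1L, st - 1L)
        if (prev %in% c("K", "R")) next           # canonical cleavage
        for (m in c("K", "R"))
            out[[length(out) + 1L]] <- data.frame(
                position = st - 1L, wt = prev, mut = m,
                label = paste0(prev, st - 1L, m), evidence = "indirect")
    }
    if (!length(out))
        return(data.frame(position = integer(), wt = character(),
                          mut = character(), label = character(),
                          evidence = character()))
    do.call(rbind, out)
}

#' Map a peptide to the proteins containing it
#'
#' Exact substring matching against a proteome, with isoleucine and leucine
#' treated as indistinguishable by default (they are isobaric in MS). A
#' peptide is unique when the set of genes it maps to has size 1.
#'
#' @param peptide peptide sequence.
#' @param proteome named character vector or \code{AAStringSet} of protein
#'   sequences (names = protein ids).
#' @param genes optional named vector mapping protein id to gene symbol;
#'   defaults to the protein ids themselves.
#' @param ilEquivalent treat I and L as equal (default TRUE).
#' @return list with \code{protein_ids}, \code{genes}, and logical
#'   \code{unique}.
#' @export
peptideUniqueness <- function(peptide, proteome, genes = NULL,
                              ilEquivalent = TRUE) {
    if (!nzchar(peptide))
        stop("empty peptide")
    seqs <- asNamedSequences(proteome)
    if (!length(seqs))
        stop("empty proteome")
    if (is.null(genes))
        genes <- stats::setNames(names(seqs), names(seqs))
    if (ilEquivalent) {
        peptide <- chartr("I", "L", peptide)
        seqs <- chartr("I", "L", seqs)
    }
    hit <- vapply(seqs, function(s) grepl(peptide, s, fixed = TRUE),
                  logical(1))
    ids <- names(seqs)[hit]
    gs <- unique(unname(genes[ids]))
    list(protein_ids = ids, genes = gs, unique = length(gs) == 1L)
}

#' Missing-protein evidence check (two peptides of length >= 9)
#'
#' Protein-level evidence claims for missing proteins require at least two
#' uniquely mapping peptides of at least 9 amino acids, following the Human
#' Proteome Project data-interpretation guidelines.
#'
#' @param uniquePeptides character vector of peptides already validated as
#'   uniquely mapping to the protein.
#' @param minPeptides,minLength guideline thresholds (defaults 2 and 9).
#' @return list with \code{pass}, \code{n_qualifying}, \code{n_total}.
#' @export
hppMissingProteinCheck <- function(uniquePeptides, minPeptides = 2L,
                                   minLength = 9L) {
    q <- sum(nchar(uniquePeptides) >= minLength)
    list(pass = q >= minPeptides, n_qualifying = q,
         n_total = length(uniquePeptides))
}

#' Tally proteins by protein-existence (PE) level
#'
#' @param peLevels vector of PE levels (1-5, \code{"PE1"}..\code{"PE5"}, or
#'   anything else, which is counted as unknown with a warning).
#' @return named integer vector with entries \code{PE1}..\code{PE5},
#'   \code{unknown}, \code{total}.
#' @export
peCategoryTally <- function(peLevels) {
    lv <- toupper(trimws(as.character(peLevels)))
    lv <- sub("^PE", "", lv)
    out <- stats::setNames(integer(6), c(paste0("PE", 1:5), "unknown"))
    known <- lv %in% as.character(1:5)
    if (any(!known) && length(lv))
        warning(sum(!known), " protein(s) with unknown PE level")
    tab <- table(factor(lv[known], levels = as.character(1:5)))
    out[1:5] <- as.integer(tab)
    out["unknown"] <- sum(!known)
    c(out, total = length(lv))
}

#' Run a mutation panel through the mutant-peptide engine
#'
#' @param proteome named character vector or \code{AAStringSet} of wild-type
#'   sequences, names matching \code{panel$gene}.
#' @param panel \code{data.frame} with columns \code{gene}, \code{position},
#'   \code{wt}, \code{mut}, and optionally \code{label}.
#' @param enzyme,maxMissed digestion settings passed through.
#' @return \code{data.frame}: one row per candidate peptide per mutation,
#'   the [mutantSpecificPeptides()] columns prefixed by \code{gene} and
#'   \code{label}.
#' @export
mutationPanelPeptides <- function(proteome, panel, enzyme = "trypsin",
                                  maxMissed = 2L) {
    seqs <- asNamedSequences(proteome)
    out <- list()
    for (i in seq_len(nrow(panel))) {
        g <- panel$gene[i]
        if (!g %in% names(seqs))
            stop("no sequence for gene '", g, "'")
        lab <- if ("label" %in% names(panel)) panel$label[i]
               else paste0(panel$wt[i], panel$position[i], panel$mut[i])
        calls <- mutantSpecificPeptides(seqs[[g]], panel$position[i],
                                        panel$wt[i], panel$mut[i],
                                        enzyme, maxMissed)
        if (nrow(calls))
            out[[length(out) + 1L]] <-
                cbind(data.frame(gene = g, label = lab), calls)
    }
    if (!length(out))
        return(data.frame())
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
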