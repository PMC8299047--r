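#' Read / write GMT annotation sets
#'
#' GMT: one tab-separated line per set (name, description, members...).
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    out <- list()
    for (ln in lines) {
        f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (length(f) < 3L)
            stop("malformed GMT line: ", substr(ln, 1, 40))
        out[[f[1]]] <- f[-(1:2)]
    }
    out
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @param descriptions optional per-set description strings.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
    if (is.null(descriptions))
        descriptions <- rep("na", length(sets))
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], descriptions[i], sets[[i]]),
              collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a protein x sample abundance matrix with a batch sidecar
#'
#' The matrix TSV has protein ids in the first column and one numeric column
#' per sample (empty cells = missing). The sidecar TSV has columns
#' \code{sample} and \code{batch}.
#'
#' @param matrixPath,batchPath file paths.
#' @param scale scale flag of the stored values.
#' @return A [ProteinAbundanceSet-class].
#' @export
readAbundanceMatrix <- function(matrixPath, batchPath,
                                scale = c("linear", "log2")) {
    scale <- match.arg(scale)
    tab <- utils::read.delim(matrixPath, check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    bt <- utils::read.delim(batchPath)
    if (!all(colnames(m) %in% bt$sample))
        stop("batch sidecar is missing samples")
    batch <- bt$batch[match(colnames(m), bt$sample)]
    ProteinAbundanceSet(m, batch = batch, scale = scale)
}

#' @rdname readAbundanceMatrix
#' @param pas a \code{ProteinAbundanceSet} to write.
#' @export
writeAbundanceMatrix <- function(pas, matrixPath, batchPath) {
    a <- abundances(pas)
    df <- data.frame(protein_id = rownames(a), a, check.names = FALSE)
    utils::write.table(df, matrixPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
        data.frame(sample = colnames(a), batch = as.character(batchOf(pas))),
        batchPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(matrixPath)
}

#' Read a proteome FASTA as a named character vector
#'
#' Thin wrapper over \code{Biostrings::readAAStringSet}; names are truncated
#' at the first whitespace.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readProteomeFasta <- function(path) {
    aa <- Biostrings::readAAStringSet(path)
    seqs <- as.character(aa)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    seqs
}

#' @rdname readProteomeFasta
#' @param proteome named character vector of sequences.
#' @export
writeProteomeFasta <- function(proteome, path) {
    aa <- Biostrings::AAStringSet(unlist(proteome))
    Biostrings::writeXStringSet(aa, path)
    invisible(path)
}

#' Read a mutation panel TSV
#'
#' Expected columns: \code{gene}, \code{position}, \code{wt}, \code{mut},
#' optional \code{label}.
#'
#' @param path file path.
#' @return \code{data.frame}.
#' @export
readMutationPanel <- function(path) {
    p <- utils::read.delim(path, colClasses = "character")
    need <- c("gene", "position", "wt", "mut")
    if (!all(need %in% names(p)))
        stop("mutation panel needs columns: ", paste(need, collapse = ", "))
    p$position <- as.integer(p$position)
    p
}

#' The packaged motif-to-kinase annotation table
#'
#' A small, synthetic (hand-curated, not exported from any external
#' database) table mapping phosphorylation motif patterns to kinases known
#' to prefer them, for [predictKinases()].
#'
#' @return \code{data.frame} with columns \code{motif}, \code{kinase}.
#' @export
kinaseMotifTable <- function() {
    utils::read.delim(system.file("extdata", "kinase_motifs_synthetic.tsv",
                                  package = "proteoMap"))
}
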