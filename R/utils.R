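# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates as-is.
withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(force(expr))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    expr
}

# Deterministic child seed for sub-generators; stays well below 2^31.
childSeed <- function(seed, offset) {
    (abs(as.integer(seed)) %% 1000003L) * 1000L + as.integer(offset)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Coerce an AAStringSet or character vector to a named character vector of
# sequences (as.character() on a plain character drops nothing, but names
# are preserved explicitly for both input types).
asNamedSequences <- function(proteome) {
    nm <- names(proteome)
    seqs <- as.character(proteome)
    names(seqs) <- if (is.null(nm)) sprintf("PROT%04d", seq_along(seqs))
                   else nm
    seqs
}

stopifnotScalarCount <- function(x, name) {
    if (length(x) != 1L || is.na(x) || x < 1 || x != round(x))
        stop("'", name, "' must be a single integer >= 1")
    invisible(as.integer(x))
}
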