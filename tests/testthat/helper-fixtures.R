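# Shared fixture builders; everything is generated in code.

# Small linear-scale matrix with explicit batch structure.
makeToyPas <- function(values, nBatches = 2L) {
    values <- as.matrix(values)
    batch <- rep(sprintf("b%d", seq_len(nBatches)),
                 length.out = ncol(values))
    ProteinAbundanceSet(values, batch = sort(batch), scale = "linear")
}

# Random amino-acid sequence guaranteed to contain cleavage sites.
randomProtein <- function(n = 60L) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWYKRKRP", "")[[1]], n,
                 replace = TRUE), collapse = "")
}

# Brute-force digest oracle used against digestProtein(): enumerate all
# substrings delimited by cleavage boundaries, fully independently.
oracleDigest0 <- function(seq, enzyme = "trypsin") {
    res <- strsplit(seq, "")[[1]]
    cut <- if (enzyme == "trypsin") c("K", "R") else "R"
    sites <- integer()
    for (i in seq_len(length(res) - 1L))
        if (res[i] %in% cut && res[i + 1L] != "P")
            sites <- c(sites, i)
    bounds <- c(0L, sites, length(res))
    mapply(function(a, b) substr(seq, a + 1L, b),
           bounds[-length(bounds)], bounds[-1L])
}
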