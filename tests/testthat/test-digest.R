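test_that("tryptic digestion cleaves after K/R, honors the proline rule, and tiles the protein", {
    expect_equal(digestProtein("PEPTIDEKAAA")$sequence,
                 c("PEPTIDEK", "AAA"))
    expect_equal(digestProtein("PEPTIDEKPAA")$sequence, "PEPTIDEKPAA")
    expect_equal(digestProtein("QVVIDGETCLLDILDTAGQEEYSAMR")$sequence,
                 "QVVIDGETCLLDILDTAGQEEYSAMR")
    expect_equal(digestProtein("AAKBBRCC", enzyme = "argc")$sequence,
                 c("AAKBBR", "CC"))
    expect_error(digestProtein(""), "non-empty")

    set.seed(31)
    for (rep in 1:10) {
        seq <- randomProtein(sample(20:120, 1))
        d0 <- digestProtein(seq, maxMissed = 0)
        expect_identical(paste(d0$sequence, collapse = ""), seq)
        expect_identical(unname(oracleDigest0(seq)), d0$sequence)
        # every k-missed peptide concatenates k+1 adjacent 0-missed peptides
        dk <- digestProtein(seq, maxMissed = 2)
        for (i in which(dk$missed_cleavages > 0)) {
            k <- dk$missed_cleavages[i]
            j <- match(dk$start[i], d0$start)
            expect_identical(
                paste(d0$sequence[j:(j + k)], collapse = ""),
                dk$sequence[i])
        }
    }
})

test_that("applyMutation substitutes, validates the wild type, and is an involution", {
    expect_equal(applyMutation("AATAGQEEYA", 6, "Q", "K"), "AATAGKEEYA")
    expect_error(applyMutation("AATAGQEEYA", 6, "A", "K"),
                 "expected 'A', found 'Q'")
    s <- "AATAGQEEYA"
    expect_identical(applyMutation(applyMutation(s, 6, "Q", "K"),
                                   6, "K", "Q"), s)
})

test_that("mutant-specific peptides carry cleavage gain/loss and the WT comparison", {
    prot <- simulateProteome(nFiller = 0)
    q61k <- mutantSpecificPeptides(prot[["NRAS"]], 61, "Q", "K")
    expect_true("QVVIDGETCLLDILDTAGK" %in%
                q61k$peptide[q61k$distinguishable])
    expect_equal(unique(q61k$cleavage_change), "gained")
    # the gained site truncates the WT peptide: no mutant-specific peptide
    # covering Gln61 retains the downstream -EEYSAMR tail
    direct <- q61k[q61k$evidence == "direct" & q61k$missed_cleavages == 0, ]
    expect_false(any(grepl("EEYSAMR$", direct$peptide)))

    g13d <- mutantSpecificPeptides(prot[["KRAS"]], 13, "G", "D")
    expect_true("LVVVGAGDVGK" %in% g13d$peptide[g13d$distinguishable])
    expect_equal(unique(g13d$cleavage_change), "none")

    # destroying a cleavage site is reported as lost
    lost <- mutantSpecificPeptides("AAAKBBBKCCC", 4, "K", "Q")
    expect_equal(unique(lost$cleavage_change), "lost")
    expect_true("AAAQBBBK" %in% lost$peptide[lost$distinguishable])
})

test_that("distinguishability agrees with a dual-digest oracle on random mutations", {
    set.seed(37)
    for (rep in 1:20) {
        seq <- randomProtein(50)
        pos <- sample(nchar(seq), 1)
        wt <- substr(seq, pos, pos)
        mut <- sample(setdiff(c("A", "K", "R", "P", "Q"), wt), 1)
        calls <- mutantSpecificPeptides(seq, pos, wt, mut, maxMissed = 1)
        wtPeps <- digestProtein(seq, maxMissed = 1)$sequence
        mutPeps <- digestProtein(applyMutation(seq, pos, wt, mut),
                                 maxMissed = 1)$sequence
        for (i in seq_len(nrow(calls)))
            expect_identical(calls$distinguishable[i],
                             !(calls$peptide[i] %in% wtPeps))
        # every reported peptide really is a mutant digest product
        expect_true(all(calls$peptide %in% mutPeps))
    }
})

test_that("indirect cleavage evidence proposes K/R substitutions at non-tryptic starts", {
    prot <- simulateProteome(nFiller = 0)
    cand <- inferIndirectCleavage("SSVILFLNK", prot[["GNA11"]])
    expect_equal(nrow(cand), 2L)
    expect_equal(unique(cand$position), 266L)
    expect_equal(unique(cand$wt), "N")
    expect_setequal(cand$mut, c("K", "R"))
    expect_equal(cand$label[cand$mut == "K"], "N266K")
    # canonical cleavage upstream: nothing to propose
    expect_equal(nrow(inferIndirectCleavage("QVVIDGETCLLDILDTAGQEEYSAMR",
                                            prot[["NRAS"]])), 0L)
    # N-terminal match has no preceding residue
    expect_equal(nrow(inferIndirectCleavage("MTEYK", prot[["NRAS"]])), 0L)
    expect_error(inferIndirectCleavage("WWWWWW", prot[["NRAS"]]),
                 "not found")
})

test_that("peptide uniqueness uses I/L-equivalent substring matching", {
    proteome <- c(g1 = "MMMPEPTLDEKWWW", g2 = "CCCAAACCC",
                  g3 = "DDDPEPKDDD")
    u <- peptideUniqueness("AAA", proteome)
    expect_identical(u$protein_ids, "g2")
    expect_true(u$unique)
    expect_true(peptideUniqueness("PEPTIDE", proteome)$unique)   # I == L
    expect_identical(peptideUniqueness("PEPTIDE", proteome,
                                       ilEquivalent = FALSE)$protein_ids,
                     character(0))
    # gene-level collapse: two proteins of one gene stay unique
    genes <- c(g1 = "GENEA", g1b = "GENEA")
    two <- c(g1 = "AAPEPKAA", g1b = "CCPEPKCC")
    expect_true(peptideUniqueness("PEPK", two, genes = genes)$unique)
    expect_error(peptideUniqueness("", proteome), "empty")
})

test_that("uniqueness agrees with a brute-force substring scan", {
    set.seed(41)
    proteome <- vapply(1:6, function(i) randomProtein(80), character(1))
    names(proteome) <- paste0("pr", 1:6)
    scan <- chartr("I", "L", proteome)
    for (rep in 1:200) {
        src <- sample(6, 1)
        st <- sample(70, 1)
        pep <- substr(proteome[[src]], st, st + sample(4:9, 1))
        hits <- names(scan)[vapply(scan, function(s)
            grepl(chartr("I", "L", pep), s, fixed = TRUE), logical(1))]
        expect_setequal(peptideUniqueness(pep, proteome)$protein_ids, hits)
    }
})

test_that("missing-protein evidence needs two unique peptides of length >= 9", {
    expect_true(hppMissingProteinCheck(c("ABCDEFGHI", "IHGFEDCBA"))$pass)
    expect_false(hppMissingProteinCheck("ABCDEFGHIJKLMNOPQRST")$pass)
    r <- hppMissingProteinCheck(c("12345678", "123456789", "1234567890"))
    expect_true(r$pass)
    expect_equal(r$n_qualifying, 2L)
})

test_that("PE tallies are complete and flag unknown levels", {
    tal <- peCategoryTally(rep(c("PE2", "PE3", "PE5"), c(20, 2, 4)))
    expect_equal(unname(tal[c("PE2", "PE3", "PE5")]), c(20L, 2L, 4L))
    expect_equal(unname(tal["total"]), 26L)
    expect_equal(unname(peCategoryTally(character())["total"]), 0L)
    expect_warning(tal2 <- peCategoryTally(c("PE1", "PE1", "woot")),
                   "unknown")
    expect_equal(unname(tal2["unknown"]), 1L)
    expect_equal(unname(tal2["total"]), 3L)
})
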