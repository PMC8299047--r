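test_that("cvPercent follows the sample-sd formula and is scale invariant", {
    expect_equal(cvPercent(c(10, 10, 10)), 0)
    expect_equal(cvPercent(c(1, 3)), 100 * sqrt(2) / 2)
    set.seed(5)
    v <- stats::rlnorm(20)
    expect_equal(cvPercent(v * 17), cvPercent(v))
    expect_error(cvPercent(5), "fewer than 2")
    expect_error(cvPercent(c(-3, 1)), "non-positive mean")
})

test_that("log2 median centering zeroes per-sample medians and keeps missingness", {
    pas <- makeToyPas(cbind(c(2, 8, 32)), nBatches = 1)
    out <- log2MedianCenter(pas)
    expect_equal(unname(abundances(out)[, 1]), c(-2, 0, 2))

    set.seed(7)
    m <- matrix(stats::rlnorm(120, 8, 2), 20, 6)
    m[sample(120, 15)] <- NA
    pas <- makeToyPas(m)
    out <- log2MedianCenter(pas)
    a <- abundances(out)
    expect_identical(unname(is.na(a)), is.na(m))
    for (j in 1:6)   # independent median oracle
        expect_equal(stats::median(a[, j], na.rm = TRUE), 0,
                     tolerance = 1e-9)
    # re-centering the (exponentiated) centered matrix changes nothing
    again <- log2MedianCenter(makeToyPas(2^a))
    expect_equal(abundances(again), a)
})

test_that("non-positive abundances are rejected with the offending cell named", {
    m <- matrix(c(1, 2, 0, 4), 2, 2,
                dimnames = list(c("pA", "pB"), c("s1", "s2")))
    expect_error(log2MedianCenter(makeToyPas(m)), "pA.*s2")
})

test_that("reference selection applies detection and per-batch CV rules exactly", {
    # 3 proteins x 2 batches x 3 samples; values chosen at the CV boundary
    mkRow <- function(cv) {
        # symmetric triple around 10 with prescribed sample CV (percent)
        d <- cv / 100 * 10 * sqrt(2) / sqrt(3) * sqrt(3 / 2)
        c(10 - d, 10, 10 + d)
    }
    good <- c(mkRow(59.9), mkRow(59.9))
    edge <- c(mkRow(59.9), mkRow(60.0))
    m <- rbind(good = good, edge = edge, miss = good)
    colnames(m) <- paste0("s", 1:6)
    m["miss", 4] <- NA
    pas <- ProteinAbundanceSet(m, batch = rep(c("b1", "b2"), each = 3))
    expect_equal(cvPercent(m["good", 1:3]), 59.9, tolerance = 1e-9)
    expect_equal(cvPercent(m["edge", 4:6]), 60.0, tolerance = 1e-9)
    rs <- selectReferenceProteins(pas, cvThreshold = 60)
    expect_identical(referenceIds(rs), "good")   # edge: CV not < 60 in b2
    expect_equal(dim(perBatchCV(rs)), c(1L, 2L))
})

test_that("inter-batch correction zeroes the reference median in every batch", {
    set.seed(9)
    m <- matrix(stats::rlnorm(200, 9, 1), 20, 10)
    rownames(m) <- sprintf("P%02d", 1:20)
    pas <- ProteinAbundanceSet(m, batch = rep(c("b1", "b2"), each = 5))
    centered <- log2MedianCenter(pas)
    rs <- selectReferenceProteins(pas, cvThreshold = 1e6)
    out <- interbatchCorrect(centered, rs)
    a <- abundances(out)
    for (b in c("b1", "b2"))
        expect_equal(stats::median(a[referenceIds(rs),
                                     batchOf(out) == b]), 0,
                     tolerance = 1e-9)
    # single batch: output equals input shifted by one constant
    pas1 <- ProteinAbundanceSet(m, batch = rep("b1", 10))
    c1 <- log2MedianCenter(pas1)
    out1 <- interbatchCorrect(c1, selectReferenceProteins(pas1, 1e6))
    shift <- abundances(c1) - abundances(out1)
    expect_equal(max(shift) - min(shift), 0, tolerance = 1e-12)
})

test_that("an empty reference set passes through with a warning", {
    m <- matrix(c(1, 2, 4, 8), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
    m[1, 1] <- NA
    m[2, 2] <- NA
    pas <- ProteinAbundanceSet(m, batch = c("b1", "b2"))
    expect_warning(rs <- selectReferenceProteins(pas), "no protein")
    centered <- suppressWarnings(
        log2MedianCenter(ProteinAbundanceSet(m, batch = c("b1", "b2"))))
    expect_warning(out <- interbatchCorrect(centered, rs), "empty")
    expect_equal(abundances(out), abundances(centered))
})

test_that("relative abundance maps equal a per-row median oracle with reproducible ranks", {
    set.seed(13)
    m <- matrix(stats::rlnorm(60, 8, 3), 10, 6)
    m[sample(60, 10)] <- NA
    rownames(m) <- sprintf("P%02d", 1:10)
    pas <- makeToyPas(m)
    map <- relativeAbundance(log2MedianCenter(pas))
    centered <- abundances(log2MedianCenter(pas))
    for (i in seq_len(nrow(map))) {
        p <- map$protein_id[i]
        expect_equal(map$median_abundance[i],
                     stats::median(centered[p, ], na.rm = TRUE))
        expect_equal(map$n_samples_detected[i], sum(!is.na(centered[p, ])))
    }
    expect_identical(sort(map$rank), seq_len(nrow(map)))
    # a protein detected once reports that single value
    one <- matrix(c(4, NA, NA, 8), 2, 2,
                  dimnames = list(c("x", "y"), c("s1", "s2")))
    pone <- ProteinAbundanceSet(log2(one), batch = c("b1", "b1"),
                                scale = "log2")
    mo <- relativeAbundance(pone)
    expect_equal(mo$median_abundance[mo$protein_id == "x"], 2)
    expect_equal(mo$n_samples_detected[mo$protein_id == "x"], 1L)
})

test_that("the normalization pipeline is invariant to sample order and re-selection keeps qualifiers", {
    sim <- simulateAbundance(simConfig(nProteins = 300, nBatches = 3,
                                       samplesPerBatch = 8,
                                       nReference = 10, seed = 42))
    res <- normalizeProteome(sim$matrix)
    # shuffle sample columns
    a <- abundances(sim$matrix)
    ord <- sample(ncol(a))
    shuffled <- ProteinAbundanceSet(a[, ord],
                                    batch = batchOf(sim$matrix)[ord])
    res2 <- normalizeProteome(shuffled)
    expect_equal(res2$map, res$map)
    expect_setequal(referenceIds(res2$refset), referenceIds(res$refset))
    # CV is computed on the original linear values, so re-selecting on the
    # uncorrected matrix after the pipeline returns the same qualifiers
    rs2 <- selectReferenceProteins(sim$matrix)
    expect_true(all(referenceIds(res$refset) %in% referenceIds(rs2)))
})

test_that("noise-free planted batch offsets are removed exactly by the pipeline", {
    base <- simConfig(nProteins = 150, nBatches = 4, samplesPerBatch = 5,
                      nReference = 10, noiseSdRange = c(0, 0),
                      refNoiseSd = 0, batchShiftSd = 0,
                      detectionMidpoint = -Inf,
                      enforcePlanted = FALSE, seed = 99)
    shifted <- base; shifted$batchShiftSd <- 2
    simFlat <- simulateAbundance(base)
    simShift <- simulateAbundance(shifted)
    expect_equal(simFlat$truth$batch_offsets,
                 simFlat$truth$batch_offsets * 0)
    nFlat <- normalizeProteome(simFlat$matrix, cvThreshold = 1e6)
    nShift <- normalizeProteome(simShift$matrix, cvThreshold = 1e6)
    expect_equal(abundances(nShift$normalized),
                 abundances(nFlat$normalized), tolerance = 1e-12)
})
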