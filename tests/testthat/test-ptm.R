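test_that("Class I filtering is inclusive at the threshold", {
    s <- data.frame(site = 1:4,
                    localization_prob = c(0.75, 0.749, 1.0, 0.2))
    out <- classifySites(s)
    expect_equal(out$site, c(1L, 3L))
    expect_equal(nrow(classifySites(s, threshold = 0)), 4L)
    set.seed(61)
    r <- data.frame(localization_prob = runif(500))
    expect_equal(nrow(classifySites(r, 0.6)),
                 sum(r$localization_prob >= 0.6))
    expect_error(classifySites(data.frame(localization_prob = 1.2)),
                 "0, 1")
})

test_that("multiplicity histogram bins mono/di/multi and sums to the input", {
    expect_equal(unname(multiplicityHistogram(c(1, 1, 2, 3, 4))),
                 c(2L, 1L, 2L))
    expect_equal(unname(multiplicityHistogram(integer())), c(0L, 0L, 0L))
    set.seed(62)
    m <- sample(1:6, 300, TRUE)
    h <- multiplicityHistogram(m)
    expect_equal(sum(h), 300L)
    expect_equal(unname(h["multi"]), sum(m >= 3))
})

test_that("site windows are centered, padded at termini, and match a slicing oracle", {
    seqv <- "ABCDEFGSIJKLMNOPQRST"
    w <- extractSiteWindow(seqv, 8)
    expect_equal(nchar(w), 15L)
    expect_equal(substr(w, 8, 8), "S")
    expect_equal(w, "ABCDEFGSIJKLMNO")
    expect_equal(extractSiteWindow("SABCDEFGH", 1),
                 "_______SABCDEFG")
    expect_error(extractSiteWindow(seqv, 2), "not S/T/Y")
    set.seed(63)
    prot <- randomProtein(100)
    sty <- which(strsplit(prot, "")[[1]] %in% c("S", "T", "Y"))
    for (p in sty) {
        win <- extractSiteWindow(prot, p)
        core <- gsub("_", "", win)
        expect_equal(core, substr(prot, max(1, p - 7), min(100, p + 7)))
        expect_equal(substr(win, 8, 8), substr(prot, p, p))
    }
})

test_that("motif enrichment recovers a planted motif at rank 1", {
    sim <- simulatePhospho(nPeptides = 2000, nBackground = 8000,
                           plantedFraction = 0.3, seed = 64)
    res <- enrichMotifs(sim$peptides$window, sim$background)
    expect_gt(nrow(res), 0)
    expect_equal(res$motif[1], "R-x-x-S#")
    # frequency-count oracle: every planted window carries the pattern
    w <- sim$peptides$window
    matches <- substring(w, 5, 5) == "R" & substring(w, 8, 8) == "S"
    expect_true(all(matches[sim$peptides$planted]))
    expect_gte(sum(matches), sum(sim$peptides$planted))
    expect_gte(res$n_foreground[1], 0.8 * sum(sim$peptides$planted))
    expect_error(enrichMotifs(sim$peptides$window,
                              sim$background[1:100]), "smaller")
    expect_equal(nrow(enrichMotifs(sim$peptides$window[1],
                                   sim$background)), 0L)
})

test_that("motif search controls false discoveries on motif-free foregrounds", {
    set.seed(65)
    false <- 0L
    for (rep in 1:100) {
        sim <- simulatePhospho(nPeptides = 6000, nBackground = 6000,
                               plantedFraction = 0, seed = 6500 + rep)
        fg <- sample(sim$background, 500)
        res <- enrichMotifs(fg, sim$background)
        false <- false + nrow(res)
    }
    expect_lte(false, 5L)
})

test_that("kinase prediction joins enriched motifs against the annotation table", {
    tab <- kinaseMotifTable()
    motifs <- data.frame(motif = c("R-x-x-S#", "S#-P"),
                         n_foreground = c(120L, 80L))
    pred <- predictKinases(motifs, tab)
    expect_true(all(c("PRKACA", "CAMK2A", "CDK1", "MAPK1") %in%
                    pred$kinase))
    expect_equal(pred$n_supporting[pred$kinase == "PRKACA"], 120L)
    expect_equal(nrow(predictKinases(motifs[0, ], tab)), 0L)
    planted <- data.frame(motif = c("A-x-S#", "S#-x-B"),
                          kinase = c("KIN1", "KIN2"))
    expect_error(predictKinases(motifs, planted), "bad motif token")
    ok <- data.frame(motif = "A-x-S#", kinase = "KIN1")
    got <- predictKinases(data.frame(motif = "A-x-S#",
                                     n_foreground = 7L), ok)
    expect_identical(got$kinase, "KIN1")
    expect_identical(got$n_supporting, 7L)
})

test_that("kinome union obeys inclusion-exclusion and warns on foreign ids", {
    kin <- paste0("K", 1:100)
    a <- paste0("K", 1:40); b <- paste0("K", 31:60)
    u <- kinomeUnion(a, b, kin)
    expect_equal(u$union_count, 60L)
    expect_equal(u$union_count,
                 length(a) + length(b) - length(intersect(a, b)))
    expect_equal(u$coverage_fraction, 60)
    expect_equal(kinomeUnion(paste0("K", 1:5), paste0("K", 6:8),
                             kin)$union_count, 8L)
    expect_equal(kinomeUnion(a, a[1:5], kin)$union_count, length(a))
    expect_warning(kinomeUnion(c(a, "XXX"), b, kin), "dropped")
    expect_error(kinomeUnion(a, b, character()), "empty kinome")
})

test_that("acetyl occupancy follows 100*L/(L+H) with scale invariance and NA for empty sites", {
    expect_equal(acetylOccupancy(0, 100), 0)
    expect_equal(acetylOccupancy(5, 5), 50)
    expect_equal(acetylOccupancy(1, 0), 100)
    expect_true(is.na(acetylOccupancy(0, 0)))
    set.seed(66)
    l <- runif(50); h <- runif(50)
    expect_equal(acetylOccupancy(l * 1e6, h * 1e6),
                 acetylOccupancy(l, h))
    expect_error(acetylOccupancy(-1, 2), "non-negative")
})

test_that("occupancy summaries are per sample and pooled groups ignore label permutation", {
    st <- data.frame(sample = "s1", occupancy = c(10, 20, 30))
    od <- occupancyDistribution(st)
    expect_equal(od$per_sample$median, 20)
    expect_equal(od$grand_median, 20)
    st2 <- data.frame(sample = rep(c("a", "b"), each = 4),
                      group = rep(c("g1", "g2"), each = 4),
                      occupancy = c(1, 2, 3, 4, 5, 6, 7, 8))
    od2 <- occupancyDistribution(st2)
    st2perm <- st2; st2perm$group <- rev(st2$group)
    pooled <- function(x) sort(x$per_sample$median)
    expect_equal(pooled(occupancyDistribution(st2perm)), pooled(od2))
})

test_that("set enrichment equals an exhaustive enumeration oracle on a toy universe", {
    bg <- paste0("p", 1:10)
    ann <- list(term = paste0("p", 1:5))
    target <- c("p1", "p2", "p3", "p7")
    res <- setEnrichment(target, ann, bg)
    q <- res$n_overlap
    # enumerate all possible targets of the same size drawn from bg
    combos <- utils::combn(10, length(target))
    overlaps <- apply(combos, 2, function(ix)
        length(intersect(bg[ix], ann$term)))
    expect_equal(res$p_raw, mean(overlaps >= q))
    expect_equal(q, 3L)
    # disjoint annotation: no enrichment signal
    res0 <- setEnrichment(target, list(t = c("zz")), bg)
    expect_equal(res0$p_raw, 1)
    expect_error(setEnrichment(c("p1", "nope"), ann, bg), "subset")
    # target = background: overlap is the full annotation
    resAll <- setEnrichment(bg, ann, bg)
    expect_equal(resAll$n_overlap, 5L)
    expect_equal(resAll$p_raw, 1)
})
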