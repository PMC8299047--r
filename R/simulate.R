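#' Simulation configuration for the synthetic cohort generators
#'
#' Bundles the parameters shared by the generators. Defaults describe the
#' cohort structure the analysis assumes: 2000 proteins over 5 batches of 20
#' samples, abundances spanning ~6 orders of magnitude, 45 planted
#' low-variability reference proteins, protein-transcript correlation 0.44,
#' and low acetylation occupancies (Beta(1, 9), mean 10%).
#'
#' @param nProteins,nBatches,samplesPerBatch,nReference cohort dimensions;
#'   all counts >= 1 except \code{nReference} which may be 0;
#'   \code{nReference <= nProteins}.
#' @param dynamicRangeLog10 spread of true abundances in log10 units
#'   (default 6).
#' @param batchShiftSd standard deviation of additive per-batch offsets in
#'   log2 units (default 0.5).
#' @param detectionMidpoint log2 abundance at which detection probability is
#'   50% (logistic missingness model); \code{-Inf} disables missingness.
#' @param detectionSlope logistic scale in log2 units (default 1.5).
#' @param refNoiseSd,noiseSdRange within-batch measurement noise sd (log2)
#'   for reference proteins, and the range from which each non-reference
#'   protein's noise sd is drawn.
#' @param rhoTranscript target protein-transcript Pearson correlation, in
#'   [-1, 1].
#' @param occupancyAlpha,occupancyBeta Beta parameters of true acetylation
#'   occupancies (> 0).
#' @param enforcePlanted keep the planted reference set exactly separable:
#'   re-draw a planted protein whose sampled per-batch CV strays above the
#'   60% criterion and knock one measurement out of any non-planted protein
#'   that would accidentally qualify (default TRUE; turn off for degenerate
#'   noise-free configurations).
#' @param seed master seed; all generators derive child seeds from it.
#' @return list of validated parameters (class \code{"simConfig"}).
#' @export
simConfig <- function(nProteins = 2000L, nBatches = 5L,
                      samplesPerBatch = 20L, nReference = 45L,
                      dynamicRangeLog10 = 6, batchShiftSd = 0.5,
                      detectionMidpoint = 6, detectionSlope = 1.5,
                      refNoiseSd = 0.35, noiseSdRange = c(0.8, 1.8),
                      rhoTranscript = 0.44,
                      occupancyAlpha = 1, occupancyBeta = 9,
                      enforcePlanted = TRUE, seed = 1L) {
    stopifnotScalarCount(nProteins, "nProteins")
    stopifnotScalarCount(nBatches, "nBatches")
    stopifnotScalarCount(samplesPerBatch, "samplesPerBatch")
    if (nReference < 0 || nReference > nProteins)
        stop("'nReference' must lie in [0, nProteins]")
    if (dynamicRangeLog10 <= 0)
        stop("'dynamicRangeLog10' must be positive")
    if (abs(rhoTranscript) > 1)
        stop("'rhoTranscript' must lie in [-1, 1]")
    if (occupancyAlpha <= 0 || occupancyBeta <= 0)
        stop("Beta occupancy parameters must be positive")
    cfg <- list(nProteins = as.integer(nProteins),
                nBatches = as.integer(nBatches),
                samplesPerBatch = as.integer(samplesPerBatch),
                nReference = as.integer(nReference),
                dynamicRangeLog10 = dynamicRangeLog10,
                batchShiftSd = batchShiftSd,
                detectionMidpoint = detectionMidpoint,
                detectionSlope = detectionSlope,
                refNoiseSd = refNoiseSd,
                noiseSdRange = noiseSdRange,
                rhoTranscript = rhoTranscript,
                occupancyAlpha = occupancyAlpha,
                occupancyBeta = occupancyBeta,
                enforcePlanted = isTRUE(enforcePlanted),
                seed = as.integer(seed))
    class(cfg) <- "simConfig"
    cfg
}

#' Simulate a multi-batch protein abundance matrix with planted references
#'
#' True abundances are log-uniform over \code{dynamicRangeLog10} orders of
#' magnitude. Measurements add a per-batch offset and per-protein noise in
#' log2 space; detection follows a logistic curve in true log2 abundance
#' (monotone: more abundant proteins are seen more often). A planted set of
#' \code{nReference} proteins is detected in every sample with per-batch
#' linear CV below 60%, and (under \code{enforcePlanted}) every other
#' protein violates at least one of the two criteria, so
#' [selectReferenceProteins()] recovers exactly the planted set.
#'
#' @param config a [simConfig()].
#' @return list with \code{matrix} (linear-scale
#'   [ProteinAbundanceSet-class]) and \code{truth} (list:
#'   \code{reference_ids}, \code{batch_offsets},
#'   \code{true_abundances_log2}, \code{noise_sd}).
#' @export
simulateAbundance <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    withSeed(childSeed(config$seed, 101L), {
        nP <- config$nProteins
        nS <- config$nBatches * config$samplesPerBatch
        ids <- sprintf("P%05d", seq_len(nP))
        batch <- factor(rep(sprintf("batch%02d", seq_len(config$nBatches)),
                            each = config$samplesPerBatch))
        trueLog2 <- stats::runif(nP, 0, config$dynamicRangeLog10) * log2(10)
        # housekeeping-like anchors live in the upper abundance range
        eligible <- which(trueLog2 >= stats::quantile(trueLog2, 0.5))
        refIdx <- if (config$nReference > 0)
            sort(sample(eligible, config$nReference)) else integer()
        offsets <- stats::rnorm(config$nBatches, 0, config$batchShiftSd)
        names(offsets) <- levels(batch)
        sdP <- stats::runif(nP, config$noiseSdRange[1],
                            config$noiseSdRange[2])
        sdP[refIdx] <- config$refNoiseSd
        noise <- matrix(stats::rnorm(nP * nS), nP, nS) * sdP
        la <- trueLog2 + noise + rep(offsets[as.integer(batch)],
                                     each = nP)
        detp <- stats::plogis((trueLog2 - config$detectionMidpoint) /
                              config$detectionSlope)
        det <- matrix(stats::runif(nP * nS), nP, nS) < detp
        det[refIdx, ] <- TRUE
        m <- 2^la
        m[!det] <- NA
        dimnames(m) <- list(ids, sprintf("S%03d", seq_len(nS)))
        if (config$enforcePlanted)
            m <- enforcePlantedSeparation(m, batch, refIdx, trueLog2,
                                          offsets, config)
        pas <- ProteinAbundanceSet(m, batch = batch, scale = "linear")
        list(matrix = pas,
             truth = list(reference_ids = ids[refIdx],
                          batch_offsets = offsets,
                          true_abundances_log2 = stats::setNames(trueLog2,
                                                                 ids),
                          noise_sd = stats::setNames(sdP, ids)))
    })
}

# Guarantee that planted reference proteins qualify (CV < 60% in every
# batch) and that no other protein does. Re-draws noisy planted rows;
# knocks one measurement out of accidental qualifiers.
enforcePlantedSeparation <- function(m, batch, refIdx, trueLog2, offsets,
                                     config) {
    qualifies <- function(v) {
        if (anyNA(v)) return(FALSE)
        for (b in levels(batch)) {
            x <- v[batch == b]
            if (100 * stats::sd(x) / mean(x) >= 60) return(FALSE)
        }
        TRUE
    }
    nS <- length(batch)
    for (i in refIdx) {
        tries <- 0L
        sd_i <- config$refNoiseSd
        while (!qualifies(m[i, ]) && tries < 100L) {
            tries <- tries + 1L
            if (tries %% 20L == 0L) sd_i <- sd_i * 0.7
            m[i, ] <- 2^(trueLog2[i] + stats::rnorm(nS, 0, sd_i) +
                         offsets[as.integer(batch)])
        }
    }
    nonref <- setdiff(seq_len(nrow(m)), refIdx)
    for (i in nonref) {
        if (qualifies(m[i, ]))
            m[i, sample.int(nS, 1L)] <- NA
    }
    m
}

#' Simulate a transcript table paired to a protein abundance matrix
#'
#' Gene-matched transcript intensities whose log2 medians correlate with the
#' protein relative abundances at a tunable Pearson \code{rho} (bivariate
#' construction: the transcript latent is \code{rho * z + sqrt(1 - rho^2) *
#' e} against the standardized protein medians \code{z}). A configurable
#' fraction of transcript-only genes is appended and of protein-only genes
#' withheld.
#'
#' @param proteins a [ProteinAbundanceSet-class], or a named numeric vector
#'   of per-gene protein medians (log2).
#' @param rho target Pearson correlation in [-1, 1].
#' @param nSamples transcript samples to simulate (default 100).
#' @param fracTranscriptOnly fraction of the transcript table without a
#'   protein counterpart (default 0.27).
#' @param fracProteinOnly fraction of protein genes withheld from the
#'   transcript table (default 0.03).
#' @param sampleNoiseSd per-sample log2 noise around a gene's transcript
#'   level (default 0.5).
#' @param seed integer seed.
#' @return list with \code{table} (\code{data.frame}: \code{transcript_id},
#'   \code{gene}, per-sample intensity columns), \code{detected_fraction}
#'   (named vector: fraction of samples with >= 10 simulated reads) and
#'   \code{truth} (latent transcript log2 levels, rho).
#' @export
simulateTranscripts <- function(proteins, rho, nSamples = 100L,
                                fracTranscriptOnly = 0.27,
                                fracProteinOnly = 0.03,
                                sampleNoiseSd = 0.5, seed = 1L) {
    if (abs(rho) > 1)
        stop("'rho' must lie in [-1, 1]")
    med <- if (methods::is(proteins, "ProteinAbundanceSet"))
        apply(log2(abundances(proteins)), 1L, stats::median, na.rm = TRUE)
    else proteins
    stopifnot(!is.null(names(med)))
    withSeed(childSeed(seed, 211L), {
        keep <- sort(sample(names(med),
                            round((1 - fracProteinOnly) * length(med))))
        z <- med[keep]
        z <- (z - mean(z)) / stats::sd(z)
        nShared <- length(z)
        latentShared <- rho * z +
            sqrt(max(0, 1 - rho^2)) * stats::rnorm(nShared)
        nOnly <- round(fracTranscriptOnly * length(med))
        latentOnly <- stats::rnorm(nOnly)
        genes <- c(names(z), sprintf("TRONLY%05d", seq_len(nOnly)))
        latent <- c(latentShared, latentOnly)
        level <- 8 + 2 * latent          # log2 intensity scale
        vals <- matrix(2^(level + stats::rnorm(length(level) * nSamples,
                                               0, sampleNoiseSd)),
                       nrow = length(level))
        colnames(vals) <- sprintf("R%03d", seq_len(nSamples))
        detected <- rowMeans(vals >= 10)
        tab <- data.frame(transcript_id = paste0("T_", genes),
                          gene = genes, vals, check.names = FALSE)
        list(table = tab,
             detected_fraction = stats::setNames(detected, genes),
             truth = list(rho = rho,
                          latent_log2 = stats::setNames(level, genes)))
    })
}

#' Simulate an acetylome of light/heavy intensity pairs
#'
#' Per site, a true occupancy \eqn{\theta} is drawn from
#' Beta(\code{occupancyAlpha}, \code{occupancyBeta}); the endogenous (light)
#' and chemically labeled (heavy) channel intensities are
#' \eqn{\theta I \epsilon} and \eqn{(1-\theta) I \epsilon'} with a
#' log-normal site intensity \eqn{I} and multiplicative channel noise.
#' Samples carry origin groups (primary / lymph node / other metastasis in
#' 16:23:21 proportions) and 200-2000 sites each.
#'
#' @param config a [simConfig()]; uses \code{occupancyAlpha},
#'   \code{occupancyBeta}, \code{seed}.
#' @param nSamples number of samples (default 60).
#' @param sitesRange min/max sites per sample (default c(200, 2000)).
#' @param noiseSd sdlog of the multiplicative channel noise (default 0.2;
#'   0 = noiseless, occupancies recoverable exactly).
#' @return list with \code{sites} (\code{data.frame}: \code{sample},
#'   \code{group}, \code{protein_id}, \code{lysine_position}, \code{light},
#'   \code{heavy}) and \code{truth} (vector of true occupancies, as
#'   fractions, aligned to rows).
#' @export
simulateAcetylome <- function(config, nSamples = 60L,
                              sitesRange = c(200L, 2000L), noiseSd = 0.2) {
    stopifnot(inherits(config, "simConfig"))
    withSeed(childSeed(config$seed, 307L), {
        props <- c(primary = 16, lymph_node = 23, other_metastasis = 21)
        counts <- round(props / sum(props) * nSamples)
        while (sum(counts) < nSamples) counts[1] <- counts[1] + 1
        while (sum(counts) > nSamples) counts[which.max(counts)] <-
            counts[which.max(counts)] - 1
        grp <- rep(names(counts), counts)
        rows <- vector("list", nSamples)
        for (s in seq_len(nSamples)) {
            n <- sample(sitesRange[1]:sitesRange[2], 1L)
            theta <- stats::rbeta(n, config$occupancyAlpha,
                                  config$occupancyBeta)
            intensity <- 10^stats::runif(n, 3, 7)
            e1 <- if (noiseSd > 0) stats::rlnorm(n, 0, noiseSd) else 1
            e2 <- if (noiseSd > 0) stats::rlnorm(n, 0, noiseSd) else 1
            rows[[s]] <- data.frame(
                sample = sprintf("A%02d", s), group = grp[s],
                protein_id = sprintf("AC%05d", sample.int(5000L, n,
                                                          replace = TRUE)),
                lysine_position = sample.int(800L, n, replace = TRUE),
                light = theta * intensity * e1,
                heavy = (1 - theta) * intensity * e2,
                true_occupancy = theta)
        }
        tab <- do.call(rbind, rows)
        truth <- tab$true_occupancy
        tab$true_occupancy <- NULL
        list(sites = tab, truth = truth)
    })
}

#' Simulate phosphosite windows with a planted motif
#'
#' Foreground site windows (width 15, center S/T/Y) are drawn with uniform
#' residue usage; a planted fraction carries a fixed motif (default
#' \code{"R-x-x-S#"}: arginine three positions upstream of a phospho-serine).
#' A larger motif-free background set is returned for [enrichMotifs()].
#' Localization probabilities and multiplicities emulate a search-engine
#' site table.
#'
#' @param nPeptides foreground peptides (default 5000).
#' @param nBackground background windows (default 20000).
#' @param plantedMotif motif pattern (syntax of [enrichMotifs()] output).
#' @param plantedFraction fraction of foreground carrying it (default 0.3).
#' @param seed integer seed.
#' @return list with \code{peptides} (\code{data.frame}: \code{window},
#'   \code{protein_id}, \code{position}, \code{localization_prob},
#'   \code{multiplicity}, \code{planted}), \code{background} (character
#'   windows), \code{truth} (motif, fraction).
#' @export
simulatePhospho <- function(nPeptides = 5000L, nBackground = 20000L,
                            plantedMotif = "R-x-x-S#",
                            plantedFraction = 0.3, seed = 1L) {
    parsed <- parseMotif(plantedMotif)
    withSeed(childSeed(seed, 401L), {
        mkWindows <- function(n) {
            w <- matrix(sample(AA20, 15L * n, replace = TRUE), n, 15L)
            w[, 8L] <- sample(c("S", "T", "Y"), n, replace = TRUE,
                              prob = c(0.6, 0.3, 0.1))
            w
        }
        fg <- mkWindows(nPeptides)
        planted <- stats::runif(nPeptides) < plantedFraction
        fg[planted, 8L] <- parsed$center
        for (i in seq_along(parsed$offsets))
            fg[planted, 8L + parsed$offsets[i]] <- parsed$residues[i]
        bg <- mkWindows(nBackground)
        fgw <- apply(fg, 1L, paste, collapse = "")
        bgw <- apply(bg, 1L, paste, collapse = "")
        peptides <- data.frame(
            window = fgw,
            protein_id = sprintf("PH%05d", sample.int(3000L, nPeptides,
                                                      replace = TRUE)),
            position = sample.int(1000L, nPeptides, replace = TRUE),
            localization_prob = stats::rbeta(nPeptides, 5, 1),
            multiplicity = sample(1:4, nPeptides, replace = TRUE,
                                  prob = c(0.6, 0.25, 0.1, 0.05)),
            planted = planted)
        list(peptides = peptides, background = bgw,
             truth = list(motif = plantedMotif,
                          fraction = plantedFraction))
    })
}

#' Simulate a peptide-level quantification table
#'
#' Label-free (peptide areas) or TMT (reporter intensities per channel)
#' peptide records with unique/razor flags, for the roll-up functions.
#'
#' @param nProteins proteins (default 50).
#' @param maxPeptides maximum peptides per protein (1 to this, uniform).
#' @param nChannels 0 for label-free areas, otherwise the number of TMT
#'   reporter channels.
#' @param seed integer seed.
#' @return \code{data.frame} of peptide records.
#' @export
simulatePeptideTable <- function(nProteins = 50L, maxPeptides = 8L,
                                 nChannels = 0L, seed = 1L) {
    withSeed(childSeed(seed, 503L), {
        rows <- lapply(seq_len(nProteins), function(i) {
            n <- sample.int(maxPeptides, 1L)
            d <- data.frame(
                protein_id = sprintf("Q%04d", i),
                sequence = vapply(seq_len(n), function(j)
                    paste(c(sample(AA20, 8L + sample.int(10L, 1L),
                                   replace = TRUE), "K"), collapse = ""),
                    character(1)),
                is_unique = stats::runif(n) < 0.8)
            d$is_razor <- !d$is_unique & stats::runif(n) < 0.5
            if (nChannels == 0L) {
                d$area <- stats::rlnorm(n, 12, 1.5)
            } else {
                for (ch in seq_len(nChannels))
                    d[[sprintf("channel_%02d", ch)]] <-
                        stats::rlnorm(n, 10, 1)
            }
            d
        })
        do.call(rbind, rows)
    })
}

#' Simulate plasma spectral counts with planted blood-origin proteins
#'
#' A plasma proteome with spectral counts and protein lengths, tissue
#' proteome/transcriptome gene sets constructed so that exactly
#' \code{nBlood} plasma proteins lack tissue transcript evidence, and
#' per-tissue-sample identification sets in which blood-origin proteins
#' appear at low frequency.
#'
#' @param nProteins plasma proteins (default 1000).
#' @param nBlood planted blood-origin proteins (default 112).
#' @param nTissueSamples tissue samples (default 50).
#' @param seed integer seed.
#' @return list with \code{counts} (\code{data.frame}: \code{protein_id},
#'   \code{spectral_count}, \code{length}), \code{tissue_protein_genes},
#'   \code{tissue_transcript_genes}, \code{per_sample} (named list of
#'   identified-protein sets) and \code{truth} (\code{blood_ids}).
#' @export
simulatePlasmaCounts <- function(nProteins = 1000L, nBlood = 112L,
                                 nTissueSamples = 50L, seed = 1L) {
    if (nBlood > nProteins)
        stop("'nBlood' cannot exceed 'nProteins'")
    withSeed(childSeed(seed, 601L), {
        ids <- sprintf("PL%04d", seq_len(nProteins))
        blood <- sort(sample(ids, nBlood))
        nonblood <- setdiff(ids, blood)
        counts <- data.frame(
            protein_id = ids,
            spectral_count = stats::rnbinom(nProteins, mu = 20,
                                            size = 0.8) + 1L,
            length = sample(100:3000, nProteins, replace = TRUE))
        tissueExtra <- sprintf("TIS%04d", seq_len(3000L))
        tissueTranscript <- c(nonblood, tissueExtra)
        tissueProtein <- c(ids, sample(tissueExtra, 2000L))
        universe <- c(nonblood, tissueExtra)
        coreSize <- min(2000L, length(universe))
        perSample <- lapply(seq_len(nTissueSamples), function(s) {
            core <- sample(universe, coreSize)
            nb <- sample.int(min(20L, length(blood)), 1L)
            unique(c(core, sample(blood, nb)))
        })
        names(perSample) <- sprintf("TS%03d", seq_len(nTissueSamples))
        list(counts = counts,
             tissue_protein_genes = tissueProtein,
             tissue_transcript_genes = tissueTranscript,
             per_sample = perSample,
             truth = list(blood_ids = blood))
    })
}

#' Driver-mutation panel (gene, position, wild-type and mutant residue)
#'
#' The eight recurrent melanoma driver substitutions across six genes used
#' throughout the examples: BRAF V600E, NRAS Q61K/Q61R/G12A, KRAS G13D,
#' KIT N566D, CDKN2A P114L (p16-INK4a) and GNA11 N266K.
#'
#' @return \code{data.frame} with columns \code{gene}, \code{label},
#'   \code{position}, \code{wt}, \code{mut}.
#' @export
driverMutationPanel <- function() {
    data.frame(
        gene = c("BRAF", "NRAS", "NRAS", "NRAS", "KRAS", "KIT",
                 "CDKN2A", "GNA11"),
        label = c("V600E", "Q61K", "Q61R", "G12A", "G13D", "N566D",
                  "P114L", "N266K"),
        position = c(600L, 61L, 61L, 12L, 13L, 566L, 114L, 266L),
        wt = c("V", "Q", "Q", "G", "G", "N", "P", "N"),
        mut = c("E", "K", "R", "A", "D", "D", "L", "K"))
}

#' Toy proteome embedding the driver-mutation sequence contexts
#'
#' Wild-type protein sequences for the six driver-mutation genes, built so
#' that each mutation of [driverMutationPanel()] sits at its nomenclature
#' position within its native tryptic context (e.g. NRAS Gln61 inside the
#' wild-type peptide QVVIDGETCLLDILDTAGQEEYSAMR), padded to length with
#' inert filler repeats, plus optional random filler proteins for
#' uniqueness checks.
#'
#' @param nFiller extra random proteins (default 4).
#' @param fillerLength their length (default 300).
#' @param seed seed for the random filler proteins.
#' @return named character vector of protein sequences (names = gene
#'   symbols / FILLERn).
#' @export
simulateProteome <- function(nFiller = 4L, fillerLength = 300L, seed = 1L) {
    nras <- paste0("MTEYKLVVVGAGGVGKSALTIQLIQNHFVDEYDPTIEDSYRK",
                   "QVVIDGETCLLDILDTAGQEEYSAMR",
                   "DQYMRTGEGFLCVFAINNTKSFEDIHQYR")
    kras <- paste0("MTEYKLVVVGAGGVGKSALTIQLIQNHFVDEYDPTIEDSYR",
                   "EQDSEKGNSSNDGTQGFLK")
    braf <- paste0(strrep("ASNDGSQTER", 58), "SGSHLER", "LTVK",
                   "IGDFGLATVK", "SRWSGSHQFEQLSGSILWMAPEVIR")
    kit <- paste0(strrep("ADQSGLNTER", 55), "GSDTHAQK",
                  "VVEEINGNNYVYIDPTQLPYDHK", "WMAPESLR")
    cdkn2a <- paste0(strrep("ASGDQNLHER", 11), "GR",
                     "LPVDLAEELGHR", "DVARYLR")
    gna11 <- paste0(strrep("GADSQNLHER", 26), "EYNLVN",
                    "SSVILFLNK", "EDVTQR")
    prot <- c(BRAF = braf, NRAS = nras, KRAS = kras, KIT = kit,
              CDKN2A = cdkn2a, GNA11 = gna11)
    panel <- driverMutationPanel()
    for (i in seq_len(nrow(panel))) {   # construction self-check
        found <- substring(prot[[panel$gene[i]]], panel$position[i],
                           panel$position[i])
        if (found != panel$wt[i])
            stop("internal error: context mismatch for ", panel$gene[i],
                 " ", panel$label[i])
    }
    if (nFiller > 0) {
        fill <- withSeed(childSeed(seed, 701L),
            vapply(seq_len(nFiller), function(i)
                paste(sample(AA20, fillerLength, replace = TRUE),
                      collapse = ""), character(1)))
        names(fill) <- sprintf("FILLER%d", seq_len(nFiller))
        prot <- c(prot, fill)
    }
    prot
}
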