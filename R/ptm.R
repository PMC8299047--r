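#' Class I phosphosite filter
#'
#' Keeps sites whose localization probability is at or above the threshold
#' (inclusive; default 0.75, the conventional Class I cutoff).
#'
#' @param sites \code{data.frame} with a \code{localization_prob} column in
#'   [0, 1].
#' @param threshold inclusive probability cutoff (default 0.75).
#' @return The filtered \code{data.frame}.
#' @export
classifySites <- function(sites, threshold = 0.75) {
    stopifnot(is.data.frame(sites), "localization_prob" %in% names(sites))
    p <- sites$localization_prob
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("localization probabilities must lie in [0, 1]")
    sites[!is.na(p) & p >= threshold, , drop = FALSE]
}

#' Phosphopeptide multiplicity histogram
#'
#' Bins peptides as mono- (1), di- (2) and multi- (>= 3) phosphorylated.
#'
#' @param multiplicities integer vector of phospho-residue counts per
#'   peptide, or a \code{data.frame} with a \code{multiplicity} column.
#' @return named integer vector \code{c(mono, di, multi)}.
#' @export
multiplicityHistogram <- function(multiplicities) {
    if (is.data.frame(multiplicities))
        multiplicities <- multiplicities$multiplicity
    if (any(multiplicities < 1, na.rm = TRUE))
        stop("multiplicities must be >= 1")
    m <- multiplicities[!is.na(multiplicities)]
    c(mono = sum(m == 1L), di = sum(m == 2L), multi = sum(m >= 3L))
}

#' Fixed-width sequence window around a phosphosite
#'
#' Extracts the site residue with 7 neighbors on each side (width 15 by
#' default); positions beyond the protein termini are filled with the pad
#' character so every window has uniform length with the site at the center.
#'
#' @param sequence protein sequence string.
#' @param position 1-based index of the site; the residue there must be S, T
#'   or Y.
#' @param width odd window width (default 15).
#' @param pad single pad character (default \code{"_"}).
#' @return The window string of length \code{width}.
#' @examples
#' extractSiteWindow("MASSPYLLKRSTAQWS", 4)
#' @export
extractSiteWindow <- function(sequence, position, width = 15L, pad = "_") {
    sequence <- as.character(sequence)
    if (width %% 2L != 1L)
        stop("'width' must be odd")
    n <- nchar(sequence)
    if (position < 1L || position > n)
        stop("position outside sequence")
    center <- substring(sequence, position, position)
    if (!center %in% c("S", "T", "Y"))
        stop("residue at position ", position, " is '", center,
             "', not S/T/Y")
    flank <- (width - 1L) %/% 2L
    lo <- position - flank; hi <- position + flank
    core <- substring(sequence, max(1L, lo), min(n, hi))
    paste0(strrep(pad, max(0L, 1L - lo)), core,
           strrep(pad, max(0L, hi - n)))
}

# Parse a motif pattern like "R-x-x-S#" into (offsets relative to center,
# residues, center residue). Errors on malformed syntax.
parseMotif <- function(pattern) {
    toks <- strsplit(pattern, "-", fixed = TRUE)[[1]]
    centerIdx <- grep("#$", toks)
    if (length(centerIdx) != 1L)
        stop("motif '", pattern, "' must have exactly one '#' center token")
    centerRes <- sub("#$", "", toks[centerIdx])
    if (!centerRes %in% c("S", "T", "Y"))
        stop("motif center must be S, T or Y")
    fixed <- list()
    for (i in seq_along(toks)) {
        if (i == centerIdx) next
        tk <- toks[i]
        if (tk == "x") next
        if (!tk %in% AA20)
            stop("bad motif token '", tk, "' in '", pattern, "'")
        fixed[[length(fixed) + 1L]] <- c(offset = i - centerIdx, residue = tk)
    }
    list(center = centerRes,
         offsets = vapply(fixed, function(z) as.integer(z[["offset"]]),
                          integer(1)),
         residues = vapply(fixed, function(z) z[["residue"]], character(1)))
}

# Logical: which windows (15-char, center index 8) match a parsed motif.
matchMotif <- function(windows, parsed, center = 8L) {
    ok <- substring(windows, center, center) == parsed$center
    for (i in seq_along(parsed$offsets)) {
        p <- center + parsed$offsets[i]
        ok <- ok & substring(windows, p, p) == parsed$residues[i]
    }
    ok
}

#' Iterative motif enrichment on phosphosite windows (motif-x style)
#'
#' Greedy motif extraction: at each step the (position, residue) pair with
#' the smallest binomial tail probability of its foreground count, given the
#' current background frequency, is fixed; both window sets are filtered to
#' windows carrying it, and the step repeats until no pair reaches both the
#' p-value cutoff and the minimum occurrence count. The completed motif's
#' matching windows are removed from the foreground and the search restarts
#' for further motifs. The search is run separately for each central residue
#' (S, T, Y) and is fully deterministic: ties are broken by position index,
#' then residue alphabetically.
#'
#' @param foreground,background character vectors of equal-width site
#'   windows (see [extractSiteWindow()]); the background must be at least as
#'   large as the foreground.
#' @param pCutoff binomial tail cutoff per fixed position (default 1e-6).
#' @param minOccurrences minimum foreground windows carrying the motif
#'   (default 20).
#' @param maxDepth maximum fixed positions per motif (default 5).
#' @return \code{data.frame} with columns \code{motif} (pattern such as
#'   \code{"R-x-x-S#"}), \code{n_foreground}, \code{fold_enrichment},
#'   \code{p_cumulative} (product of stage tail probabilities; may
#'   underflow, see \code{neg_log10_p}) and \code{neg_log10_p}, ordered by
#'   decreasing foreground support.
#' @export
enrichMotifs <- function(foreground, background, pCutoff = 1e-6,
                         minOccurrences = 20L, maxDepth = 5L) {
    if (!length(foreground))
        stop("empty foreground")
    if (length(background) < length(foreground))
        stop("background smaller than foreground")
    w <- unique(nchar(c(foreground, background)))
    if (length(w) != 1L)
        stop("all windows must share one width")
    center <- (w + 1L) %/% 2L
    out <- list()
    for (cr in c("S", "T", "Y")) {
        fg <- foreground[substring(foreground, center, center) == cr]
        bgAll <- background[substring(background, center, center) == cr]
        if (!length(fg) || !length(bgAll)) next
        repeat {
            found <- extractOneMotif(fg, bgAll, cr, center, w, pCutoff,
                                     minOccurrences, maxDepth)
            if (is.null(found)) break
            out[[length(out) + 1L]] <- found$row
            fg <- fg[!found$fgMatch]
            if (length(fg) < minOccurrences) break
        }
    }
    if (!length(out))
        return(data.frame(motif = character(), n_foreground = integer(),
                          fold_enrichment = numeric(),
                          p_cumulative = numeric(),
                          neg_log10_p = numeric()))
    res <- do.call(rbind, out)
    res <- res[order(-res$n_foreground, -res$neg_log10_p), ]
    rownames(res) <- NULL
    res
}

# One greedy motif extraction pass; returns NULL when nothing significant.
extractOneMotif <- function(fg, bg, centerRes, center, width, pCutoff,
                            minOcc, maxDepth) {
    fg0 <- fg; bg0 <- bg
    fixedPos <- integer(); fixedRes <- character()
    logP <- 0
    positions <- setdiff(seq_len(width), center)
    repeat {
        if (length(fixedPos) >= maxDepth || length(fg) < minOcc) break
        best <- NULL
        logCut <- log(pCutoff)
        for (p in positions) {
            if (p %in% fixedPos) next
            fgRes <- substring(fg, p, p)
            bgRes <- substring(bg, p, p)
            for (r in AA20) {
                k <- sum(fgRes == r)
                if (k < minOcc) next
                p0 <- sum(bgRes == r) / length(bgRes)
                if (p0 <= 0 || p0 >= 1) next
                lpv <- stats::pbinom(k - 1L, length(fg), p0,
                                     lower.tail = FALSE, log.p = TRUE)
                if (lpv > logCut) next
                if (is.null(best) || lpv < best$lpv ||
                    (lpv == best$lpv && (p < best$p ||
                                         (p == best$p && r < best$r))))
                    best <- list(p = p, r = r, lpv = lpv)
            }
        }
        if (is.null(best)) break
        fixedPos <- c(fixedPos, best$p)
        fixedRes <- c(fixedRes, best$r)
        logP <- logP + best$lpv
        keepF <- substring(fg, best$p, best$p) == best$r
        keepB <- substring(bg, best$p, best$p) == best$r
        fg <- fg[keepF]; bg <- bg[keepB]
    }
    if (!length(fixedPos)) return(NULL)
    pattern <- buildMotifPattern(fixedPos, fixedRes, centerRes, center)
    parsed <- parseMotif(pattern)
    fgMatch <- matchMotif(fg0, parsed, center)
    bgFrac <- mean(matchMotif(bg0, parsed, center))
    fold <- if (bgFrac > 0) (sum(fgMatch) / length(fg0)) / bgFrac else Inf
    row <- data.frame(motif = pattern, n_foreground = sum(fgMatch),
                      fold_enrichment = fold, p_cumulative = exp(logP),
                      neg_log10_p = -logP / log(10))
    list(row = row, fgMatch = fgMatch)
}

buildMotifPattern <- function(fixedPos, fixedRes, centerRes, center) {
    span <- sort(unique(c(fixedPos, center)))
    lo <- min(span); hi <- max(span)
    toks <- character()
    for (p in lo:hi) {
        toks <- c(toks, if (p == center) paste0(centerRes, "#")
                  else if (p %in% fixedPos) fixedRes[match(p, fixedPos)]
                  else "x")
    }
    paste(toks, collapse = "-")
}

#' Kinase prediction from enriched motifs
#'
#' Looks enriched motif patterns up in a motif-to-kinase annotation table
#' and aggregates the supporting foreground window counts per kinase.
#'
#' @param motifs result of [enrichMotifs()] (or a \code{data.frame} with
#'   \code{motif} and \code{n_foreground} columns).
#' @param kinaseMotifTable \code{data.frame} with columns \code{motif} and
#'   \code{kinase}; see \code{system.file("extdata",
#'   "kinase_motifs_synthetic.tsv", package = "proteoMap")} for the packaged
#'   example table. All motif patterns are syntax-checked.
#' @return \code{data.frame} with columns \code{kinase}, \code{n_motifs},
#'   \code{n_supporting}, sorted by decreasing support.
#' @export
predictKinases <- function(motifs, kinaseMotifTable) {
    stopifnot(all(c("motif", "kinase") %in% names(kinaseMotifTable)))
    for (m in unique(c(motifs$motif, kinaseMotifTable$motif)))
        parseMotif(m)   # errors on bad syntax
    hit <- merge(motifs, kinaseMotifTable, by = "motif")
    if (!nrow(hit))
        return(data.frame(kinase = character(), n_motifs = integer(),
                          n_supporting = integer()))
    agg <- do.call(rbind, lapply(split(hit, hit$kinase), function(d)
        data.frame(kinase = d$kinase[1], n_motifs = nrow(d),
                   n_supporting = sum(d$n_foreground))))
    agg <- agg[order(-agg$n_supporting, agg$kinase), ]
    rownames(agg) <- NULL
    agg
}

#' Kinome coverage from identified and predicted kinases
#'
#' @param identified kinases observed directly in the proteome.
#' @param predicted kinases inferred from substrate motifs.
#' @param kinome the reference human kinome; members of the other two sets
#'   outside it are dropped with a warning.
#' @return list with \code{identified}, \code{predicted} (as given, within
#'   the kinome), \code{union_count}, \code{coverage_fraction} (percent of
#'   the kinome).
#' @export
kinomeUnion <- function(identified, predicted, kinome) {
    kinome <- unique(kinome)
    if (!length(kinome))
        stop("empty kinome")
    identified <- unique(identified); predicted <- unique(predicted)
    outI <- setdiff(identified, kinome); outP <- setdiff(predicted, kinome)
    if (length(outI) || length(outP))
        warning(length(outI) + length(outP),
                " kinase id(s) outside the reference kinome were dropped")
    identified <- intersect(identified, kinome)
    predicted <- intersect(predicted, kinome)
    u <- union(identified, predicted)
    list(identified = identified, predicted = predicted,
         union_count = length(u),
         coverage_fraction = 100 * length(u) / length(kinome))
}

#' Acetylation-site occupancy from light/heavy intensities
#'
#' Endogenous acetylation carries the light label; chemical acetylation of
#' previously unmodified lysines carries the heavy label. Site occupancy
#' (stoichiometry) is therefore \code{100 * light / (light + heavy)}
#' percent. Sites with both intensities zero have undefined occupancy
#' (\code{NA}).
#'
#' @param light,heavy non-negative intensity vectors of equal length.
#' @return numeric vector of occupancies in [0, 100] (percent), \code{NA}
#'   where undefined.
#' @examples
#' acetylOccupancy(c(0, 5, 1), c(100, 5, 0))  # 0, 50, 100
#' @export
acetylOccupancy <- function(light, heavy) {
    if (length(light) != length(heavy))
        stop("'light' and 'heavy' must have equal length")
    if (any(light < 0, na.rm = TRUE) || any(heavy < 0, na.rm = TRUE))
        stop("intensities must be non-negative")
    tot <- light + heavy
    ifelse(!is.na(tot) & tot > 0, 100 * light / tot, NA_real_)
}

#' Per-sample summaries of acetylation occupancy
#'
#' @param sites \code{data.frame} with columns \code{sample}, and either
#'   \code{occupancy} (percent) or \code{light}/\code{heavy} intensities;
#'   an optional \code{group} column (e.g. primary / lymph node / other
#'   metastasis) enables per-group pooled summaries.
#' @return list with \code{per_sample} (sample, group, n, n_undefined,
#'   median, q1, q3), \code{per_group} (or \code{NULL}), and
#'   \code{grand_median}: the median over per-sample median occupancies.
#' @export
occupancyDistribution <- function(sites) {
    stopifnot(is.data.frame(sites), "sample" %in% names(sites))
    if (!"occupancy" %in% names(sites)) {
        if (!all(c("light", "heavy") %in% names(sites)))
            stop("need 'occupancy' or 'light'+'heavy' columns")
        sites$occupancy <- acetylOccupancy(sites$light, sites$heavy)
    }
    hasGroup <- "group" %in% names(sites)
    per <- do.call(rbind, lapply(split(sites, sites$sample), function(d) {
        occ <- d$occupancy
        def <- occ[!is.na(occ)]
        if (!length(def))
            stop("sample '", d$sample[1], "' has no defined occupancy")
        q <- stats::quantile(def, c(0.25, 0.5, 0.75), names = FALSE)
        data.frame(sample = d$sample[1],
                   group = if (hasGroup) as.character(d$group[1])
                           else NA_character_,
                   n = length(def), n_undefined = sum(is.na(occ)),
                   median = q[2], q1 = q[1], q3 = q[3])
    }))
    rownames(per) <- NULL
    perGroup <- NULL
    if (hasGroup) {
        perGroup <- do.call(rbind, lapply(split(sites, sites$group),
            function(d) {
                def <- d$occupancy[!is.na(d$occupancy)]
                data.frame(group = as.character(d$group[1]),
                           n_sites = length(def),
                           median = stats::median(def))
            }))
        rownames(perGroup) <- NULL
    }
    list(per_sample = per, per_group = perGroup,
         grand_median = stats::median(per$median))
}

#' Hypergeometric over-representation of annotation terms
#'
#' For each term, tests whether the target protein set is enriched for the
#' term's members relative to the background universe (upper-tail
#' hypergeometric), with Benjamini-Hochberg adjustment across terms.
#'
#' @param target character vector of proteins of interest; must be a subset
#'   of \code{background}.
#' @param annotations named list of character vectors (term -> members).
#' @param background the protein universe.
#' @return \code{data.frame} with columns \code{term}, \code{n_members}
#'   (term members in the background), \code{n_overlap} (in the target),
#'   \code{p_raw}, \code{p_adjusted}, ordered by \code{p_raw}.
#' @export
setEnrichment <- function(target, annotations, background) {
    target <- unique(target); background <- unique(background)
    if (length(setdiff(target, background)))
        stop("'target' must be a subset of 'background'")
    N <- length(background); k <- length(target)
    rows <- lapply(names(annotations), function(term) {
        members <- intersect(annotations[[term]], background)
        m <- length(members)
        q <- length(intersect(members, target))
        p <- stats::phyper(q - 1L, m, N - m, k, lower.tail = FALSE)
        data.frame(term = term, n_members = m, n_overlap = q, p_raw = p)
    })
    out <- do.call(rbind, rows)
    out$p_adjusted <- stats::p.adjust(out$p_raw, method = "BH")
    out <- out[order(out$p_raw), ]
    rownames(out) <- NULL
    out
}
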