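---
title: "Mapping a tumor proteome: models, parameters, and design choices"
author: "proteoMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a tumor proteome: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoMap)
```

# The problem

Deep proteomic surveys of tumor cohorts (here: cutaneous melanoma, hundreds
of primary tumors and metastases) are acquired in many batches over years,
on mixed label-free and isobaric (TMT) workflows. Turning the raw
quantifications into a single *relative abundance map* — every detected
proteoform ranked by its typical abundance across the cohort — requires
peptide-to-protein roll-up, normalization that is robust to batch effects,
and bookkeeping layers for proteogenomics (mutation-bearing peptides),
transcriptome integration, post-translational modifications, and plasma
profiling. proteoMap implements each stage as a small, testable function,
and ships a seeded generator that emulates the statistical structure of
such a cohort so the whole pipeline can be exercised without any external
download.

# Protein quantification

Label-free protein abundance uses the TOP3 rule: the mean of the three
largest peptide areas among the protein's unique and razor peptides
(`top3Rollup()`). When fewer than three eligible peptides exist we take the
mean of what is available — the convention is not universal, and this
choice keeps single-peptide proteins quantifiable rather than dropping
them. Ties at the top-3 boundary are harmless: the mean does not depend on
which tied record is chosen. TMT abundances are per-channel sums of
reporter-ion intensities over *unique* peptides only (`tmtRollup()`);
razor peptides are excluded there because reporter signal from a shared
peptide cannot be apportioned between proteins. Zero-intensity channels
contribute zero, not missingness.

# Two-stage normalization

`log2MedianCenter()` log2-transforms intensities and subtracts each
sample's median (computed over the values present in that sample), removing
per-sample loading and instrument-response differences.

`selectReferenceProteins()` then finds housekeeping-like anchors: proteins
detected in **100% of the samples** whose coefficient of variation is
**below 60% in every batch**. Two conventions had to be fixed because
either choice is defensible:

* CV is computed on *linear-scale* intensities with the sample (n−1)
  standard deviation. CV is a linear-scale concept (sd/mean of
  intensities); computing it after log transformation would measure
  something else, and the 60% threshold reads naturally on the linear
  scale.
* "identified in all samples" means the whole cohort, not per batch —
  the stricter reading, consistent with describing the anchors as
  detected in 100% of samples.

`interbatchCorrect()` subtracts, within each batch, the median of the
reference proteins over that batch's samples, so the reference median is
zero in — hence identical across — all batches. This removes exactly the
additive (in log2) batch shifts that a median-type correction can remove;
no empirical-Bayes (ComBat-style) moderation is attempted, and missing
values are never imputed. `relativeAbundance()` finally reports each
protein's median over its detected samples, its detection count, and a
dense rank (ties broken lexicographically by protein id so the ranking is
a reproducible permutation).

# Mutation-bearing tryptic peptides

`digestProtein()` enumerates fully specific tryptic peptides (cleavage
after K/R, suppressed before proline) or Arg-C-like peptides (after R
only — the effective specificity of trypsin on fully lysine-acetylated
proteins), with 0–k missed cleavages. The proline rule is enforced
because the recurrent driver-mutation peptides we reproduce are consistent
with it; semi-tryptic peptides are assumed absent.

`mutantSpecificPeptides()` digests the mutated sequence and reports
peptides that evidence the mutation. Direct evidence is a peptide covering
the mutated residue. A substitution that *creates* a cleavage site (e.g.
Gln→Lys) also produces peptides that abut the new site without containing
the mutated residue; these exist in no wild-type digest and are reported
with `evidence = "indirect"`. This matters in practice: for a Gly-protein
α-subunit N266K substitution the observable peptide is the downstream
SSVILFLNK, which starts right after the gained site. The converse
reasoning is available as `inferIndirectCleavage()`: an observed peptide
whose upstream residue is not K/R can only arise (under full specificity)
if that residue mutated to K or R, so those two candidates are emitted —
as candidates only, never auto-promoted to calls.

Peptide uniqueness (`peptideUniqueness()`) is exact substring matching
with I/L treated as equal by default, since the two residues are isobaric
and indistinguishable in standard MS — the same convention as the common
online uniqueness checkers. `hppMissingProteinCheck()` applies the
missing-protein evidence rule of at least two uniquely mapping peptides of
length ≥ 9.

# Transcriptome integration

`filterTranscripts()` keeps transcripts with at least 10 reads and
collapses them to genes. "At least ten reads" is ambiguous (per sample?
total?); we threshold the per-transcript *maximum* over samples, which is
the most permissive per-sample reading, and expose `statistic = "total"`
for the alternative. `overlapSets()` does the three-way Venn bookkeeping
against the annotated human proteome. `correlateOmics()` computes Pearson
correlation on the gene intersection, optionally restricted to transcripts
detected in ≥ 99% of samples; protein and transcript summaries may each be
min-max scaled to [10, 35] for plotting (`minmaxScale()`), which leaves
the correlation unchanged (affine invariance). Positive transcript counts
are log2-transformed before summarizing; the correlation is computed on
log scales, where protein–mRNA relationships are conventionally assessed.

`enrichment1D()` tests, per annotation term, whether member genes shift
within a single ranked score list (typically protein-minus-transcript
differences). Significance is a two-sided Mann–Whitney test; the effect
size is

$$ s = \frac{2\,(\bar R_{\mathrm{in}} - \tfrac{n+1}{2})}{\,n - n_{\mathrm{in}}\,} \in [-1, 1], $$

with mid-ranks for ties. The formula is pinned down by its contract:
\(s = +1\) when members hold the \(n_{\mathrm{in}}\) largest ranks, \(-1\)
at the opposite extreme, expectation 0 under exchangeability, and
invariance under any strictly monotone transform of the scores. P-values
are Benjamini–Hochberg adjusted across terms.

# Phosphoproteome, motifs, and the kinome

Class I phosphosites are those with localization probability ≥ 0.75
(inclusive); different search engines phrase the threshold as ">75" or
"≥ 0.75", and we unify them as one configurable inclusive cutoff.
`extractSiteWindow()` produces the uniform 15-residue windows (site
centered, termini padded) on which `enrichMotifs()` runs a motif-x-style
greedy search: repeatedly fix the (position, residue) pair with the
smallest binomial tail probability of its foreground count given the
current background frequency, filter both sets, and stop when no pair
reaches both the p-value cutoff (default 1e-6) and the minimum occurrence
count (default 20) — standard motif-x practice. The search is
deterministic (ties broken by position, then residue) and is run per
central residue (S, T, Y). Extracted motifs are ranked by foreground
support; cumulative p-values are also reported on a −log10 scale because
the products underflow routinely. Greedy searches of this family can
emit over-refined variants of a strong motif (an extra fixed position that
clears the cutoff by chance); ranking by support keeps the parent motif on
top, and the type-I behavior on motif-free foregrounds is tested
explicitly.

`predictKinases()` maps enriched motifs to kinases through a packaged
table (`kinase_motifs_synthetic.tsv`) of well-known motif–kinase
preferences (basophilic R-x-x-S for PKA/CaMK2, proline-directed S-P for
CDKs/MAPKs, acidophilic S-x-x-E for CK2, S-Q for ATM/ATR, …). The table is
deliberately small and synthetic — a stand-in for the large curated
substrate databases, which are not redistributable — so kinase counts from
real motif databases are *not* reproduced here; what is tested is exact
recovery of planted motif→kinase pairs. `kinomeUnion()` combines directly
identified and motif-predicted kinases into coverage of a reference
kinome, with inclusion–exclusion as an enforced invariant.

# Acetylation occupancy

In the chemical-labeling design, endogenous acetyl groups are light and
chemically introduced acetyl groups (on previously unmodified lysines)
are heavy, so site occupancy is

$$ \theta = \frac{L}{L + H} \times 100\% , $$

implemented in `acetylOccupancy()`. The formula follows directly from the
labeling chemistry: light and heavy signal partition one site's molecules.
Sites with \(L = H = 0\) are undefined and flagged rather than zeroed.
`occupancyDistribution()` summarizes occupancies per sample (median and
quartiles) and per origin group, and reports the grand median over
per-sample medians — the median is used for "average occupancy" because
occupancy distributions are strongly right-skewed.

# Plasma profiling

`nsaf()` computes normalized spectral abundance factors,
\( (SpC_i/L_i) / \sum_j (SpC_j/L_j) \), preferring FASTA-derived lengths
over a length column when both are given. `classifyOrigin()` labels a
plasma protein blood-origin exactly when its gene has no tissue transcript
evidence, and `tissueBloodFraction()` gives the per-tissue-sample
percentage of identifications that are blood-origin. Immunoglobulin
flagging is a documented gene-prefix heuristic (IGH/IGK/IGL); the
disease-marker panel ships as a small editable synthetic GMT because the
exact regulatory panel is not published as a machine-readable list.

# The synthetic cohort generator

The generators are first-class, tested code; their defaults *are* the
study conditions and are not revisited:

* **Abundances** (`simulateAbundance()`): true log2 abundances are uniform
  over 6 orders of magnitude (the generator models only the observed
  spread, which is the one property asserted of the real distribution);
  measurements add a per-batch offset (sd 0.5 log2) and per-protein noise
  (sd 0.8–1.8 log2; 0.35 for planted references, i.e. linear CV ≈ 25%).
  Missingness follows a logistic detection curve in true log2 abundance
  (midpoint 6, slope 1.5), making detection probability monotone in
  abundance; no missingness mechanism is known for the real data, so this
  is a modeling choice. The default cohort is 2000 proteins, 5 batches of
  20 samples, 45 planted reference proteins.
* **Planted separation**: the generator's contract is that the planted
  reference set is *exactly* the qualifying set. A planted protein whose
  sampled CV strays over the 60% criterion is re-drawn (seeded, bounded),
  and a non-planted protein that would accidentally qualify has one
  measurement knocked out. Disable with `enforcePlanted = FALSE` for
  degenerate noise-free configurations.
* **Transcripts** (`simulateTranscripts()`): the transcript latent is
  \( \rho z + \sqrt{1-\rho^2}\,\varepsilon \) against the standardized
  protein medians, which yields sample correlations converging to ρ
  regardless of the protein-median distribution; defaults plant 27%
  transcript-only and 3% protein-only genes, mirroring realistic
  proteome/transcriptome asymmetries.
* **Acetylome** (`simulateAcetylome()`): true occupancies are
  Beta(1, 9) (mean 10%, median ≈ 7.4% — "most sites have low occupancy");
  60 samples with 200–2000 sites each in origin groups of 16 primary,
  23 lymph-node, 21 other metastases; channel noise is log-normal with
  sdlog 0.2, at which occupancy recovery has a median absolute error
  under 2 percentage points.
* **Phosphosites** (`simulatePhospho()`): uniform residue usage with a
  planted motif (default R-x-x-S# in 30% of the foreground against a ~5%
  background rate).

What the generator does *not* emulate: correlated protein modules,
protein-group/parsimony ambiguity, peptide-level missingness structure,
isotope impurities, heavy-tailed spectral-count overdispersion beyond a
negative binomial, or inter-sample biology. Tests passing on this
generator therefore validate the *algorithms and their contracts*, not
cohort-level biological claims.

All generators take one master seed and derive fixed child seeds, so every
table is bit-reproducible; the caller's RNG state is left untouched.

# Problem sizes and numerical choices

The shipped test suite runs desk-scale problems: the default 2000 × 100
abundance matrix, acetylomes of up to ~70k sites, motif searches on
5000/20000 windows, a 10 000-draw permutation-null calibration of the 1D
enrichment score, and ρ-recovery at 10 000 genes — sizes chosen so the
complete suite runs in well under a minute while keeping Monte-Carlo
tolerances tight (±0.03 on ρ at n = 10 000; a few per mil on permutation
means). Medians over even counts use R's interpolation convention;
centering tolerances are 1e-9; NSAF sums are checked to 1e-12. Degenerate
inputs (constant vectors in `minmaxScale()`, empty reference sets, samples
with no defined occupancy, zero-count NSAF tables) raise errors or warnings
rather than silently producing numbers.

# Known limitations

* No protein inference/grouping: `protein_id` is taken as given.
* No TMT isotope-impurity correction, no PSM-level FDR modeling, no
  spectral simulation.
* The reference-protein rule is data-driven; on real data the size of the
  selected set depends on cohort depth and missingness and need not be 45.
* Kinase predictions are only as good as the packaged (synthetic) motif
  table; it is a scaffold to plug a real substrate resource into.
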