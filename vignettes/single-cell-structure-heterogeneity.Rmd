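---
title: "Measuring RNA structural heterogeneity in single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring RNA structural heterogeneity in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scstructr)
```

## The measurement

Chemical structure probing with an acylating reagent modifies the 2′-OH of
flexible — predominantly single-stranded — nucleotides. Under mutational
profiling, reverse transcriptase reads through the adduct and leaves a
mutation, so the per-base mutation rate in sequencing reads is a proxy for
structural accessibility. Two channels are sequenced: reagent-treated
cells, and DMSO-treated (mock) cells whose mutation rates estimate the
background error of the entire pipeline. Per-base **reactivity** is the
difference of the two rates. In single cells, the same quantities are
available per cell, at much lower and more uneven depth; the scientific
question this package addresses is whether a transcript folds the same way
in every cell, and where along the transcript it does not.

`scstructr` assumes its input is a table of per-cell, per-base counts —
coverage and mutated reads in transcript coordinates — produced upstream by
any aligner plus base counter. Alignment, UMI handling and expression
normalization are out of scope; expression values for QC and stratified
analyses are consumed as an externally normalized table.

## Window-level heterogeneity: the adjusted-R² statistic

The transcript is tiled into fixed, non-overlapping windows of
`window_size = 10` nt anchored at position 0 (a trailing partial window is
dropped: a fixed tiling makes windows comparable across cells and
transcripts). For window *s* and cell *c*, `depth(c, s)` and
`mutant(c, s)` are the coverage and mutated-read counts summed over the
window's positions. If all cells share one conformation, every cell
modifies the window at the same underlying rate `mod(s)` and

```
mutant(c, s) = mod(s) · depth(c, s) + ε
```

holds with only counting noise in ε: the points (depth, mutant) across
cells fall on one line. If cells carry different conformations the rate
itself varies and the cloud fans out. The goodness of the ordinary
least-squares fit therefore measures homogeneity. We fit with an intercept
and take R² as the squared Pearson correlation of mutant and depth; the
reported statistic is the adjusted R²,

```
adj R² = 1 − (1 − R²)(n − 1)/(n − 2),
```

with one predictor and n = number of cells covering the window, which
penalizes windows seen in few cells. The conceptual model has no intercept
(zero depth forces zero mutants), but a through-origin R² is not comparable
across windows with different baselines and the standard simple-regression
R² is what the usual fitting routines report; we follow the latter and
document the divergence. The fitted slope is reported as the window's
modification rate.

Windows enter downstream analysis only when **detected**: total coverage
strictly greater than `min_window_reads = 600` reads (a depth at which
replicate reactivities correlate well for 10-nt windows) and coverage in at
least `min_cell_fraction = 50%` of cells. Detection per cell is any
nonzero window coverage; the 600-read rule applies to the cell-summed
total. Both inequalities follow the strict/non-strict wording of their
thresholds exactly (600 fails, 601 passes; 50% passes, 49% fails), and the
boundary behaviour is pinned by tests.

Degenerate fits are flagged rather than coerced: fewer than
`min_cells = 4` covered cells (the adjusted-R² denominator n − 2 needs
headroom) or zero variance in depth yield `defined = FALSE` with a reason.
Coercing them to 0 or 1 would bias the quartile classification that
follows. A window whose mutant counts have zero variance (typically all
zero) gets R² = 0: the fit explains nothing there, which is the honest
value.

## Gene-level heterogeneity: cosine dispersion

Per-cell reactivity profiles of a transcript are first **quantile
normalized** across cells to remove cell-to-cell differences in
modification efficiency: each cell's unmasked values are replaced by the
mean of the order statistics across cells at the same fractional rank.
Cells covering different numbers of positions are put on a common rank grid
by linear interpolation, and ties within a cell receive the average of the
reference values across the tied ranks (so tied inputs stay tied). The
pseudobulk profile is normalized together with the cells so that distances
are computed on one scale.

Each cell is then compared to the pseudobulk by cosine distance over the
positions unmasked in both,

```
D_i = 1 − (R_i · R_pb) / (‖R_i‖ ‖R_pb‖),
```

and the transcript's heterogeneity is the root-mean-square dispersion
`sqrt(Σ D_i² / n)`. Cosine distance is scale-invariant, which is the reason
for choosing it — residual per-cell efficiency differences cancel — but it
is sign-sensitive: negative reactivities (background exceeding signal at
individual bases) are retained by default because the subtraction defines
them, and a `clamp` option exists for callers who prefer the truncated
convention. Cells sharing fewer than 10 positions with the pseudobulk, or
with zero-norm vectors, are excluded with a warning; fewer than two usable
cells is an error.

**Pseudobulk** profiles sum counts across cells before dividing, rather
than averaging per-cell rates: that is how a merged library would behave,
weighting each cell by its evidence. The alternative (rate averaging)
gives deep and shallow cells equal say and is markedly noisier; the two
differ exactly when coverage and rate are correlated across cells, and the
tests pin the count-sum definition.

## Classification, regions, metagene, trajectories

Transcripts (or windows) are binned by quartile: the bottom quartile of
the heterogeneity value is called homogeneous, the top heterogeneous, the
middle half intermediate. Boundaries use the linear-interpolation
percentile (R type 7); values tied with a boundary go to the extreme
class, and if the two boundaries coincide (all values equal) everything is
intermediate, with a warning. Note the orientation: gene-level dispersion
is a heterogeneity score (low = homogeneous) while adjusted R² is a
homogeneity score, so the pipeline classifies `−adj R²`.

Windows are assigned to 5′UTR/CDS/3′UTR by the region of their midpoint
`floor((start + end)/2)` against the half-open CDS interval. Metagene
densities around the start or stop codon scale each window's offset by the
length of the flank it falls in (upstream of the anchor: distance to the
transcript start; downstream: to the end), bin the scaled position into
`n_bins` bins over [−1, 1], and test per-bin enrichment of an interest set
over the background with an upper-tail hypergeometric test (population =
all windows, successes = interest windows, draws = windows in the bin);
empty bins report density 0 and p = 1.

Heterogeneity trajectories across stages are clustered by k-means under
dynamic time warping (squared local cost, unconstrained monotone
alignment, distance = square root of the accumulated cost) with DBA
(DTW barycenter averaging) centroids. The default `k = 6` follows the
number of trajectory archetypes typically distinguished across a four-stage
differentiation; 10 seeded restarts are run and the solution with the
lowest within-cluster inertia kept, so results are deterministic given the
seed. Cell-level clustering by reactivity profile uses plain k-means on
the mask-intersection positions.

## Structure benchmarking

Reference structures arrive as dot-bracket (each pseudoknot bracket tier
balanced independently; unknown characters are a hard error, since silent
"unpaired" defaults would corrupt labels) or CT files. Unpaired bases are
labeled true (truly modifiable), paired false. When a 2′-OH solvent
accessibility table is available, bases below 3 Å² are excluded from both
classes — a buried ribose cannot react regardless of pairing, so it is
uninformative for either label; without a table all bases are used
(benchmarks of transfected RNAs without a 3D model). AUC uses the
rank/Mann–Whitney formulation with half-credit for ties, which the tests
verify against an O(n²) pair-count oracle and an external ROC
implementation. The paired-vs-unpaired comparison uses a two-sided
Mann–Whitney U: exact enumeration of all group assignments when both
classes have ≤ 8 values (correct under ties), otherwise the normal
approximation with tie-corrected variance and a 0.5 continuity correction.

## Enrichment and stratified comparisons

Window-class enrichment over feature/RBP intervals is an upper-tail
hypergeometric test per feature (overlap = nonempty half-open
intersection), Bonferroni-adjusted across the features tested in the call
— the family is the features actually tested, the only family size that is
well-defined at call time — with `enriched ⇔ adj p ≤ 0.05`. Depletion via
the lower tail is available but off by default.

Expression-quartile stratification ranks cells by a gene's expression
(ties broken by cell id, so the split is reproducible) into four bins
whose sizes differ by at most one, lower bins taking the remainder. The
reactivity change between top and bottom quartiles is
`log2((mean_q4 + c)/(mean_q1 + c))` with pseudocount `c = 0.01`, which
keeps the ratio defined when near-zero or slightly negative mean
reactivities occur; windows where a shifted mean is still nonpositive are
skipped with a reason. Significance is a two-sided Welch t-test on the
per-cell window reactivities — unequal variances between expression strata
are expected, so the pooled-variance variant would be anticonservative.
If both strata are exactly constant the statistic degenerates and we
report t = 0, p = 1 for equal means (and p = 0 otherwise) rather than
erroring mid-pipeline.

## The simulator: what it emulates, and what it does not

`simulate_counts()` draws, per cell and transcript: a conformation from
the transcript's mixture weights; per-base coverage from a negative
binomial (`depth_dispersion = 5`; single-cell depth is overdispersed
relative to Poisson) whose mean decays exponentially with distance from
the 3′ end (`depth_decay = 1/1000` per base, reflecting fragmented
libraries that sequence roughly a kilobase from the 3′ end); and mutated
counts from a binomial with probability = conformation modification
probability + `control_error_rate`, capped at 1. Control cells are
separate cells seeing background error only; the default
treated:control cell ratio (~6:1, e.g. 40:7) mirrors typical probed
batches. Whole cell × transcript dropouts occur with probability 0.1.
Base modification probabilities default to the 1–4% range so simulated
treated mutation rates land in the 2–3% regime characteristic of the
reagent. Everything is deterministic given the config seed.

The model deliberately omits several features of real data: sequence
context and base-selectivity of the reagent, correlated errors along
reads, PCR duplication, alignment artifacts, multi-hit kinetics, and any
coupling between expression level and conformation. Recovery results on
simulated data therefore show that the statistics identify the signal they
are defined to identify at realistic depth and noise — not that real
libraries are free of the confounders above. The depth-subsampling
control (`subsample_counts`, binomial thinning with hypergeometric
mutated-count thinning, which preserves the expected rate exactly) is the
in-package tool for checking depth-driven artifacts on real data.

The two-conformation panel (`make_two_conformation_panel`) places the gap
at 5 of 10 window positions with 50/50 weights; at its default study
settings (40 cells, 1000× flat depth, gap 0.1) ranking windows by adjusted
R² separates true labels essentially perfectly, and the test suite asserts
AUC ≥ 0.9 at 100+100 windows. The reference fixture
(`make_reference_fixture`) generates a uniformly random fully nested
pairing at the requested unpaired fraction with modification probabilities
0.08/0.01 (unpaired/paired); the simulate → pseudobulk → ROC loop recovers
it with AUC ≥ 0.9 at depth 1000, while label-shuffled controls sit at
0.5.

## Quality control

Cells are kept when they detect at least 5000 genes (expression > 0) and
have a mitochondrial expression fraction of at most 5%. Both thresholds
are strict in the failing direction — 4999 genes fails, exactly 5000
passes; 5.1% fails, exactly 5.0% passes. The mitochondrial fraction is
computed from whatever values the expression table carries (raw or mapped
read counts); the choice of denominator is the caller's, made by the table
they supply, and is documented rather than guessed.

## Numerical and interface conventions

- Coordinates are 0-based half-open everywhere inside the package; CT and
  SHAPE files are 1-based per their standards and converted only in the
  I/O layer, so off-by-one drift has a single place to not happen.
- `mutated` aggregates mismatches and indels; no formula downstream
  distinguishes them.
- Masks are authoritative: no rate or reactivity value exists at a
  position without coverage, and every operation propagates masks by
  intersection rather than imputing.
- The 2–8% gene-level normalization excludes the top
  `ceiling(0.02·n)` reactivities and divides by the mean of the next
  `ceiling(0.08·n)`; a nonpositive normalizer (profiles dominated by
  negative values) is an error naming the degenerate profile.
- SHAPE files write missing positions as −999 and numbers at 15
  significant digits (round-trip exact at working precision).
- Manifests record MD5 digests of every output; run logs record package
  version, seed, thresholds and machine-readable `EXCLUDED` lines for
  every dropped cell and window. Logs contain no timestamps, so reruns
  with identical inputs and seed are digest-identical.

## Problem sizes

The shipped tests and the acceptance script run the statistics at the
sizes the methods are designed for while staying desk-sized: 1000 random
windows for the least-squares oracle, exhaustive hypergeometric
enumeration to N = 12 plus 300 random cases to N = 30, 500 ROC instances
up to 200 positions, a 200-window/40-cell recovery panel at 1000× depth, a
300-nt benchmark structure, 2000 null simulations for test calibration,
and a 3-transcript, 47-cell demo dataset for the end-to-end determinism
check. These sizes are the package's own choice of a thorough yet quick
default; all of them scale up by changing the corresponding arguments.

## Known limitations

- The window statistic conflates conformational heterogeneity with any
  other source of cell-to-cell rate variation (e.g. reagent dosage
  differences that survive normalization).
- Adjusted R² is undefined below 4 covered cells; sparse transcripts
  yield many flagged windows rather than values.
- The metagene scaling treats each flank as a unit interval, so
  transcripts with extreme UTR/CDS length ratios compress differently.
- DTW k-means is a local optimizer; determinism comes from seeded
  restarts, not from a global optimum.
- The simulator's independence assumptions (see above) make it a
  calibration tool, not a generative model of real libraries.
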