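# scstructr

Single-cell RNA structure probing analysis in R.

Chemical probing with a SHAPE reagent (e.g. NAI-N3) modifies flexible,
mostly unpaired nucleotides; during reverse transcription the adducts leave
mutations, so the per-base **mutation rate** read out by sequencing reports
RNA structure. `scstructr` takes per-cell, per-base count tables (coverage
and mutated reads, for a reagent-treated and a DMSO control channel) and
computes, per cell and per transcript:

- **reactivity** — treated minus control mutation rate,
  `R(i) = m_T(i)/c_T(i) − m_C(i)/c_C(i)`, with gene-level (2–8%) and
  cross-cell quantile normalization, pseudobulk pooling, and depth
  subsampling controls;
- **window-level structural heterogeneity** — the transcriptome is tiled
  into 10-nt windows; for each window the per-cell mutated count is
  regressed on the per-cell coverage,
  `mutant(c) = mod · depth(c) + ε`, and the adjusted *R²* of the fit is the
  homogeneity score: one shared modification rate across cells gives
  adj *R²* ≈ 1, cell-to-cell structural differences push it toward 0;
- **gene-level structural heterogeneity** — the RMS dispersion of per-cell
  cosine distances to the pseudobulk profile,
  `H = sqrt( Σᵢ D_i² / n )`, `D_i = 1 − (Rᵢ·R_pb)/(‖Rᵢ‖‖R_pb‖)`;
- **structure accuracy** — ROC/AUC of reactivities against reference
  secondary structures (dot-bracket or CT), with an optional 2′-OH
  solvent-accessibility filter (≥ 3 Å²), plus a paired-vs-unpaired
  Mann–Whitney comparison;
- **enrichment** — one-sided hypergeometric overlap of window classes with
  feature/RBP binding intervals (Bonferroni-adjusted), metagene densities
  around start/stop codons, expression-quartile-stratified reactivity
  changes (Welch *t*), and DTW k-means clustering of heterogeneity
  trajectories across stages.

A fully seeded simulator (`sim_config()`, `simulate_counts()`,
`make_two_conformation_panel()`, `make_reference_fixture()`) generates
count tables from known conformation mixtures — binomial mutation counts on
negative-binomial, 3′-biased coverage with dropout — so the entire pipeline
is testable with no sequencing data. Intended users are computational
biologists working with single-cell mutational-profiling structure data or
benchmarking heterogeneity statistics.

## Worked example

Simulate a small panel of 10-nt windows probed in 40 cells — half the
windows identical in all cells, half a 50/50 mixture of two conformations
differing by 0.1 in modification rate — then score heterogeneity:

```r
library(scstructr)
panel <- make_two_conformation_panel(n_hom = 4, n_het = 4, rate_gap = 0.1,
                                     n_cells = 40, depth_mean = 1000, seed = 1)
sim <- simulate_counts(panel$config)
wt  <- window_table(sim$treated, "panel")
merge(wt, panel$truth, by = c("transcript_id", "window_start", "window_end"))
```

```
 window_start window_end n_cells total_reads detected  slope adj_r_squared         label
            0         10      40      397105     TRUE 0.0281        0.8682   homogeneous
           10         20      40      393966     TRUE 0.0294        0.8547   homogeneous
           20         30      40      408461     TRUE 0.1191        0.2901 heterogeneous
           30         40      40      419837     TRUE 0.0632        0.0665 heterogeneous
           40         50      40      408326     TRUE 0.0399        0.0316 heterogeneous
           50         60      40      401503     TRUE 0.0238        0.7213   homogeneous
           60         70      40      394489     TRUE 0.0189       -0.0198 heterogeneous
           70         80      40      391351     TRUE 0.0275        0.8020   homogeneous
```

Every window clears the detection filter (> 600 total reads, ≥ 50% of
cells). The `slope` is the fitted window modification rate (here ~2–3%, as
expected for this reagent); the truly homogeneous windows score adj *R²*
0.72–0.87 while the mixture windows drop to 0.29 and below — ranking
windows by adj *R²* separates the truth labels (AUC ≥ 0.9 at the full
100+100-window panel).

Benchmarking a pseudobulk reactivity profile against the structure it was
simulated from recovers the pairing state essentially perfectly at this
depth:

```r
bc   <- make_benchmark_config(length = 300, unpaired_fraction = 0.5, seed = 2)
simb <- simulate_counts(bc$config)
prof <- compute_reactivity(
  pseudobulk(simb$treated, unique(simb$treated$cell_id), "treated", "fixture", 300),
  pseudobulk(simb$control, unique(simb$control$cell_id), "control", "fixture", 300))
roc_auc(prof, label_positions(bc$structure))
#> <roc_result> AUC = 1.0000 (n_true = 150, n_false = 150)
```

A file-level interface is available as a thin command-line wrapper:

```sh
inst/cli/scstructr simulate --out demo --seed 1
inst/cli/scstructr run --treated demo/treated_counts.tsv \
    --control demo/control_counts.tsv --out results \
    --expression demo/expression.tsv --mito-genes demo/mito_genes.txt \
    --annotation demo/annotation.tsv --intervals demo/intervals.bed \
    --sequences demo/sequences.tsv
```

## Package layout

- `R/io.R` — count/structure/interval/SHAPE/expression readers and writers
  (0-based half-open internally; CT and SHAPE are 1-based at the boundary)
- `R/reactivity.R` — rates, QC, reactivity, normalizations, pseudobulk
- `R/heterogeneity.R` — window and gene heterogeneity, classification,
  metagene, DTW clustering
- `R/benchmark.R` — labeling, ROC/AUC, rank-sum comparisons
- `R/enrichment.R` — interval overlap, hypergeometric enrichment,
  quartile stratification
- `R/simulate.R` — the generative model and fixtures
- `R/pipeline.R` — file-level orchestration (`sc_simulate_dataset`,
  `sc_run`, `sc_benchmark`), manifests, run logs
- `vignettes/single-cell-structure-heterogeneity.Rmd` — the methods
  vignette (model, assumptions, parameter choices, limitations)
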