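# Synthetic single-cell structure-probing data with known ground truth.
#
# The generative model: each cell draws one conformation per transcript from
# the transcript's conformation weights; per-base coverage is negative
# binomial with a mean that decays exponentially with distance from the 3'
# end (fragmented libraries sequence ~1 kb from the 3' end); treated mutated
# counts are binomial with probability = conformation modification
# probability + background error (capped at 1); control (DMSO) cells see
# background error only. Everything is deterministic under the config seed.

#' Build and validate a simulation configuration
#'
#' @param n_cells number of treated cells (default 40, a typical probed
#'   single-cell batch).
#' @param n_control_cells number of control (DMSO) cells; default about one
#'   sixth of the treated cells, mirroring the usual treated:control ratio.
#' @param transcripts list of lists with `id`, `length`, optional
#'   `sequence` (random ACGU generated when absent).
#' @param conformations per transcript, a list of per-position modification
#'   probability vectors (values in [0, 0.15]).
#' @param weights per transcript, a probability vector over conformations.
#' @param control_error_rate background mutation probability (default 0.003).
#' @param depth_mean mean per-base coverage per cell at the 3' end
#'   (default 50).
#' @param depth_decay exponential decay of mean coverage per base of
#'   distance from the 3' end (default 1/1000).
#' @param depth_dispersion negative binomial size parameter (default 5;
#'   single-cell depth is overdispersed relative to Poisson).
#' @param dropout probability that a cell x transcript is unobserved
#'   (default 0.1).
#' @param seed integer seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 40,
                       n_control_cells = max(2L, round(n_cells / 6)),
                       transcripts,
                       conformations,
                       weights = NULL,
                       control_error_rate = 0.003,
                       depth_mean = 50,
                       depth_decay = 1 / 1000,
                       depth_dispersion = 5,
                       dropout = 0.1,
                       seed = 1) {
  if (!is_count(n_cells) || !is_count(n_control_cells))
    stop_validation("n_cells and n_control_cells must be positive integers")
  ids <- vapply(transcripts, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_validation("duplicate transcript ids")
  if (is.null(weights))
    weights <- lapply(conformations, function(cf)
      rep(1 / length(cf), length(cf)))
  if (length(conformations) != length(transcripts) ||
      length(weights) != length(transcripts))
    stop_validation("conformations and weights must align with transcripts")
  for (i in seq_along(transcripts)) {
    L <- transcripts[[i]]$length
    for (v in conformations[[i]]) {
      if (length(v) != L)
        stop_validation(sprintf(
          "conformation length %d != transcript length %d for '%s'",
          length(v), L, ids[i]))
      if (any(v < 0 | v > 1))
        stop_validation("modification probabilities must be in [0, 1]")
    }
    w <- weights[[i]]
    if (length(w) != length(conformations[[i]]) || any(w < 0) ||
        abs(sum(w) - 1) > 1e-8)
      stop_validation(sprintf("weights for '%s' must sum to 1", ids[i]))
  }
  if (control_error_rate < 0 || control_error_rate > 1 ||
      dropout < 0 || dropout > 1)
    stop_validation("probabilities must be in [0, 1]")
  if (depth_mean <= 0 || depth_dispersion <= 0 || depth_decay < 0)
    stop_validation("depth model parameters must be positive")
  structure(list(n_cells = as.integer(n_cells),
                 n_control_cells = as.integer(n_control_cells),
                 transcripts = transcripts,
                 conformations = conformations,
                 weights = weights,
                 control_error_rate = control_error_rate,
                 depth_mean = depth_mean,
                 depth_decay = depth_decay,
                 depth_dispersion = depth_dispersion,
                 dropout = dropout,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# truth heterogeneity label per tiled window: heterogeneous when any two
# conformations with positive weight differ anywhere in the window
truth_window_labels <- function(config, window_size = 10) {
  out <- list()
  for (i in seq_along(config$transcripts)) {
    tx <- config$transcripts[[i]]
    cf <- config$conformations[[i]]
    w <- config$weights[[i]]
    active <- cf[w > 0]
    n_windows <- tx$length %/% window_size
    if (n_windows == 0) next
    lab <- vapply(seq_len(n_windows), function(wi) {
      pos <- ((wi - 1) * window_size + 1):(wi * window_size)
      if (length(active) < 2) return("homogeneous")
      ref <- active[[1]][pos]
      het <- any(vapply(active[-1], function(v) any(v[pos] != ref), TRUE))
      if (het) "heterogeneous" else "homogeneous"
    }, "")
    out[[tx$id]] <- data.frame(
      transcript_id = tx$id,
      window_start = (seq_len(n_windows) - 1L) * window_size,
      window_end = seq_len(n_windows) * window_size,
      label = lab, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Simulate per-cell per-base count tables
#'
#' @param config a [sim_config].
#' @param window_size window size used for the truth heterogeneity labels
#'   (default 10).
#' @return list with `treated` and `control` [base_counts] tables and
#'   `truth` (cell_conformations, window_labels, conformations).
#' @export
simulate_counts <- function(config, window_size = 10) {
  if (!inherits(config, "sim_config"))
    stop_usage("config must be built with sim_config()")
  set.seed(config$seed)
  treated <- list()
  control <- list()
  assign_rows <- list()
  cell_ids <- sprintf("cell_%03d", seq_len(config$n_cells))
  ctrl_ids <- sprintf("ctrl_%03d", seq_len(config$n_control_cells))
  for (i in seq_along(config$transcripts)) {
    tx <- config$transcripts[[i]]
    L <- tx$length
    mu <- config$depth_mean *
      exp(-config$depth_decay * (L - 1 - (seq_len(L) - 1)))
    cf <- config$conformations[[i]]
    w <- config$weights[[i]]
    for (ci in seq_along(cell_ids)) {
      if (stats::runif(1) < config$dropout) next
      conf_idx <- sample.int(length(cf), 1, prob = w)
      assign_rows[[length(assign_rows) + 1]] <- data.frame(
        cell_id = cell_ids[ci], transcript_id = tx$id,
        conformation = conf_idx, stringsAsFactors = FALSE)
      cov <- stats::rnbinom(L, mu = mu, size = config$depth_dispersion)
      p <- pmin(1, cf[[conf_idx]] + config$control_error_rate)
      mut <- stats::rbinom(L, cov, p)
      keep <- cov > 0
      if (!any(keep)) next
      treated[[length(treated) + 1]] <- data.frame(
        cell_id = cell_ids[ci], transcript_id = tx$id,
        position = which(keep) - 1L, coverage = cov[keep],
        mutated = mut[keep], condition = "treated",
        stringsAsFactors = FALSE)
    }
    for (ci in seq_along(ctrl_ids)) {
      if (stats::runif(1) < config$dropout) next
      cov <- stats::rnbinom(L, mu = mu, size = config$depth_dispersion)
      mut <- stats::rbinom(L, cov, config$control_error_rate)
      keep <- cov > 0
      if (!any(keep)) next
      control[[length(control) + 1]] <- data.frame(
        cell_id = ctrl_ids[ci], transcript_id = tx$id,
        position = which(keep) - 1L, coverage = cov[keep],
        mutated = mut[keep], condition = "control",
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(cell_id = character(0), transcript_id = character(0),
                      position = integer(0), coverage = integer(0),
                      mutated = integer(0), condition = character(0),
                      stringsAsFactors = FALSE)
  treated_df <- if (length(treated) > 0) do.call(rbind, treated) else empty
  control_df <- if (length(control) > 0) do.call(rbind, control) else empty
  truth <- list(
    cell_conformations = if (length(assign_rows) > 0)
      do.call(rbind, assign_rows) else NULL,
    window_labels = truth_window_labels(config, window_size),
    conformations = config$conformations)
  list(treated = base_counts(treated_df),
       control = base_counts(control_df),
       truth = truth)
}

#' Two-conformation window panel with known heterogeneity labels
#'
#' Builds a single synthetic transcript tiled with `n_hom` homogeneous and
#' `n_het` heterogeneous 10-nt windows in shuffled order, probed by a 50/50
#' mixture of two conformations. Heterogeneous windows differ between the
#' conformations by `rate_gap` at 5 of their 10 positions; homogeneous
#' windows are identical. Per-position base modification rates are drawn
#' uniformly from `base_rate_range` (defaults spanning the 2-3% regime
#' typical of the probe).
#'
#' @param n_hom,n_het window counts (defaults 100 each).
#' @param rate_gap modification-rate gap in (0, 0.15]; 0 is allowed and
#'   makes every window truly homogeneous.
#' @param n_cells,n_control_cells,depth_mean,seed passed to [sim_config];
#'   depth defaults to 1000x per base with no 3' decay (a benchmarking
#'   panel, not a library emulation).
#' @param base_rate_range range of per-position base modification rates.
#' @param ... further arguments to [sim_config].
#' @return list with `config` (a [sim_config]) and `truth` (the window
#'   label data.frame).
#' @export
make_two_conformation_panel <- function(n_hom = 100, n_het = 100,
                                        rate_gap = 0.1,
                                        n_cells = 40, n_control_cells = 7,
                                        depth_mean = 1000, seed = 1,
                                        base_rate_range = c(0.015, 0.035),
                                        ...) {
  if (rate_gap < 0 || rate_gap > 0.15)
    stop_validation("rate_gap must be in [0, 0.15]")
  set.seed(seed)
  n_windows <- n_hom + n_het
  L <- 10L * n_windows
  base <- stats::runif(L, base_rate_range[1], base_rate_range[2])
  conf1 <- base
  conf2 <- base
  het_windows <- sample(rep(c(TRUE, FALSE), c(n_het, n_hom)))
  for (wi in which(het_windows)) {
    pos <- ((wi - 1) * 10 + 1):((wi - 1) * 10 + 5)  # 5 of the 10 positions
    conf2[pos] <- pmin(0.15, conf1[pos] + rate_gap)
  }
  config <- sim_config(
    n_cells = n_cells, n_control_cells = n_control_cells,
    transcripts = list(list(id = "panel", length = L,
                            sequence = random_sequence(L))),
    conformations = list(list(conf1, conf2)),
    weights = list(c(0.5, 0.5)),
    depth_mean = depth_mean, depth_decay = 0, dropout = 0,
    seed = seed, ...)
  list(config = config, truth = truth_window_labels(config))
}

#' Random nested reference structure with a modification profile
#'
#' Generates a well-formed, fully nested random pairing with approximately
#' the requested unpaired fraction (exact to within rounding the pair count
#' to an integer), plus a per-position modification probability vector: 0.08
#' at unpaired positions, 0.01 at paired ones -- the contrast the probe is
#' expected to read out.
#'
#' @param length transcript length.
#' @param unpaired_fraction target fraction of unpaired bases in (0, 1].
#' @param seed integer seed.
#' @param mod_unpaired,mod_paired modification probabilities (defaults 0.08
#'   and 0.01).
#' @return list with `structure` (a [reference_structure]) and
#'   `modification` (numeric vector).
#' @export
make_reference_fixture <- function(length, unpaired_fraction, seed = 1,
                                   mod_unpaired = 0.08, mod_paired = 0.01) {
  if (unpaired_fraction <= 0 || unpaired_fraction > 1)
    stop_validation("unpaired_fraction must be in (0, 1]")
  set.seed(seed)
  n_pairs <- floor((length - round(length * unpaired_fraction)) / 2)
  n_unpaired <- length - 2L * n_pairs
  rec <- function(p, u) {
    if (p == 0) return(strrep(".", u))
    if (u > 0 && stats::runif(1) < u / (u + 2 * p)) {
      paste0(".", rec(p, u - 1L))
    } else {
      p_in <- sample.int(p, 1) - 1L
      u_in <- if (u > 0) stats::rbinom(1, u, 0.5) else 0L
      paste0("(", rec(p_in, u_in), ")", rec(p - 1L - p_in, u - u_in))
    }
  }
  db <- rec(n_pairs, n_unpaired)
  partner <- parse_structure_line(db, "fixture")
  seq_chars <- random_sequence(length)
  structure_obj <- new_reference_structure("fixture", partner,
                                           sequence = seq_chars)
  modification <- ifelse(structure_obj$paired, mod_paired, mod_unpaired)
  list(structure = structure_obj, modification = modification)
}

#' Simulation config for a structure-accuracy benchmark
#'
#' One transcript whose single conformation follows a
#' [make_reference_fixture] structure: pooling the simulated cells into a
#' pseudobulk reactivity profile and scoring it against the structure is the
#' end-to-end accuracy check.
#'
#' @inheritParams make_reference_fixture
#' @param n_cells,n_control_cells,depth_mean,seed simulation settings
#'   (defaults: 40 cells, 1000x flat depth).
#' @param ... further arguments to [sim_config].
#' @return list with `config`, `structure`, `modification`.
#' @export
make_benchmark_config <- function(length = 300, unpaired_fraction = 0.5,
                                  n_cells = 40, n_control_cells = 7,
                                  depth_mean = 1000, seed = 1, ...) {
  fix <- make_reference_fixture(length, unpaired_fraction, seed)
  config <- sim_config(
    n_cells = n_cells, n_control_cells = n_control_cells,
    transcripts = list(list(id = "fixture", length = length,
                            sequence = fix$structure$sequence)),
    conformations = list(list(fix$modification)),
    weights = list(1),
    depth_mean = depth_mean, depth_decay = 0, dropout = 0,
    seed = seed, ...)
  list(config = config, structure = fix$structure,
       modification = fix$modification)
}

#' Demo simulation config
#'
#' Three transcripts emulating a small probed single-cell batch: 40 treated
#' and 7 control cells, 3'-biased overdispersed coverage, 10% dropout, one
#' structurally homogeneous transcript and two with a second conformation in
#' a subset of windows.
#'
#' @param seed integer seed.
#' @return a [sim_config].
#' @export
demo_sim_config <- function(seed = 1) {
  set.seed(seed)
  lengths <- c(tx1 = 1000L, tx2 = 800L, tx3 = 600L)
  transcripts <- lapply(names(lengths), function(id)
    list(id = id, length = lengths[[id]],
         sequence = random_sequence(lengths[[id]])))
  conformations <- list()
  weights <- list()
  for (i in seq_along(lengths)) {
    L <- lengths[[i]]
    base <- stats::runif(L, 0.01, 0.04)
    if (i == 1) {
      conformations[[i]] <- list(base)
      weights[[i]] <- 1
    } else {
      alt <- base
      n_windows <- L %/% 10
      flips <- sample.int(n_windows, round(0.3 * n_windows))
      for (wi in flips) {
        pos <- ((wi - 1) * 10 + 1):((wi - 1) * 10 + 5)
        alt[pos] <- pmin(0.15, base[pos] + 0.05)
      }
      conformations[[i]] <- list(base, alt)
      weights[[i]] <- c(0.5, 0.5)
    }
  }
  sim_config(n_cells = 40, n_control_cells = 7,
             transcripts = transcripts, conformations = conformations,
             weights = weights, seed = seed)
}

#' Simulate a sparse per-cell expression table
#'
#' Companion expression data for QC and stratified analyses: `n_genes`
#' nuclear genes of which each cell detects a random fraction, plus a small
#' mitochondrial gene set whose summed share of the cell's expression is
#' drawn from a Beta distribution centred near 3% (so a minority of cells
#' exceed the 5% QC cutoff). Does not touch the seed: call after seeding
#' (e.g. inside a seeded dataset build) for determinism.
#'
#' @param cells character vector of cell ids.
#' @param n_genes number of nuclear genes (default 8000).
#' @param detect_range range of per-cell detected-gene fractions
#'   (default 0.55-0.90, straddling the 5000-gene cutoff).
#' @param n_mito_genes mitochondrial genes (default 10).
#' @return list with `expression` (an `expression_table`) and `mito_genes`.
#' @export
simulate_expression <- function(cells, n_genes = 8000,
                                detect_range = c(0.55, 0.90),
                                n_mito_genes = 10) {
  genes <- sprintf("g%05d", seq_len(n_genes))
  mito <- sprintf("MT-%02d", seq_len(n_mito_genes))
  rows <- lapply(cells, function(cl) {
    n_det <- round(n_genes * stats::runif(1, detect_range[1],
                                          detect_range[2]))
    det <- sample(genes, n_det)
    vals <- stats::rlnorm(n_det, meanlog = 1, sdlog = 1)
    mito_frac <- stats::rbeta(1, 2.5, 75)  # mean ~3.2%, tail past 5%
    mito_total <- mito_frac / (1 - mito_frac) * sum(vals)
    mito_vals <- as.vector(stats::rmultinom(1, 1000, rep(1, n_mito_genes))) /
      1000 * mito_total
    data.frame(cell_id = cl,
               gene_id = c(det, mito),
               expression = c(vals, mito_vals),
               stringsAsFactors = FALSE)
  })
  list(expression = expression_table(do.call(rbind, rows)),
       mito_genes = mito)
}
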