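# End-to-end orchestration: dataset simulation to disk, the QC ->
# reactivity -> heterogeneity -> enrichment pipeline, and the structure
# benchmark. Everything is file-in/file-out, deterministic under the seed,
# and logged; excluded cells and windows are recorded with reasons, never
# silently dropped.

#' Pipeline thresholds and settings
#'
#' Every analysis threshold is a named parameter with the assay's standard
#' value as default: cells need at least `min_genes` (5000) detected genes
#' and at most `max_mito` (5%) mitochondrial fraction; windows are `window_size`
#' (10) nt, detected above `min_window_reads` (600, strict) total reads in
#' at least `min_cell_fraction` (50%) of cells; enrichment calls features at
#' Bonferroni-adjusted p <= `enrichment_alpha` (0.05).
#'
#' @param min_genes,max_mito cell QC thresholds.
#' @param window_size,min_window_reads,min_cell_fraction window filters.
#' @param min_cells_fit minimum covered cells for a defined window fit.
#' @param enrichment_alpha adjusted-p cutoff for enrichment.
#' @param clamp_negative clamp negative reactivities at 0 (default FALSE).
#' @param seed integer seed for any stochastic step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_genes = 5000, max_mito = 0.05,
                            window_size = 10, min_window_reads = 600,
                            min_cell_fraction = 0.5, min_cells_fit = 4,
                            enrichment_alpha = 0.05,
                            clamp_negative = FALSE, seed = 1) {
  if (min_genes < 0 || max_mito < 0 || window_size < 1 ||
      min_window_reads < 0 || min_cell_fraction < 0 ||
      min_cell_fraction > 1 || enrichment_alpha <= 0)
    stop_validation("invalid pipeline threshold")
  structure(list(min_genes = min_genes, max_mito = max_mito,
                 window_size = window_size,
                 min_window_reads = min_window_reads,
                 min_cell_fraction = min_cell_fraction,
                 min_cells_fit = min_cells_fit,
                 enrichment_alpha = enrichment_alpha,
                 clamp_negative = clamp_negative,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_manifest <- function(out_dir, files) {
  md5 <- tools::md5sum(file.path(out_dir, files))
  write_tsv(data.frame(file = files, md5 = unname(md5),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "manifest.tsv"))
}

#' Verify a dataset or run manifest
#'
#' Recomputes the MD5 digest of every file listed in `manifest.tsv` and
#' fails on any mismatch or missing file.
#'
#' @param dir directory containing `manifest.tsv`.
#' @return TRUE invisibly on success; error on tampering.
#' @export
verify_manifest <- function(dir) {
  mf <- utils::read.delim(file.path(dir, "manifest.tsv"),
                          stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mf))) {
    path <- file.path(dir, mf$file[i])
    if (!file.exists(path))
      stop_validation(sprintf("manifest file missing: %s", mf$file[i]))
    digest <- unname(tools::md5sum(path))
    if (digest != mf$md5[i])
      stop_validation(sprintf("digest mismatch for %s", mf$file[i]))
  }
  invisible(TRUE)
}

#' Simulate a complete demo dataset to disk
#'
#' Writes the count tables, expression table, mitochondrial gene list,
#' region annotation, feature intervals, sequences and ground-truth files
#' for a [sim_config], plus a manifest of MD5 digests. Output is
#' byte-identical for identical config and seed.
#'
#' @param out_dir output directory (created; refuses to overwrite a
#'   nonempty directory unless `force`).
#' @param config a [sim_config]; default [demo_sim_config] under `seed`.
#' @param seed seed used when `config` is not supplied.
#' @param force overwrite an existing nonempty directory.
#' @return invisible character vector of written files.
#' @export
sc_simulate_dataset <- function(out_dir, config = NULL, seed = 1,
                                force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop_usage(sprintf(
      "output directory '%s' exists and is not empty (use force)", out_dir))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- config %||% demo_sim_config(seed)
  sim <- simulate_counts(config)  # seeds the stream from config$seed
  cells <- c(unique(sim$treated$cell_id), unique(sim$control$cell_id))
  expr <- simulate_expression(cells)
  annotation <- region_annotation(do.call(rbind, lapply(
    config$transcripts, function(tx) data.frame(
      transcript_id = tx$id, transcript_length = tx$length,
      cds_start = round(0.2 * tx$length), cds_end = round(0.8 * tx$length),
      stringsAsFactors = FALSE))))
  intervals <- interval_set(do.call(rbind, lapply(
    sprintf("sim_rbp_%d", 1:6), function(f) do.call(rbind, lapply(
      config$transcripts, function(tx) {
        starts <- sort(sample.int(tx$length - 20L, 5))
        data.frame(transcript_id = tx$id, start = starts,
                   end = starts + 20L, feature_name = f,
                   stringsAsFactors = FALSE)
      })))))
  sequences <- stats::setNames(
    vapply(config$transcripts, `[[`, "", "sequence"),
    vapply(config$transcripts, `[[`, "", "id"))
  files <- c("treated_counts.tsv", "control_counts.tsv", "expression.tsv",
             "mito_genes.txt", "annotation.tsv", "intervals.bed",
             "sequences.tsv", "truth_window_labels.tsv",
             "truth_cell_conformations.tsv")
  write_base_counts(sim$treated, file.path(out_dir, "treated_counts.tsv"))
  write_base_counts(sim$control, file.path(out_dir, "control_counts.tsv"))
  write_expression_table(expr$expression, file.path(out_dir, "expression.tsv"))
  writeLines(expr$mito_genes, file.path(out_dir, "mito_genes.txt"))
  write_region_annotation(annotation, file.path(out_dir, "annotation.tsv"))
  write_intervals_bed(intervals, file.path(out_dir, "intervals.bed"))
  write_sequences(sequences, file.path(out_dir, "sequences.tsv"))
  write_tsv(sim$truth$window_labels,
            file.path(out_dir, "truth_window_labels.tsv"))
  write_tsv(sim$truth$cell_conformations,
            file.path(out_dir, "truth_cell_conformations.tsv"))
  write_manifest(out_dir, files)
  invisible(c(files, "manifest.tsv"))
}

#' Run the analysis pipeline on count tables
#'
#' Stages, in order: cell QC (when an expression table is given), pseudobulk
#' reactivity per transcript (SHAPE files), window-level heterogeneity
#' (tiling, 600-read/50%-cell detection, adjusted R^2), gene-level
#' heterogeneity (quantile normalization, cosine dispersion), quartile
#' classification, and feature enrichment of the heterogeneous window class
#' (when intervals are given). Outputs are TSVs under `out_dir` plus a run
#' log and an MD5 manifest; reruns with identical inputs and seed are
#' digest-identical.
#'
#' @param counts_treated,counts_control paths to base-count TSVs (the
#'   control/DMSO channel is required: reactivity is defined as a
#'   background-subtracted rate).
#' @param out_dir output directory.
#' @param expression optional path to an expression TSV (enables QC).
#' @param mito_genes optional path to a text file of mitochondrial gene ids
#'   (one per line), or a character vector.
#' @param annotation optional path to a region-annotation TSV.
#' @param intervals optional path to a feature BED.
#' @param sequences optional path to a sequence TSV.
#' @param config a [pipeline_config].
#' @return invisible list of the main result data.frames.
#' @export
sc_run <- function(counts_treated, counts_control, out_dir,
                   expression = NULL, mito_genes = NULL, annotation = NULL,
                   intervals = NULL, sequences = NULL,
                   config = pipeline_config()) {
  if (is.null(counts_control))
    stop_usage("control counts are required: the DMSO channel defines the background subtracted from treated rates")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("package scstructr %s",
            as.character(utils::packageVersion("scstructr"))),
    sprintf("seed %d", config$seed),
    sprintf("thresholds min_genes=%g max_mito=%g window_size=%d min_window_reads=%g min_cell_fraction=%g min_cells_fit=%d enrichment_alpha=%g",
            config$min_genes, config$max_mito, config$window_size,
            config$min_window_reads, config$min_cell_fraction,
            config$min_cells_fit, config$enrichment_alpha))
  logmsg <- function(...) log_lines <<- c(log_lines, sprintf(...))

  treated <- read_base_counts(counts_treated)
  control <- read_base_counts(counts_control)
  treated_cells <- sort(unique(treated$cell_id))
  control_cells <- sort(unique(control$cell_id))
  files <- character(0)

  # --- cell QC -------------------------------------------------------------
  if (!is.null(expression)) {
    expr <- read_expression_table(expression)
    mito <- if (is.character(mito_genes) && length(mito_genes) == 1 &&
                file.exists(mito_genes)) readLines(mito_genes)
            else mito_genes
    if (is.null(mito)) stop_usage("mito_genes required when expression given")
    qc <- cell_qc(expr, mito, cells = c(treated_cells, control_cells),
                  min_genes = config$min_genes, max_mito = config$max_mito)
    write_tsv(qc, file.path(out_dir, "qc.tsv"))
    files <- c(files, "qc.tsv")
    for (cl in qc$cell_id[!qc$passed])
      logmsg("EXCLUDED cell %s reason=qc genes=%d mito=%.4f", cl,
             qc$genes_detected[qc$cell_id == cl],
             qc$mito_fraction[qc$cell_id == cl])
    treated_cells <- intersect(treated_cells, qc$cell_id[qc$passed])
    control_cells <- intersect(control_cells, qc$cell_id[qc$passed])
  }
  if (length(treated_cells) == 0 || length(control_cells) == 0)
    stop_validation("no cells survive QC in one of the channels")
  logmsg("cells treated=%d control=%d", length(treated_cells),
         length(control_cells))

  ann <- if (!is.null(annotation)) read_region_annotation(annotation)
  ivs <- if (!is.null(intervals)) read_intervals_bed(intervals)
  seqs <- if (!is.null(sequences)) read_sequences(sequences)

  transcripts <- sort(unique(treated$transcript_id))

  # --- pseudobulk reactivity ----------------------------------------------
  pb_profiles <- list()
  for (tx in transcripts) {
    pb_t <- pseudobulk(treated, treated_cells, "treated", tx)
    pb_c <- pseudobulk(control, control_cells, "control", tx,
                       transcript_length = length(pb_t$rate))
    prof <- compute_reactivity(pb_t, pb_c, clamp = config$clamp_negative)
    pb_profiles[[tx]] <- prof
    f <- sprintf("reactivity_%s.shape", tx)
    write_shape(prof, file.path(out_dir, f))
    files <- c(files, f)
  }

  # --- window-level heterogeneity -----------------------------------------
  win_tabs <- lapply(transcripts, function(tx) {
    wt <- window_table(treated, tx, window_size = config$window_size,
                       cells = treated_cells,
                       min_total_reads = config$min_window_reads,
                       min_cell_fraction = config$min_cell_fraction,
                       min_cells = config$min_cells_fit)
    if (!is.null(ann) && tx %in% ann$transcript_id && nrow(wt) > 0)
      wt$region <- as.character(assign_region(wt$transcript_id,
                                              wt$window_start,
                                              wt$window_end, ann))
    else if (nrow(wt) > 0) wt$region <- NA_character_
    if (nrow(wt) > 0) {
      pr <- pb_profiles[[tx]]$reactivity
      wt$mean_reactivity <- vapply(seq_len(nrow(wt)), function(i) {
        seg <- pr[(wt$window_start[i] + 1):wt$window_end[i]]
        if (all(is.na(seg))) NA_real_ else mean(seg, na.rm = TRUE)
      }, 0)
      wt$gc <- if (!is.null(seqs) && tx %in% names(seqs))
        vapply(seq_len(nrow(wt)), function(i)
          mean(strsplit(substr(seqs[[tx]], wt$window_start[i] + 1,
                               wt$window_end[i]), "")[[1]] %in% c("G", "C")),
          0)
      else NA_real_
    } else {
      wt$region <- character(0)
      wt$mean_reactivity <- numeric(0)
      wt$gc <- numeric(0)
    }
    wt
  })
  windows <- do.call(rbind, win_tabs)
  for (i in which(!windows$detected))
    logmsg("EXCLUDED window %s:%d-%d reason=not_detected reads=%g cells=%d",
           windows$transcript_id[i], windows$window_start[i],
           windows$window_end[i], windows$total_reads[i],
           windows$n_cells_detected[i])

  usable <- windows$detected & windows$defined
  windows$class <- NA_character_
  if (sum(usable) >= 4) {
    # adjusted R^2 is a homogeneity score: negate so the bottom quartile of
    # the classified value is the homogeneous class
    cls <- classify_quantiles(-windows$adj_r_squared[usable])
    windows$class[usable] <- as.character(cls)
  }
  write_tsv(windows, file.path(out_dir, "windows.tsv"))
  files <- c(files, "windows.tsv")

  # --- gene-level heterogeneity -------------------------------------------
  gene_rows <- list()
  for (tx in transcripts) {
    n <- length(pb_profiles[[tx]]$reactivity)
    ctrl_pb <- pseudobulk(control, control_cells, "control", tx,
                          transcript_length = n)
    profs <- lapply(treated_cells, function(cl) {
      tr <- mutation_rate(treated, cl, "treated", tx, transcript_length = n)
      compute_reactivity(tr, ctrl_pb, clamp = config$clamp_negative)
    })
    names(profs) <- treated_cells
    mat <- do.call(rbind, lapply(profs, function(p) p$reactivity))
    mat <- rbind(mat, pseudo = pb_profiles[[tx]]$reactivity)
    res <- tryCatch({
      qn <- suppressWarnings(quantile_normalize(mat))
      cell_profiles <- lapply(seq_len(nrow(qn) - 1),
                              function(i) qn[i, ])
      names(cell_profiles) <- rownames(mat)[-nrow(mat)]
      suppressWarnings(gene_heterogeneity(cell_profiles, qn[nrow(qn), ]))
    }, scstructr_error = function(e) e)
    if (inherits(res, "error")) {
      logmsg("EXCLUDED transcript %s reason=gene_heterogeneity: %s", tx,
             conditionMessage(res))
    } else {
      gene_rows[[tx]] <- data.frame(transcript_id = tx, n = res$n,
                                    heterogeneity = res$heterogeneity,
                                    stringsAsFactors = FALSE)
    }
  }
  genes <- if (length(gene_rows) > 0) do.call(rbind, gene_rows) else
    data.frame(transcript_id = character(0), n = integer(0),
               heterogeneity = numeric(0))
  rownames(genes) <- NULL
  if (nrow(genes) >= 4)
    genes$class <- as.character(classify_quantiles(genes$heterogeneity))
  write_tsv(genes, file.path(out_dir, "genes.tsv"))
  files <- c(files, "genes.tsv")

  # --- enrichment ----------------------------------------------------------
  enrich <- NULL
  if (!is.null(ivs)) {
    bg <- windows[usable, , drop = FALSE]
    interest <- bg[!is.na(bg$class) & bg$class == "heterogeneous", ,
                   drop = FALSE]
    if (nrow(interest) > 0 && nrow(bg) > 0) {
      enrich <- hypergeometric_enrichment(interest, bg, ivs,
                                          alpha = config$enrichment_alpha)
      write_tsv(enrich, file.path(out_dir, "enrichment.tsv"))
      files <- c(files, "enrichment.tsv")
    } else {
      logmsg("enrichment skipped: no heterogeneous windows")
    }
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  files <- c(files, "run_log.txt")
  write_manifest(out_dir, files)
  invisible(list(windows = windows, genes = genes, enrichment = enrich,
                 profiles = pb_profiles, log = log_lines))
}

#' Benchmark reactivity profiles against reference structures
#'
#' For every transcript present both as a SHAPE profile and a reference
#' structure: label positions (optionally filtered by solvent
#' accessibility), compute the ROC curve and AUC, and run the
#' paired-vs-unpaired rank-sum test. Writes `benchmark_summary.tsv` and
#' `roc_points.tsv`.
#'
#' @param shape_paths named character vector of SHAPE file paths (names =
#'   transcript ids).
#' @param structures path to a dot-bracket file (`.db`/`.dot`/anything not
#'   ending in `.ct`) or a CT file (`.ct`).
#' @param out_dir output directory.
#' @param accessibility optional named list/vector of accessibility TSV
#'   paths per transcript; transcripts without one use all bases.
#' @param accessibility_threshold inclusion cutoff (default 3).
#' @return invisible data.frame summary (transcript, n_true, n_false, auc,
#'   mw_p, accessibility_filtered).
#' @export
sc_benchmark <- function(shape_paths, structures, out_dir,
                         accessibility = NULL,
                         accessibility_threshold = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  structs <- if (grepl("\\.ct$", structures)) {
    s <- read_ct(structures)
    stats::setNames(list(s), s$transcript_id)
  } else {
    s <- read_dot_bracket(structures)
    if (inherits(s, "reference_structure"))
      stats::setNames(list(s), s$transcript_id)
    else s
  }
  shared <- intersect(names(shape_paths), names(structs))
  if (length(shared) == 0)
    stop_validation("no overlapping transcripts between profiles and structures")
  summary_rows <- list()
  roc_rows <- list()
  for (tx in shared) {
    prof <- read_shape(shape_paths[[tx]], transcript_id = tx)
    st <- structs[[tx]]
    filtered <- FALSE
    if (!is.null(accessibility) && tx %in% names(accessibility)) {
      st$solvent_accessibility <- read_accessibility(accessibility[[tx]])
      filtered <- TRUE
    }
    labels <- label_positions(st, accessibility_threshold)
    roc <- roc_auc(prof, labels)
    mw <- paired_unpaired_test(prof, labels)
    summary_rows[[tx]] <- data.frame(
      transcript_id = tx, n_true = roc$n_true, n_false = roc$n_false,
      auc = roc$auc, mw_p = mw$p, accessibility_filtered = filtered,
      stringsAsFactors = FALSE)
    roc_rows[[tx]] <- cbind(transcript_id = tx, roc$curve)
  }
  summary_df <- do.call(rbind, summary_rows)
  rownames(summary_df) <- NULL
  write_tsv(summary_df, file.path(out_dir, "benchmark_summary.tsv"))
  write_tsv(do.call(rbind, roc_rows), file.path(out_dir, "roc_points.tsv"))
  invisible(summary_df)
}
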