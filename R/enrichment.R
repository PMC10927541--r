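# Feature/RBP enrichment over window classes and expression-stratified
# reactivity comparisons.

window_key <- function(df) {
  paste(df$transcript_id, df$window_start, df$window_end, sep = ":")
}

#' Overlap windows with feature intervals
#'
#' A window overlaps a feature when the half-open interval intersection on
#' the same transcript is nonempty (`start < window_end` and
#' `end > window_start`).
#'
#' @param windows data.frame with transcript_id, window_start, window_end.
#' @param intervals an `interval_set` data.frame.
#' @return logical matrix, one row per window, one column per feature.
#' @export
overlap_windows <- function(windows, intervals) {
  features <- sort(unique(intervals$feature_name))
  out <- matrix(FALSE, nrow = nrow(windows), ncol = length(features),
                dimnames = list(window_key(windows), features))
  for (f in features) {
    iv <- intervals[intervals$feature_name == f, ]
    for (w in seq_len(nrow(windows))) {
      hit <- iv$transcript_id == windows$transcript_id[w] &
        iv$start < windows$window_end[w] &
        iv$end > windows$window_start[w]
      out[w, f] <- any(hit)
    }
  }
  out
}

#' Hypergeometric feature enrichment of a window class
#'
#' For each feature: population = background windows (N), successes =
#' background windows overlapping the feature (K), draws = interest windows
#' (n), observed = interest windows overlapping the feature (k). The
#' one-sided upper-tail p-value P(X >= k) is Bonferroni-adjusted across the
#' features tested in this call; a feature is enriched when the adjusted
#' p <= `alpha`. Set `depletion = TRUE` for the lower tail P(X <= k)
#' instead.
#'
#' @param interest data.frame of interest windows; must be a subset of
#'   `background` (matched on transcript/start/end).
#' @param background data.frame of all candidate windows.
#' @param intervals an `interval_set`.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param depletion test the lower tail instead (default FALSE).
#' @return data.frame with feature_name, k, K, n, N, p_value, adj_p,
#'   enriched.
#' @export
hypergeometric_enrichment <- function(interest, background, intervals,
                                      alpha = 0.05, depletion = FALSE) {
  if (nrow(background) == 0) stop_validation("background is empty")
  if (!all(window_key(interest) %in% window_key(background)))
    stop_validation("interest windows must be a subset of the background")
  ov_bg <- overlap_windows(background, intervals)
  ov_in <- ov_bg[window_key(background) %in% window_key(interest), ,
                 drop = FALSE]
  N <- nrow(background)
  n <- nrow(interest)
  features <- colnames(ov_bg)
  K <- colSums(ov_bg)
  k <- colSums(ov_in)
  p <- vapply(seq_along(features), function(i) {
    if (depletion) stats::phyper(k[i], K[i], N - K[i], n)
    else stats::phyper(k[i] - 1, K[i], N - K[i], n, lower.tail = FALSE)
  }, 0)
  adj <- stats::p.adjust(p, method = "bonferroni")
  data.frame(feature_name = features, k = as.integer(k), K = as.integer(K),
             n = n, N = N, p_value = p, adj_p = adj,
             enriched = adj <= alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Bin cells into expression quartiles for a gene
#'
#' Cells are ranked by the gene's expression (ties broken by cell id for a
#' stable, reproducible split) and divided into four consecutive bins
#' q1 (lowest) to q4 (highest) whose sizes differ by at most one (the lower
#' bins take the remainder).
#'
#' @param expression an `expression_table`.
#' @param gene gene id to stratify on.
#' @param cells cells to bin; default all cells carrying the gene. At least
#'   8 required.
#' @return factor (levels q1..q4) named by cell id.
#' @export
rbp_quartile_bins <- function(expression, gene, cells = NULL) {
  e <- expression[expression$gene_id == gene, ]
  if (nrow(e) == 0)
    stop_lookup(sprintf("gene '%s' absent from expression table", gene))
  if (!is.null(cells)) {
    missing_cells <- setdiff(cells, e$cell_id)
    if (length(missing_cells) > 0)
      stop_lookup(sprintf("no '%s' expression for cell '%s'", gene,
                          missing_cells[1]))
    e <- e[e$cell_id %in% cells, ]
  }
  n <- nrow(e)
  if (n < 8)
    stop_validation(sprintf("quartile binning needs >= 8 cells (have %d)", n))
  if (length(unique(e$expression)) == 1)
    warning("all cells have equal expression; split is by cell id only")
  o <- order(e$expression, e$cell_id)
  sizes <- n %/% 4 + (seq_len(4) <= n %% 4)
  bins <- rep(paste0("q", 1:4), times = sizes)
  stats::setNames(factor(bins, levels = paste0("q", 1:4)), e$cell_id[o])
}

#' Reactivity change between expression quartiles
#'
#' For each target window, the per-cell window reactivity (the cell's window
#' mutation rate in the treated channel minus the control pseudobulk rate
#' over the window) is compared between cells in the top (q4) and bottom
#' (q1) expression quartiles: log2 fold change of the bin means with a
#' pseudocount guarding near-zero and negative means, and a two-sided Welch
#' t-test on the per-cell values.
#'
#' @param counts a [base_counts] table with treated and control records.
#' @param bins factor from [rbp_quartile_bins], named by cell.
#' @param target_windows data.frame with transcript_id, window_start,
#'   window_end.
#' @param pseudocount added to both means inside the log ratio
#'   (default 0.01); windows where a shifted mean is still nonpositive are
#'   skipped.
#' @param min_cells minimum cells with defined window reactivity per bin
#'   (default 3).
#' @return data.frame with one row per window: bin means, log2fc, t, p,
#'   skipped, reason.
#' @export
stratified_reactivity_change <- function(counts, bins, target_windows,
                                         pseudocount = 0.01, min_cells = 3) {
  q1_cells <- names(bins)[bins == "q1"]
  q4_cells <- names(bins)[bins == "q4"]
  ctrl_cells <- unique(counts$cell_id[counts$condition == "control"])
  rows <- lapply(seq_len(nrow(target_windows)), function(i) {
    tw <- target_windows[i, ]
    base <- data.frame(transcript_id = tw$transcript_id,
                       window_start = tw$window_start,
                       window_end = tw$window_end,
                       mean_q1 = NA_real_, mean_q4 = NA_real_,
                       log2fc = NA_real_, t = NA_real_, p = NA_real_,
                       skipped = TRUE, reason = NA_character_,
                       stringsAsFactors = FALSE)
    sel <- counts$transcript_id == tw$transcript_id &
      counts$position >= tw$window_start & counts$position < tw$window_end
    sub <- counts[sel, ]
    ctrl <- sub[sub$condition == "control", ]
    ctrl_rate <- if (nrow(ctrl) > 0 && sum(ctrl$coverage) > 0)
      sum(ctrl$mutated) / sum(ctrl$coverage) else 0
    cell_react <- function(cl) {
      s <- sub[sub$condition == "treated" & sub$cell_id == cl, ]
      if (nrow(s) == 0 || sum(s$coverage) == 0) return(NA_real_)
      sum(s$mutated) / sum(s$coverage) - ctrl_rate
    }
    v1 <- stats::na.omit(vapply(q1_cells, cell_react, 0))
    v4 <- stats::na.omit(vapply(q4_cells, cell_react, 0))
    if (length(v1) < min_cells || length(v4) < min_cells) {
      base$reason <- sprintf("insufficient cells (q1: %d, q4: %d)",
                             length(v1), length(v4))
      return(base)
    }
    m1 <- mean(v1); m4 <- mean(v4)
    base$mean_q1 <- m1; base$mean_q4 <- m4
    if (m1 + pseudocount <= 0 || m4 + pseudocount <= 0) {
      base$reason <- "nonpositive shifted mean"
      return(base)
    }
    base$log2fc <- log2((m4 + pseudocount) / (m1 + pseudocount))
    if (stats::var(v1) == 0 && stats::var(v4) == 0) {
      # degenerate but well-defined: identical constants are a null result,
      # distinct constants an (unattainably) extreme one
      base$t <- if (m1 == m4) 0 else sign(m4 - m1) * Inf
      base$p <- if (m1 == m4) 1 else 0
    } else {
      tt <- stats::t.test(v4, v1, var.equal = FALSE)
      base$t <- unname(tt$statistic)
      base$p <- tt$p.value
    }
    base$skipped <- FALSE
    base
  })
  do.call(rbind, rows)
}

#' Compare two groups of values by a two-sided Mann-Whitney U test
#'
#' The same rank-sum engine used for the paired/unpaired comparison, applied
#' to arbitrary grouped values (e.g. half-lives of transcripts classed by
#' heterogeneity change). Exact enumeration when both groups have at most 8
#' values; tie-corrected normal approximation otherwise.
#'
#' @param values_a,values_b numeric vectors, each of length >= 3.
#' @return list with U (a vs b), p, group sizes, method.
#' @export
halflife_group_compare <- function(values_a, values_b) {
  if (length(values_a) < 3 || length(values_b) < 3)
    stop_validation("both groups need >= 3 values")
  mann_whitney(values_a, values_b)
}
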