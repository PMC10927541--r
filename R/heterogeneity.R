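# Window- and gene-level structural heterogeneity statistics, quantile
# classification, region assignment, metagene enrichment, and trajectory
# clustering.
#
# The window statistic: per 10-nt window, regress the per-cell mutated read
# count against the per-cell coverage (OLS with intercept). If every cell
# modifies the window at the same rate, the points fall on a line through
# the cloud and R^2 is near 1 (homogeneous); cell-to-cell differences in
# modification rate scatter the points and push R^2 toward 0
# (heterogeneous). Adjusted R^2 corrects for the number of cells observed.

# ---------------------------------------------------------------------------
# Window tiling and filtering

#' Tile a transcript into fixed non-overlapping windows
#'
#' Windows of `window_size` nt from position 0; a trailing partial window is
#' dropped. For each window and each cell, coverage and mutated counts are
#' summed over the window's positions (uncovered positions contribute 0).
#'
#' @param counts a [base_counts] table.
#' @param transcript_id transcript to tile.
#' @param transcript_length optional; inferred from the counts when absent.
#' @param window_size window length in nt (default 10).
#' @param condition which channel to aggregate (default `"treated"`).
#' @param cells cells defining the columns; default: all cells of that
#'   condition present in the count table.
#' @return list of `window_counts` objects (fields: transcript_id,
#'   window_start, window_end, cells, depth, mutant).
#' @export
tile_windows <- function(counts, transcript_id, transcript_length = NULL,
                         window_size = 10, condition = "treated",
                         cells = NULL) {
  if (!is_count(window_size))
    stop_validation("window_size must be a positive integer")
  n <- transcript_len(counts, transcript_id, transcript_length)
  n_windows <- n %/% window_size
  if (is.null(cells))
    cells <- sort(unique(counts$cell_id[counts$condition == condition]))
  if (n_windows == 0) return(list())
  sel <- counts$transcript_id == transcript_id &
    counts$condition == condition & counts$cell_id %in% cells &
    counts$position < n_windows * window_size
  sub <- counts[sel, ]
  win <- sub$position %/% window_size
  depth <- matrix(0, nrow = length(cells), ncol = n_windows,
                  dimnames = list(cells, NULL))
  mutant <- depth
  if (nrow(sub) > 0) {
    ci <- match(sub$cell_id, cells)
    idx <- cbind(ci, win + 1L)
    depth_s <- rowsum(sub$coverage, paste(ci, win))
    # rowsum keyed aggregation: decode keys back to (cell, window)
    keys <- do.call(rbind, strsplit(rownames(depth_s), " "))
    depth[cbind(as.integer(keys[, 1]), as.integer(keys[, 2]) + 1L)] <-
      depth_s[, 1]
    mut_s <- rowsum(sub$mutated, paste(ci, win))
    mutant[cbind(as.integer(keys[, 1]), as.integer(keys[, 2]) + 1L)] <-
      mut_s[, 1]
  }
  lapply(seq_len(n_windows), function(w) {
    structure(list(transcript_id = transcript_id,
                   window_start = (w - 1L) * window_size,
                   window_end = w * window_size,
                   cells = cells,
                   depth = unname(depth[, w]),
                   mutant = unname(mutant[, w])),
              class = "window_counts")
  })
}

#' Flag detected windows
#'
#' A window is detected in a cell when that cell has any coverage in it; a
#' window is detected overall when its total coverage is strictly greater
#' than `min_total_reads` (default 600) and it is detected in at least
#' `min_cell_fraction` (default 50%) of the cells.
#'
#' @param windows list of `window_counts` from [tile_windows].
#' @param min_total_reads total-coverage cutoff (strict; default 600).
#' @param min_cell_fraction minimum detected-cell fraction (default 0.5).
#' @param total_cells denominator for the cell fraction; default: number of
#'   cells carried by the windows.
#' @return the windows, each with `n_cells_detected`, `total_reads` and
#'   `detected` fields added.
#' @export
filter_windows <- function(windows, min_total_reads = 600,
                           min_cell_fraction = 0.5, total_cells = NULL) {
  lapply(windows, function(w) {
    tc <- total_cells %||% length(w$cells)
    if (tc < 1) stop_validation("total_cells must be >= 1")
    w$n_cells_detected <- sum(w$depth > 0)
    w$total_reads <- sum(w$depth)
    w$detected <- (w$total_reads > min_total_reads) &&
      (w$n_cells_detected / tc >= min_cell_fraction)
    w
  })
}

# ---------------------------------------------------------------------------
# Window-level heterogeneity (adjusted R^2)

#' Window-level structural heterogeneity
#'
#' Fits mutant(c) = mod * depth(c) + intercept + eps by ordinary least
#' squares over the cells with coverage in the window. R^2 is the squared
#' Pearson correlation of mutant and depth; the heterogeneity measure is the
#' adjusted R^2, 1 - (1 - R^2)(n - 1)/(n - 2) (one predictor). Higher values
#' mean a more homogeneous window. The slope is the fitted per-read
#' modification rate.
#'
#' Degenerate inputs are flagged (`defined = FALSE` with a reason), never
#' silently coerced to 0 or 1: fewer than `min_cells` covered cells, or zero
#' variance in depth. A window whose mutant counts have zero variance (e.g.
#' all zero) gets R^2 = 0: the fit explains nothing.
#'
#' @param window a `window_counts` object, or a list with numeric `depth`
#'   and `mutant` vectors.
#' @param min_cells minimum covered cells for a defined fit (default 4).
#' @return list with n_cells, fitted_modification_rate (slope), intercept,
#'   r_squared, adj_r_squared, residuals, defined, reason.
#' @export
window_heterogeneity <- function(window, min_cells = 4) {
  keep <- window$depth > 0
  d <- window$depth[keep]
  m <- window$mutant[keep]
  n <- length(d)
  undefined <- function(reason) list(
    transcript_id = window$transcript_id %||% NA_character_,
    window_start = window$window_start %||% NA_integer_,
    window_end = window$window_end %||% NA_integer_,
    n_cells = n, fitted_modification_rate = NA_real_,
    intercept = NA_real_, r_squared = NA_real_, adj_r_squared = NA_real_,
    residuals = NULL, defined = FALSE, reason = reason)
  if (n < min_cells) return(undefined(sprintf("n_cells %d < %d", n, min_cells)))
  if (stats::var(d) == 0) return(undefined("zero variance in depth"))
  if (stats::var(m) == 0) {
    slope <- 0; intercept <- mean(m); r2 <- 0
  } else {
    slope <- stats::cov(m, d) / stats::var(d)
    intercept <- mean(m) - slope * mean(d)
    r2 <- stats::cor(m, d)^2
  }
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  list(transcript_id = window$transcript_id %||% NA_character_,
       window_start = window$window_start %||% NA_integer_,
       window_end = window$window_end %||% NA_integer_,
       n_cells = n, fitted_modification_rate = slope,
       intercept = intercept, r_squared = r2, adj_r_squared = adj,
       residuals = m - (intercept + slope * d), defined = TRUE,
       reason = NA_character_)
}

#' Window heterogeneity table for a transcript
#'
#' Convenience wrapper: tile, flag detection, and fit every window,
#' returning one data.frame row per window.
#'
#' @inheritParams tile_windows
#' @inheritParams filter_windows
#' @param min_cells passed to [window_heterogeneity].
#' @return data.frame with window coordinates, detection flags and fit
#'   statistics.
#' @export
window_table <- function(counts, transcript_id, transcript_length = NULL,
                         window_size = 10, condition = "treated",
                         cells = NULL, min_total_reads = 600,
                         min_cell_fraction = 0.5, min_cells = 4) {
  wins <- filter_windows(
    tile_windows(counts, transcript_id, transcript_length, window_size,
                 condition, cells),
    min_total_reads, min_cell_fraction)
  if (length(wins) == 0) return(empty_window_table())
  rows <- lapply(wins, function(w) {
    h <- window_heterogeneity(w, min_cells)
    data.frame(transcript_id = w$transcript_id,
               window_start = w$window_start, window_end = w$window_end,
               n_cells = h$n_cells, n_cells_detected = w$n_cells_detected,
               total_reads = w$total_reads, detected = w$detected,
               slope = h$fitted_modification_rate,
               r_squared = h$r_squared, adj_r_squared = h$adj_r_squared,
               defined = h$defined, reason = h$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

empty_window_table <- function() {
  data.frame(transcript_id = character(0), window_start = integer(0),
             window_end = integer(0), n_cells = integer(0),
             n_cells_detected = integer(0), total_reads = numeric(0),
             detected = logical(0), slope = numeric(0),
             r_squared = numeric(0), adj_r_squared = numeric(0),
             defined = logical(0), reason = character(0),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Gene-level heterogeneity (cosine dispersion)

#' Gene-level structural heterogeneity
#'
#' For each cell i, the cosine distance of its (quantile-normalized)
#' reactivity profile to the pseudobulk profile,
#' D_i = 1 - (R_i . R_pseudo) / (||R_i|| ||R_pseudo||), computed over the
#' positions unmasked in both; the gene-level heterogeneity is the
#' root-mean-square dispersion sqrt(sum(D_i^2) / n). Quantile-normalize the
#' per-cell profiles first (see [quantile_normalize]); this function does
#' not do it for you.
#'
#' @param profiles list of [reactivity_profile]s or numeric vectors
#'   (NA = masked), one per cell.
#' @param pseudobulk_profile the pseudobulk [reactivity_profile] or numeric
#'   vector.
#' @param min_shared minimum positions a cell must share with the pseudobulk
#'   (default 10); cells below are dropped with a warning.
#' @return list with transcript_id, cell distances `D`, `n`, `heterogeneity`.
#' @export
gene_heterogeneity <- function(profiles, pseudobulk_profile,
                               min_shared = 10) {
  pb <- if (inherits(pseudobulk_profile, "reactivity_profile"))
    pseudobulk_profile$reactivity else as.numeric(pseudobulk_profile)
  tid <- if (inherits(pseudobulk_profile, "reactivity_profile"))
    pseudobulk_profile$transcript_id else "tx"
  vals <- lapply(profiles, function(p)
    if (inherits(p, "reactivity_profile")) p$reactivity else as.numeric(p))
  nms <- names(profiles) %||% as.character(seq_along(profiles))
  D <- c(); used <- character(0)
  dropped <- character(0)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (length(v) != length(pb))
      stop_validation("profile and pseudobulk lengths differ")
    ok <- !is.na(v) & !is.na(pb)
    if (sum(ok) < min_shared) { dropped <- c(dropped, nms[i]); next }
    x <- v[ok]; y <- pb[ok]
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) { dropped <- c(dropped, nms[i]); next }
    D <- c(D, 1 - sum(x * y) / (nx * ny))
    used <- c(used, nms[i])
  }
  if (length(dropped) > 0)
    warning(sprintf("excluded %d cell(s) (too few shared positions or zero norm): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  if (length(D) < 2)
    stop_validation("fewer than 2 usable cells for gene heterogeneity")
  names(D) <- used
  list(transcript_id = tid, D = D, n = length(D),
       heterogeneity = sqrt(mean(D^2)))
}

# ---------------------------------------------------------------------------
# Quantile classification and regions

#' Classify values into homogeneity quartile classes
#'
#' Bottom quartile -> `homogeneous`, top quartile -> `heterogeneous`, the
#' middle half -> `intermediate`. Quartile boundaries use the
#' linear-interpolation percentile (R type 7); values tied with a boundary
#' go to the extreme class. If the two boundaries coincide (all values
#' equal) everything is `intermediate`, with a warning.
#'
#' Note the orientation is that of the value supplied: for gene-level
#' cosine dispersion low values are homogeneous; for window adjusted R^2
#' (where high = homogeneous) pass the negated value or relabel.
#'
#' @param values numeric vector, length >= 4.
#' @return factor with levels homogeneous, intermediate, heterogeneous.
#' @export
classify_quantiles <- function(values) {
  if (length(values) < 4)
    stop_validation("quantile classification needs >= 4 items")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE,
                       na.rm = FALSE)
  if (q[1] == q[2]) {
    warning("degenerate input: quartile boundaries coincide; all classed intermediate")
    return(factor(rep("intermediate", length(values)),
                  levels = c("homogeneous", "intermediate", "heterogeneous")))
  }
  cls <- ifelse(values <= q[1], "homogeneous",
                ifelse(values >= q[2], "heterogeneous", "intermediate"))
  factor(cls, levels = c("homogeneous", "intermediate", "heterogeneous"))
}

#' Assign windows to transcript regions
#'
#' The region (5'UTR, CDS, 3'UTR) of the window midpoint
#' floor((start + end)/2), against the half-open CDS interval
#' [cds_start, cds_end).
#'
#' @param transcript_id character vector of window transcripts.
#' @param window_start,window_end integer vectors (0-based half-open).
#' @param annotation a `region_annotation` data.frame.
#' @return factor with levels five_prime_utr, cds, three_prime_utr.
#' @export
assign_region <- function(transcript_id, window_start, window_end,
                          annotation) {
  i <- match(transcript_id, annotation$transcript_id)
  if (anyNA(i))
    stop_lookup(sprintf("no region annotation for transcript '%s'",
                        transcript_id[which(is.na(i))[1]]))
  mid <- (window_start + window_end) %/% 2L
  if (any(mid < 0 | mid >= annotation$transcript_length[i]))
    stop_validation("window midpoint outside transcript bounds")
  reg <- ifelse(mid < annotation$cds_start[i], "five_prime_utr",
                ifelse(mid < annotation$cds_end[i], "cds",
                       "three_prime_utr"))
  factor(reg, levels = c("five_prime_utr", "cds", "three_prime_utr"))
}

# ---------------------------------------------------------------------------
# Metagene enrichment

#' Metagene density of a window class around the start or stop codon
#'
#' Each window's midpoint is expressed relative to the anchor (the CDS start
#' for `start_codon`, the CDS end for `stop_codon`) and scaled by the length
#' of the flanking region it falls in, so positions run from -1 (far
#' upstream) to +1 (far downstream). Windows are histogrammed into `n_bins`
#' bins; per bin, enrichment of the interest set over the background is an
#' upper-tail (one-sided) hypergeometric test: population = all windows,
#' successes = interest windows, draws = windows in the bin.
#'
#' @param interest data.frame of windows of interest (transcript_id,
#'   window_start, window_end); must be a subset of `all_windows`.
#' @param all_windows data.frame of all (background) windows.
#' @param annotation a `region_annotation`.
#' @param anchor `"start_codon"` or `"stop_codon"`.
#' @param n_bins number of bins spanning [-1, 1] (default 20).
#' @return data.frame per bin: bin mid, counts, densities, p (upper-tail
#'   hypergeometric; empty bins get density 0 and p 1).
#' @export
metagene_enrichment <- function(interest, all_windows, annotation,
                                anchor = c("start_codon", "stop_codon"),
                                n_bins = 20) {
  anchor <- match.arg(anchor)
  if (nrow(interest) == 0 || nrow(all_windows) == 0)
    stop_validation("interest and background window sets must be nonempty")
  rel_pos <- function(df) {
    i <- match(df$transcript_id, annotation$transcript_id)
    if (anyNA(i)) stop_lookup("window transcript missing from annotation")
    a <- if (anchor == "start_codon") annotation$cds_start[i]
         else annotation$cds_end[i]
    len <- annotation$transcript_length[i]
    mid <- (df$window_start + df$window_end) %/% 2L
    off <- mid - a
    up <- pmax(a, 1L)            # upstream flank length
    down <- pmax(len - a, 1L)    # downstream flank length
    pmin(1, pmax(-1, ifelse(off < 0, off / up, off / down)))
  }
  edges <- seq(-1, 1, length.out = n_bins + 1)
  bin_of <- function(x) pmin(pmax(findInterval(x, edges,
                                               rightmost.closed = TRUE), 1L),
                             n_bins)
  b_all <- bin_of(rel_pos(all_windows))
  b_int <- bin_of(rel_pos(interest))
  N <- nrow(all_windows)
  n_int <- nrow(interest)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    K <- sum(b_all == b)   # windows in bin
    k <- sum(b_int == b)   # interest windows in bin
    p <- if (K == 0) 1
         else stats::phyper(k - 1, n_int, N - n_int, K, lower.tail = FALSE)
    data.frame(bin = b, bin_mid = (edges[b] + edges[b + 1]) / 2,
               n_all = K, n_interest = k,
               density_all = K / N,
               density_interest = if (n_int > 0) k / n_int else 0,
               p = p)
  }))
  out
}

# ---------------------------------------------------------------------------
# Dynamic time warping and trajectory clustering

#' Dynamic time warping distance between two series
#'
#' Classic dynamic program with squared-difference local cost and
#' steps (i-1,j), (i,j-1), (i-1,j-1); returns the square root of the
#' accumulated cost of the optimal alignment.
#'
#' @param a,b numeric vectors.
#' @return nonnegative scalar; 0 for identical equal-length series.
#' @export
dtw_distance <- function(a, b) {
  sqrt(dtw_accumulate(a, b)[length(a) + 1, length(b) + 1])
}

dtw_accumulate <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- (a[i] - b[j])^2
      D[i + 1, j + 1] <- cost + min(D[i, j + 1], D[i + 1, j], D[i, j])
    }
  }
  D
}

# optimal alignment path as a 2-column matrix of (i, j) indices
dtw_path <- function(a, b) {
  D <- dtw_accumulate(a, b)
  i <- length(a); j <- length(b)
  path <- list(c(i, j))
  while (i > 1 || j > 1) {
    choices <- c(if (i > 1 && j > 1) D[i, j] else Inf,
                 if (i > 1) D[i, j + 1] else Inf,
                 if (j > 1) D[i + 1, j] else Inf)
    step <- which.min(choices)
    if (step == 1) { i <- i - 1; j <- j - 1 }
    else if (step == 2) i <- i - 1
    else j <- j - 1
    path[[length(path) + 1]] <- c(i, j)
  }
  do.call(rbind, rev(path))
}

# DTW barycenter averaging: iteratively align each series to the current
# centroid and average the values mapped to each centroid coordinate.
dba_barycenter <- function(X, init = NULL, max_iter = 15, tol = 1e-8) {
  centroid <- init %||% colMeans(X)
  for (it in seq_len(max_iter)) {
    sums <- numeric(length(centroid))
    cnts <- numeric(length(centroid))
    for (r in seq_len(nrow(X))) {
      p <- dtw_path(centroid, X[r, ])
      sums[p[, 1]] <- sums[p[, 1]] + X[r, p[, 2]]
      cnts[p[, 1]] <- cnts[p[, 1]] + 1
    }
    new_centroid <- sums / cnts
    if (max(abs(new_centroid - centroid)) < tol) return(new_centroid)
    centroid <- new_centroid
  }
  centroid
}

#' K-means clustering of heterogeneity trajectories under DTW
#'
#' Clusters per-window heterogeneity trajectories across stages (e.g.
#' differentiation time points) by k-means with dynamic-time-warping
#' distance and DBA (DTW barycenter averaging) centroids. Runs `n_restarts`
#' seeded restarts and keeps the solution with the lowest within-cluster
#' inertia (sum of squared DTW distances).
#'
#' @param mat numeric matrix, one row per window, one column per stage; no
#'   missing values.
#' @param k number of clusters (default 6).
#' @param seed integer seed controlling all restarts.
#' @param n_restarts restarts (default 10).
#' @param max_iter assignment/update iterations per restart (default 30).
#' @return list with `labels` (integer per row), `centroids` (k x stages),
#'   `inertia`.
#' @export
cluster_trajectories <- function(mat, k = 6, seed = 1, n_restarts = 10,
                                 max_iter = 30) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (anyNA(mat))
    stop_validation("trajectories must have a value at every stage")
  if (k > nrow(mat))
    stop_validation(sprintf("k = %d exceeds number of windows (%d)",
                            k, nrow(mat)))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centroids <- mat[sample.int(nrow(mat), k), , drop = FALSE]
    labels <- rep(0L, nrow(mat))
    for (it in seq_len(max_iter)) {
      d <- vapply(seq_len(k), function(j)
        apply(mat, 1, dtw_distance, b = centroids[j, ]), numeric(nrow(mat)))
      d <- matrix(d, nrow = nrow(mat))
      new_labels <- max.col(-d, ties.method = "first")
      if (identical(new_labels, labels)) break
      labels <- new_labels
      for (j in seq_len(k)) {
        members <- mat[labels == j, , drop = FALSE]
        if (nrow(members) > 0)
          centroids[j, ] <- dba_barycenter(members, init = centroids[j, ])
      }
    }
    inertia <- sum(vapply(seq_len(nrow(mat)), function(i)
      dtw_distance(mat[i, ], centroids[labels[i], ])^2, 0))
    if (is.null(best) || inertia < best$inertia)
      best <- list(labels = labels, centroids = centroids, inertia = inertia)
  }
  best
}

#' Cluster cells by their reactivity profiles
#'
#' Standard k-means on per-cell reactivity vectors over the positions
#' covered in every cell (the mask intersection; at least `min_shared`
#' positions).
#'
#' @param profiles list of [reactivity_profile]s or numeric vectors, one per
#'   cell.
#' @param k number of clusters.
#' @param seed integer seed (determinism).
#' @param min_shared minimum common unmasked positions (default 10).
#' @return integer cluster labels named by cell.
#' @export
cluster_cells_by_reactivity <- function(profiles, k, seed = 1,
                                        min_shared = 10) {
  vals <- lapply(profiles, function(p)
    if (inherits(p, "reactivity_profile")) p$reactivity else as.numeric(p))
  if (k > length(vals))
    stop_validation("k exceeds the number of cells")
  common <- Reduce(`&`, lapply(vals, function(v) !is.na(v)))
  if (sum(common) < min_shared)
    stop_validation(sprintf(
      "only %d positions covered in all cells (need >= %d)",
      sum(common), min_shared))
  mat <- do.call(rbind, lapply(vals, function(v) v[common]))
  rownames(mat) <- names(profiles) %||% as.character(seq_along(profiles))
  set.seed(seed)
  fit <- stats::kmeans(mat, centers = k, nstart = 10)
  stats::setNames(fit$cluster, rownames(mat))
}

# ---------------------------------------------------------------------------
# Window correlates

#' Per-window GC content, mean reactivity and coverage
#'
#' @param windows list of `window_counts` (from [tile_windows] /
#'   [filter_windows]).
#' @param sequences named character vector of transcript sequences.
#' @param reactivity named list of per-transcript reactivity vectors
#'   (NA = masked), e.g. pseudobulk profiles; optional.
#' @return data.frame with transcript_id, window_start, window_end, gc,
#'   mean_reactivity, coverage.
#' @export
window_correlates <- function(windows, sequences, reactivity = NULL) {
  rows <- lapply(windows, function(w) {
    s <- sequences[[w$transcript_id]]
    if (is.null(s) || is.na(s))
      stop_lookup(sprintf("no sequence for transcript '%s'",
                          w$transcript_id))
    if (nchar(s) < w$window_end)
      stop_validation(sprintf(
        "sequence for '%s' (%d nt) shorter than window end %d",
        w$transcript_id, nchar(s), w$window_end))
    sub <- strsplit(toupper(substr(s, w$window_start + 1L, w$window_end)),
                    "")[[1]]
    gc <- mean(sub %in% c("G", "C"))
    mr <- NA_real_
    if (!is.null(reactivity)) {
      rv <- reactivity[[w$transcript_id]]
      if (!is.null(rv)) {
        seg <- rv[(w$window_start + 1L):w$window_end]
        if (any(!is.na(seg))) mr <- mean(seg, na.rm = TRUE)
      }
    }
    data.frame(transcript_id = w$transcript_id,
               window_start = w$window_start, window_end = w$window_end,
               gc = gc, mean_reactivity = mr, coverage = sum(w$depth),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
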