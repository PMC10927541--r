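# Cell QC, mutation rates, treated-minus-control reactivities,
# normalizations, pseudobulk aggregation and group differences.

# ---------------------------------------------------------------------------
# Containers

#' Construct a reactivity profile
#'
#' Per-base reactivities for one transcript in one cell or a pseudobulk.
#' Masked positions (no coverage in either channel) carry NA; the mask is
#' derived from the values and kept consistent by construction.
#'
#' @param reactivity numeric vector, NA at masked positions.
#' @param transcript_id transcript label.
#' @param source cell id or pseudobulk label.
#' @param treated_rate,control_rate optional per-position mutation rates.
#' @return object of class `reactivity_profile`.
#' @export
reactivity_profile <- function(reactivity, transcript_id = "tx",
                               source = "pseudobulk",
                               treated_rate = NULL, control_rate = NULL) {
  structure(list(transcript_id = transcript_id,
                 source = source,
                 reactivity = as.numeric(reactivity),
                 mask = !is.na(reactivity),
                 treated_rate = treated_rate,
                 control_rate = control_rate),
            class = "reactivity_profile")
}

#' @export
print.reactivity_profile <- function(x, ...) {
  cat(sprintf("<reactivity_profile> %s [%s]: %d nt, %d covered\n",
              x$transcript_id, x$source, length(x$reactivity), sum(x$mask)))
  invisible(x)
}

new_rate_vector <- function(transcript_id, rate, coverage, mutated,
                            source, condition) {
  structure(list(transcript_id = transcript_id, rate = rate,
                 coverage = coverage, mutated = mutated,
                 source = source, condition = condition),
            class = "rate_vector")
}

#' @export
print.rate_vector <- function(x, ...) {
  cat(sprintf("<rate_vector> %s [%s, %s]: %d nt, %d covered\n",
              x$transcript_id, x$source, x$condition, length(x$rate),
              sum(!is.na(x$rate))))
  invisible(x)
}

transcript_len <- function(counts, transcript_id, transcript_length) {
  if (!is.null(transcript_length)) return(as.integer(transcript_length))
  pos <- counts$position[counts$transcript_id == transcript_id]
  if (length(pos) == 0)
    stop_lookup(sprintf("transcript '%s' not present in counts",
                        transcript_id))
  max(pos) + 1L
}

# ---------------------------------------------------------------------------
# Rates

#' Per-base mutation rate for one cell
#'
#' rate = mutated / coverage wherever coverage > 0; positions with zero
#' coverage are masked (NA), never imputed.
#'
#' @param counts a [base_counts] table.
#' @param cell cell id.
#' @param condition `"treated"` or `"control"`.
#' @param transcript_id transcript to extract.
#' @param transcript_length optional; inferred from the counts when absent.
#' @return a `rate_vector` (rate, coverage, mutated; NA-masked).
#' @export
mutation_rate <- function(counts, cell, condition, transcript_id,
                          transcript_length = NULL) {
  if (!cell %in% counts$cell_id)
    stop_lookup(sprintf("cell '%s' not present in count table", cell))
  n <- transcript_len(counts, transcript_id, transcript_length)
  sel <- counts$cell_id == cell & counts$condition == condition &
    counts$transcript_id == transcript_id
  cov <- mut <- rep(0, n)
  cov[counts$position[sel] + 1L] <- counts$coverage[sel]
  mut[counts$position[sel] + 1L] <- counts$mutated[sel]
  rate <- ifelse(cov > 0, mut / cov, NA_real_)
  new_rate_vector(transcript_id, rate, cov, mut, cell, condition)
}

#' Pseudobulk mutation rate over a set of cells
#'
#' Counts are summed across cells before dividing
#' (rate = sum(mutated) / sum(coverage)), so each cell contributes in
#' proportion to its coverage -- the behaviour of a merged library, not the
#' mean of per-cell rates.
#'
#' @inheritParams mutation_rate
#' @param cells character vector of cell ids (nonempty).
#' @return a `rate_vector` with source `"pseudobulk"`.
#' @export
pseudobulk <- function(counts, cells, condition, transcript_id,
                       transcript_length = NULL) {
  if (length(cells) == 0) stop_validation("empty cell set for pseudobulk")
  n <- transcript_len(counts, transcript_id, transcript_length)
  sel <- counts$cell_id %in% cells & counts$condition == condition &
    counts$transcript_id == transcript_id
  cov <- mut <- rep(0, n)
  if (any(sel)) {
    cs <- rowsum(cbind(counts$coverage[sel], counts$mutated[sel]),
                 counts$position[sel])
    idx <- as.integer(rownames(cs)) + 1L
    cov[idx] <- cs[, 1]
    mut[idx] <- cs[, 2]
  }
  rate <- ifelse(cov > 0, mut / cov, NA_real_)
  new_rate_vector(transcript_id, rate, cov, mut, "pseudobulk", condition)
}

#' Treated-minus-control reactivity
#'
#' reactivity = treated rate - control (DMSO background) rate on the
#' intersection of coverage masks. Negative values are kept by default; the
#' subtraction produces them wherever background exceeds the probed signal.
#'
#' @param treated,control `rate_vector`s on the same transcript, or plain
#'   numeric rate vectors (NA = masked).
#' @param clamp if TRUE, negative reactivities are set to 0.
#' @return a [reactivity_profile].
#' @export
compute_reactivity <- function(treated, control, clamp = FALSE) {
  tid <- "tx"; src <- "pseudobulk"
  if (inherits(treated, "rate_vector") && inherits(control, "rate_vector")) {
    if (treated$transcript_id != control$transcript_id)
      stop_validation(sprintf(
        "transcript mismatch: treated '%s' vs control '%s'",
        treated$transcript_id, control$transcript_id))
    tid <- treated$transcript_id
    src <- treated$source
  }
  tr <- if (inherits(treated, "rate_vector")) treated$rate else treated
  cr <- if (inherits(control, "rate_vector")) control$rate else control
  if (length(tr) != length(cr))
    stop_validation("treated and control rate vectors differ in length")
  r <- tr - cr
  if (clamp) r <- pmax(r, 0)
  r[is.na(tr) | is.na(cr)] <- NA_real_
  reactivity_profile(r, transcript_id = tid, source = src,
                     treated_rate = tr, control_rate = cr)
}

#' Difference between two group pseudobulk reactivity-scale profiles
#'
#' Delta = pseudobulk(A) - pseudobulk(B) for one condition, on the
#' intersection of coverage masks. Used e.g. to contrast cell-cycle phases.
#'
#' @inheritParams mutation_rate
#' @param cells_a,cells_b disjoint nonempty cell sets.
#' @return numeric vector (NA where either group lacks coverage).
#' @export
group_delta_reactivity <- function(counts, cells_a, cells_b, condition,
                                   transcript_id, transcript_length = NULL) {
  if (length(cells_a) == 0 || length(cells_b) == 0)
    stop_validation("both cell groups must be nonempty")
  if (length(intersect(cells_a, cells_b)) > 0)
    stop_validation("cell groups overlap")
  pa <- pseudobulk(counts, cells_a, condition, transcript_id,
                   transcript_length)
  pb <- pseudobulk(counts, cells_b, condition, transcript_id,
                   transcript_length)
  pa$rate - pb$rate
}

# ---------------------------------------------------------------------------
# Cell quality control

#' Cell quality control
#'
#' A cell passes when it has at least `min_genes` detected genes (expression
#' strictly greater than 0) and a mitochondrial fraction of at most
#' `max_mito`. The defaults encode the usual single-cell filters for this
#' assay: strictly fewer than 5,000 genes fails, strictly more than 5%
#' mitochondrial fails, so a cell at exactly 5,000 genes and 5.0% passes.
#' The mitochondrial fraction is the summed expression of `mito_genes` over
#' the summed expression of all genes; whether those values are raw read
#' counts or mapped-read counts is the caller's choice of input.
#'
#' @param expression an `expression_table`.
#' @param mito_genes nonempty character vector of mitochondrial gene ids.
#' @param cells cells to evaluate (default: all cells in the table). Cells
#'   absent from the expression table are an error.
#' @param min_genes minimum detected genes (default 5000).
#' @param max_mito maximum mitochondrial fraction (default 0.05).
#' @return data.frame with cell_id, genes_detected, mito_fraction, passed.
#' @export
cell_qc <- function(expression, mito_genes, cells = NULL,
                    min_genes = 5000, max_mito = 0.05) {
  if (length(mito_genes) == 0)
    stop_validation("mito_genes must be nonempty")
  if (is.null(cells)) cells <- sort(unique(expression$cell_id))
  missing_cells <- setdiff(cells, expression$cell_id)
  if (length(missing_cells) > 0)
    stop_lookup(sprintf("cell '%s' missing from expression table",
                        missing_cells[1]))
  out <- do.call(rbind, lapply(cells, function(cl) {
    e <- expression[expression$cell_id == cl, ]
    detected <- sum(e$expression > 0)
    total <- sum(e$expression)
    mito <- if (total > 0) sum(e$expression[e$gene_id %in% mito_genes]) / total
            else 0
    data.frame(cell_id = cl, genes_detected = detected,
               mito_fraction = mito,
               passed = detected >= min_genes && mito <= max_mito,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Normalizations

#' Gene-level 2-8% reactivity normalization
#'
#' The standard within-transcript SHAPE scaling: drop the top 2% of
#' reactivities as outliers and divide every value by the mean of the next
#' 8%. After scaling, a typical well-reacted unpaired base sits near 1.
#'
#' @param profile a [reactivity_profile] or numeric vector (NA = masked) with
#'   at least 10 unmasked positions.
#' @param exclude_top fraction of top values excluded (default 0.02).
#' @param norm_frac fraction used as the normalizer band (default 0.08).
#' @return the scaled profile; the divisor is attached as attribute
#'   `scale_factor` (and element `$scale_factor` for profile input).
#' @export
gene_level_normalize <- function(profile, exclude_top = 0.02,
                                 norm_frac = 0.08) {
  r <- if (inherits(profile, "reactivity_profile")) profile$reactivity
       else as.numeric(profile)
  v <- r[!is.na(r)]
  if (length(v) < 10)
    stop_validation("gene-level normalization needs >= 10 unmasked positions")
  s <- sort(v, decreasing = TRUE)
  k_top <- ceiling(exclude_top * length(v))
  k_norm <- max(1L, ceiling(norm_frac * length(v)))
  band <- s[(k_top + 1):min(length(s), k_top + k_norm)]
  scale_factor <- mean(band)
  if (!is.finite(scale_factor) || scale_factor <= 0)
    stop_validation(sprintf(
      "degenerate profile: nonpositive normalizer (%.4g)", scale_factor))
  if (inherits(profile, "reactivity_profile")) {
    profile$reactivity <- profile$reactivity / scale_factor
    profile$scale_factor <- scale_factor
    attr(profile, "scale_factor") <- scale_factor
    profile
  } else {
    out <- r / scale_factor
    attr(out, "scale_factor") <- scale_factor
    out
  }
}

#' Quantile normalization across cells
#'
#' Makes the within-cell reactivity distributions identical, removing
#' cell-to-cell differences in modification efficiency while preserving each
#' cell's rank order. Each cell's unmasked values are replaced by the mean of
#' the order statistics across cells at the same (fractional) rank; cells
#' with different numbers of unmasked positions are put on a common rank
#' grid by linear interpolation. Ties within a cell receive the average of
#' the reference values over the tied ranks.
#'
#' @param mat numeric matrix, cells in rows, positions in columns, NA at
#'   masked entries; at least 2 rows.
#' @return matrix of the same shape; cells with zero unmasked positions are
#'   left all-NA with a warning.
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (nrow(mat) < 2)
    stop_validation("quantile normalization needs >= 2 cells")
  m <- rowSums(!is.na(mat))
  if (any(m == 0))
    warning(sprintf("%d cell(s) with no unmasked positions excluded",
                    sum(m == 0)))
  use <- which(m > 0)
  if (length(use) == 0) return(mat)
  n_ref <- max(m[use])
  grid <- if (n_ref == 1) 0.5 else seq(0, 1, length.out = n_ref)
  sorted_on_grid <- vapply(use, function(i) {
    v <- sort(mat[i, ][!is.na(mat[i, ])])
    if (length(v) == 1) return(rep(v, n_ref))
    stats::approx(seq(0, 1, length.out = length(v)), v, xout = grid)$y
  }, numeric(n_ref))
  ref <- if (n_ref == 1) mean(sorted_on_grid) else rowMeans(sorted_on_grid)
  out <- mat
  for (i in use) {
    idx <- which(!is.na(mat[i, ]))
    v <- mat[i, idx]
    mi <- length(v)
    pr <- if (mi == 1) 0.5 else (seq_len(mi) - 1) / (mi - 1)
    refv <- if (n_ref == 1) rep(ref, mi)
            else stats::approx(grid, ref, xout = pr)$y
    newv <- numeric(mi)
    newv[order(v)] <- refv
    if (anyDuplicated(v)) {
      newv <- stats::ave(newv, match(v, v))  # average over tied ranks
    }
    out[i, idx] <- newv
  }
  out
}

# ---------------------------------------------------------------------------
# Depth subsampling

#' Binomially thin a count table to a lower depth
#'
#' Each read is retained independently with probability p; the mutated count
#' is then thinned hypergeometrically given the retained coverage, so
#' mutated <= coverage always holds and the expected mutation rate is
#' unchanged. Used for the depth-matched controls (e.g. subsampling abundant
#' transcripts to the median depth of detectable transcripts).
#'
#' @param counts a [base_counts] table.
#' @param fraction retention probability p in [0, 1], applied to all rows.
#' @param target_depth alternatively, a target total coverage per transcript;
#'   p is computed per transcript and must not exceed 1.
#' @param seed integer seed; the thinning is deterministic given it.
#' @return a [base_counts] table (rows with retained coverage 0 kept, with
#'   zero counts).
#' @export
subsample_counts <- function(counts, fraction = NULL, target_depth = NULL,
                             seed = 1) {
  if (is.null(fraction) == is.null(target_depth))
    stop_usage("supply exactly one of fraction, target_depth")
  if (!is.null(fraction)) {
    if (fraction < 0 || fraction > 1)
      stop_validation("fraction must be in [0, 1]")
    p <- rep(fraction, nrow(counts))
  } else {
    tot <- tapply(counts$coverage, counts$transcript_id, sum)
    if (any(target_depth > tot))
      stop_validation(sprintf(
        "target depth %d exceeds existing depth %d for transcript '%s'",
        target_depth, tot[which(target_depth > tot)[1]],
        names(tot)[which(target_depth > tot)[1]]))
    p <- (target_depth / tot)[counts$transcript_id]
  }
  set.seed(seed)
  new_cov <- stats::rbinom(nrow(counts), counts$coverage, p)
  new_mut <- stats::rhyper(nrow(counts), counts$mutated,
                           counts$coverage - counts$mutated, new_cov)
  out <- counts
  out$coverage <- as.integer(new_cov)
  out$mutated <- as.integer(new_mut)
  base_counts(as.data.frame(out))
}
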