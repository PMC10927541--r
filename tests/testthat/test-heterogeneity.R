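# Window tiling/filtering, adjusted-R^2 heterogeneity, cosine dispersion,
# classification, regions, metagene, DTW clustering, correlates.

test_that("window tiling drops the trailing partial window and sums counts", {
  counts <- make_counts(c("c1", "c2"), positions = 0:24, coverage = 10,
                        rate = 0.1)
  wins <- tile_windows(counts, "tx1", transcript_length = 25)
  expect_length(wins, 2)
  expect_equal(wins[[1]]$window_start, 0)
  expect_equal(wins[[2]]$window_end, 20)
  expect_equal(wins[[1]]$depth, c(100, 100))  # 10 positions x 10 reads

  expect_length(tile_windows(counts, "tx1", transcript_length = 9), 0)
  expect_error(tile_windows(counts, "tx1", window_size = 0),
               class = "scstructr_validation_error")

  # random counts: window sums match per-position summation
  set.seed(31)
  cov <- rpois(60, 20)
  rnd <- base_counts(data.frame(
    cell_id = rep(c("a", "b"), each = 30), transcript_id = "t",
    position = rep(0:29, 2), coverage = cov,
    mutated = rbinom(60, cov, 0.1), condition = "treated",
    stringsAsFactors = FALSE))
  wins <- tile_windows(rnd, "t", transcript_length = 30)
  for (w in wins) {
    for (ci in seq_along(w$cells)) {
      sel <- rnd$cell_id == w$cells[ci] & rnd$position >= w$window_start &
        rnd$position < w$window_end
      expect_equal(w$depth[ci], sum(rnd$coverage[sel]))
      expect_equal(w$mutant[ci], sum(rnd$mutated[sel]))
    }
  }
})

test_that("window detection uses strict 600-read and 50%-cell rules", {
  win <- function(depths) structure(
    list(transcript_id = "t", window_start = 0L, window_end = 10L,
         cells = paste0("c", seq_along(depths)), depth = depths,
         mutant = rep(0, length(depths))), class = "window_counts")
  # total exactly 600: rejected (strictly more than 600 required)
  f <- filter_windows(list(win(rep(60, 10))))[[1]]
  expect_equal(f$total_reads, 600)
  expect_false(f$detected)
  # 601 reads in 50% of cells: accepted
  f <- filter_windows(list(win(c(rep(120.2, 5), rep(0, 5)))))[[1]]
  expect_true(f$n_cells_detected / 10 >= 0.5 && f$total_reads > 600)
  expect_true(f$detected)
  # present in 49 of 100 cells: rejected
  f <- filter_windows(list(win(c(rep(100, 49), rep(0, 51)))))[[1]]
  expect_false(f$detected)
})

test_that("window heterogeneity matches the normal-equation oracle", {
  # perfect proportionality: R^2 = adj R^2 = 1
  d <- seq(100, 1000, by = 100)
  w <- list(depth = d, mutant = 0.03 * d)
  h <- window_heterogeneity(w)
  expect_equal(h$r_squared, 1)
  expect_equal(h$adj_r_squared, 1)
  expect_equal(h$fitted_modification_rate, 0.03)

  # mutation rate independent of depth: adj R^2 near 0
  d2 <- rep(c(1000, 1000), 10)
  m2 <- rep(c(10, 300), 10)
  h2 <- window_heterogeneity(list(depth = d2, mutant = m2))
  expect_false(h2$defined)  # exactly equal depths are flagged, not fit
  d3 <- rep(c(1000, 1001), 10)
  m3 <- rep(c(10, 300), each = 10)  # rates unrelated to the depth wobble
  h3 <- window_heterogeneity(list(depth = d3, mutant = m3))
  expect_lt(h3$adj_r_squared, 0.05)

  # random windows against the closed-form least-squares oracle
  set.seed(41)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    depth <- rpois(n, 500) + 50
    mutant <- rbinom(n, depth, runif(1, 0.01, 0.1))
    if (var(mutant) == 0) next
    h <- window_heterogeneity(list(depth = depth, mutant = mutant))
    o <- ols_oracle(depth, mutant)
    expect_equal(h$fitted_modification_rate, o$slope, tolerance = 1e-10)
    expect_equal(h$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(h$r_squared, o$r2, tolerance = 1e-10)
    expect_equal(h$adj_r_squared, o$adj, tolerance = 1e-10)
    expect_true(h$adj_r_squared <= h$r_squared + 1e-12)

    # permutation invariance and integer scale equivariance of R^2
    p <- sample(n)
    hp <- window_heterogeneity(list(depth = depth[p], mutant = mutant[p]))
    expect_equal(hp$r_squared, h$r_squared)
    hs <- window_heterogeneity(list(depth = 3 * depth, mutant = 3 * mutant))
    expect_equal(hs$r_squared, h$r_squared, tolerance = 1e-12)
  }

  # degenerate inputs flagged, never coerced
  h4 <- window_heterogeneity(list(depth = c(10, 20, 30), mutant = c(1, 2, 3)))
  expect_false(h4$defined)
  expect_match(h4$reason, "n_cells")
})

test_that("gene heterogeneity is the RMS cosine dispersion", {
  pb <- c(1, 2, 3, 4, 5, 4, 3, 2, 1, 2)
  same <- replicate(4, pb, simplify = FALSE)
  g <- gene_heterogeneity(same, pb, min_shared = 5)
  expect_equal(g$heterogeneity, 0)
  expect_equal(unname(g$D), rep(0, 4))

  # orthogonal + identical two-cell case: sqrt((1 + 0)/2)
  pb2 <- c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0)
  orth <- c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1)
  g2 <- gene_heterogeneity(list(orth, pb2), pb2, min_shared = 5)
  expect_equal(unname(g2$D), c(1, 0))
  expect_equal(g2$heterogeneity, sqrt(1 / 2))

  # 20 random cells against a dot-product oracle
  set.seed(51)
  pb3 <- runif(40)
  cells <- lapply(1:20, function(i) {
    v <- pb3 + rnorm(40, sd = 0.3)
    v[sample(40, 5)] <- NA
    v
  })
  g3 <- gene_heterogeneity(cells, pb3)
  D_oracle <- vapply(cells, function(v) {
    ok <- !is.na(v)
    1 - sum(v[ok] * pb3[ok]) /
      (sqrt(sum(v[ok]^2)) * sqrt(sum(pb3[ok]^2)))
  }, 0)
  expect_equal(unname(g3$D), D_oracle, tolerance = 1e-12)
  expect_equal(g3$heterogeneity, sqrt(mean(D_oracle^2)), tolerance = 1e-12)

  # cosine scale invariance
  g4 <- gene_heterogeneity(lapply(cells, function(v) v * 3.7), pb3 * 0.2)
  expect_equal(g4$heterogeneity, g3$heterogeneity, tolerance = 1e-12)

  # zero-norm cells excluded with warning; < 2 usable cells errors
  expect_warning(
    g5 <- gene_heterogeneity(list(rep(0, 10), pb2, pb2), pb2,
                             min_shared = 5),
    "excluded")
  expect_equal(g5$n, 2)
  expect_error(
    suppressWarnings(gene_heterogeneity(list(rep(0, 10), pb2), pb2,
                                        min_shared = 5)),
    class = "scstructr_validation_error")
})

test_that("quartile classification follows interpolated percentiles", {
  cls <- classify_quantiles(1:100)
  expect_equal(sum(cls == "homogeneous"), 25)
  expect_equal(sum(cls == "heterogeneous"), 25)
  expect_true(all(which(cls == "homogeneous") == 1:25))
  expect_true(all(which(cls == "heterogeneous") == 76:100))

  expect_warning(cls2 <- classify_quantiles(rep(3, 10)), "degenerate")
  expect_true(all(cls2 == "intermediate"))
  expect_error(classify_quantiles(1:3), class = "scstructr_validation_error")

  set.seed(61)
  v <- rnorm(57)
  cls3 <- classify_quantiles(v)
  q <- quantile(v, c(0.25, 0.75), type = 7)
  expect_equal(as.character(cls3),
               ifelse(v <= q[1], "homogeneous",
                      ifelse(v >= q[2], "heterogeneous", "intermediate")))
})

test_that("region assignment uses the window midpoint and half-open CDS", {
  ann <- region_annotation(data.frame(
    transcript_id = "t", transcript_length = 200L, cds_start = 50L,
    cds_end = 150L, stringsAsFactors = FALSE))
  expect_equal(as.character(assign_region("t", 0L, 10L, ann)),
               "five_prime_utr")
  # midpoint exactly at cds_start -> cds
  expect_equal(as.character(assign_region("t", 45L, 55L, ann)), "cds")
  # straddle cases around cds_end: region of the midpoint
  for (start in 140:150) {
    mid <- (start + start + 10) %/% 2
    expected <- if (mid < 150) "cds" else "three_prime_utr"
    expect_equal(as.character(assign_region("t", start, start + 10L, ann)),
                 expected)
  }
  expect_error(assign_region("missing", 0L, 10L, ann),
               class = "scstructr_lookup_error")
})

test_that("metagene enrichment is an exact hypergeometric per bin", {
  ann <- region_annotation(data.frame(
    transcript_id = "t", transcript_length = 1000L, cds_start = 200L,
    cds_end = 800L, stringsAsFactors = FALSE))
  all_w <- data.frame(transcript_id = "t",
                      window_start = seq(0, 990, by = 10),
                      window_end = seq(10, 1000, by = 10))
  # interest = everything: p = 1 in every bin
  res <- metagene_enrichment(all_w, all_w, ann, "start_codon", n_bins = 10)
  expect_true(all(res$p == 1))

  # all interest concentrated in one bin: matches the enumeration oracle
  interest <- all_w[1:10, ]  # far upstream windows fall in bin 1
  res2 <- metagene_enrichment(interest, all_w, ann, "start_codon",
                              n_bins = 10)
  b <- res2$bin[which.max(res2$n_interest)]
  K <- res2$n_all[res2$bin == b]
  k <- res2$n_interest[res2$bin == b]
  expect_equal(res2$p[res2$bin == b],
               hyper_tail_oracle(k, nrow(interest), K, nrow(all_w)))
  # empty bins: density 0, p = 1
  empty <- res2[res2$n_all == 0, ]
  if (nrow(empty) > 0) expect_true(all(empty$p == 1 & empty$density_all == 0))
})

test_that("DTW distance matches exhaustive path enumeration", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtw_distance(c(0, 0, 0, 0), c(0, 0)), 0)
  set.seed(71)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(dtw_distance(a, b), dtw_exhaustive_oracle(a, b),
                 tolerance = 1e-12)
    expect_equal(dtw_distance(a, b), dtw_distance(b, a),
                 tolerance = 1e-12)
  }
})

test_that("DTW k-means clusters trajectories deterministically", {
  set.seed(81)
  up <- t(replicate(15, c(0.2, 0.4, 0.6, 0.8) + rnorm(4, sd = 0.03)))
  down <- t(replicate(15, c(0.8, 0.6, 0.4, 0.2) + rnorm(4, sd = 0.03)))
  mat <- rbind(up, down)
  truth <- rep(1:2, each = 15)

  res <- cluster_trajectories(mat, k = 2, seed = 5)
  expect_gte(cluster_agreement(res$labels, truth), 0.95)
  res2 <- cluster_trajectories(mat, k = 2, seed = 5)
  expect_identical(res$labels, res2$labels)
  expect_equal(res$inertia, res2$inertia)

  one <- cluster_trajectories(mat, k = 1, seed = 5, n_restarts = 2)
  expect_true(all(one$labels == 1))
  # k = 1 centroid is the DBA barycenter of everything
  expect_equal(sum(apply(mat, 1, dtw_distance, b = one$centroids[1, ])^2),
               one$inertia)
  expect_error(cluster_trajectories(mat, k = 31),
               class = "scstructr_validation_error")
  expect_error(cluster_trajectories(cbind(mat, NA), k = 2),
               class = "scstructr_validation_error")
})

test_that("cells cluster by reactivity into conformation groups", {
  set.seed(91)
  conf_a <- runif(40, 0, 1)
  conf_b <- rev(conf_a)
  profiles <- c(
    lapply(1:10, function(i) conf_a + rnorm(40, sd = 0.05)),
    lapply(1:10, function(i) conf_b + rnorm(40, sd = 0.05)))
  names(profiles) <- paste0("cell", 1:20)
  labels <- cluster_cells_by_reactivity(profiles, k = 2, seed = 3)
  expect_gte(cluster_agreement(labels, rep(1:2, each = 10)), 0.9)
  expect_identical(labels,
                   cluster_cells_by_reactivity(profiles, k = 2, seed = 3))
  expect_true(all(cluster_cells_by_reactivity(profiles, k = 1) == 1))
  expect_error(cluster_cells_by_reactivity(profiles[1:3], k = 5),
               class = "scstructr_validation_error")
})

test_that("window correlates report GC, mean reactivity and coverage", {
  counts <- make_counts("c1", transcript = "t", positions = 0:19,
                        coverage = 30, rate = 0.1)
  wins <- tile_windows(counts, "t", transcript_length = 20)
  seqs <- c(t = paste0(strrep("GC", 5), strrep("AT", 5)))
  react <- list(t = c(rep(0.5, 10), rep(NA, 10)))
  wc <- window_correlates(wins, seqs, react)
  expect_equal(wc$gc, c(1, 0))
  expect_equal(wc$mean_reactivity, c(0.5, NA))
  expect_equal(wc$coverage, c(300, 300))

  set.seed(101)
  seq_r <- paste(sample(c("A", "C", "G", "U"), 20, TRUE), collapse = "")
  rv <- runif(20)
  wc2 <- window_correlates(wins, c(t = seq_r), list(t = rv))
  chars <- strsplit(seq_r, "")[[1]]
  expect_equal(wc2$gc[1], mean(chars[1:10] %in% c("G", "C")))
  expect_equal(wc2$mean_reactivity[2], mean(rv[11:20]))

  expect_error(window_correlates(wins, c(t = "AUGC"), NULL),
               "shorter", class = "scstructr_validation_error")
})
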