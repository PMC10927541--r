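# Mutation rates, QC, reactivity, normalizations, pseudobulk, thinning.

test_that("mutation rates are per-position quotients with coverage mask", {
  counts <- base_counts(data.frame(
    cell_id = "c1", transcript_id = "t", position = c(0L, 2L),
    coverage = c(100L, 50L), mutated = c(2L, 5L), condition = "treated",
    stringsAsFactors = FALSE))
  rv <- mutation_rate(counts, "c1", "treated", "t", transcript_length = 3)
  expect_equal(rv$rate, c(0.02, NA, 0.1))
  expect_error(mutation_rate(counts, "nope", "treated", "t"),
               class = "scstructr_lookup_error")

  # elementwise oracle on a random table
  set.seed(21)
  cov <- rpois(40, 50)
  rnd <- base_counts(data.frame(
    cell_id = "c9", transcript_id = "t", position = 0:39,
    coverage = cov, mutated = rbinom(40, cov, 0.05),
    condition = "treated", stringsAsFactors = FALSE))
  rv <- mutation_rate(rnd, "c9", "treated", "t")
  manual <- ifelse(rnd$coverage > 0, rnd$mutated / rnd$coverage, NA)
  expect_equal(rv$rate[rnd$position + 1], manual)
  # mask consistency: no rate where no coverage
  expect_true(all(is.na(rv$rate) == (rv$coverage == 0)))
})

test_that("cell QC applies strict gene and mitochondrial cutoffs", {
  # integer-exact construction: n-1 nuclear genes at (1000 - mpm) each and
  # one mito gene at (n-1)*mpm, so the total is 1000*(n-1) exactly and the
  # mitochondrial fraction is exactly mpm/1000, with n detected genes
  qc_one <- function(n_genes, mito_per_mille) {
    n_nuc <- n_genes - 1
    e <- expression_table(data.frame(
      cell_id = "c",
      gene_id = c(sprintf("g%05d", seq_len(n_nuc)), "MT"),
      expression = c(rep(1000 - mito_per_mille, n_nuc),
                     n_nuc * mito_per_mille),
      stringsAsFactors = FALSE))
    cell_qc(e, "MT")[1, ]
  }
  res <- qc_one(4999, 10)
  expect_false(res$passed)                      # too few genes
  expect_equal(res$genes_detected, 4999)
  res <- qc_one(5000, 51)
  expect_false(res$passed)                      # mito above 5%
  res <- qc_one(5000, 50)
  expect_true(res$passed)                       # exactly 5000 genes, 5.0%
  expect_equal(res$genes_detected, 5000)

  e <- expression_table(data.frame(cell_id = "c1", gene_id = "g1",
                                   expression = 1, stringsAsFactors = FALSE))
  expect_error(cell_qc(e, "MT", cells = c("c1", "ghost")),
               "ghost", class = "scstructr_lookup_error")
})

test_that("reactivity is treated minus control on the mask intersection", {
  prof <- compute_reactivity(c(0.05, 0.01, NA), c(0.01, 0.03, 0.01))
  expect_equal(prof$reactivity, c(0.04, -0.02, NA))
  clamped <- compute_reactivity(c(0.05, 0.01, 0.02), c(0.01, 0.03, NA),
                                clamp = TRUE)
  expect_equal(clamped$reactivity, c(0.04, 0, NA))

  # self-subtraction is exactly zero wherever defined
  set.seed(3)
  x <- runif(50); x[c(4, 9)] <- NA
  self <- compute_reactivity(x, x)
  expect_true(all(self$reactivity[!is.na(x)] == 0))
  expect_equal(self$mask, !is.na(x))

  a <- structure(list(transcript_id = "a", rate = 0.1, source = "c",
                      condition = "treated"), class = "rate_vector")
  b <- structure(list(transcript_id = "b", rate = 0.1, source = "c",
                      condition = "control"), class = "rate_vector")
  expect_error(compute_reactivity(a, b), "transcript mismatch",
               class = "scstructr_validation_error")
})

test_that("pseudobulk sums counts before dividing", {
  counts <- base_counts(data.frame(
    cell_id = c("c1", "c2"), transcript_id = "t", position = 0L,
    coverage = c(100L, 900L), mutated = c(10L, 0L), condition = "treated",
    stringsAsFactors = FALSE))
  pb <- pseudobulk(counts, c("c1", "c2"), "treated", "t")
  expect_equal(pb$rate, 0.01)            # count-sum definition
  expect_false(isTRUE(all.equal(pb$rate, 0.05)))  # not the rate mean

  # single cell: equals that cell's mutation rate
  one <- pseudobulk(counts, "c1", "treated", "t")
  expect_equal(one$rate, mutation_rate(counts, "c1", "treated", "t")$rate)

  # disjoint coverage: union of per-cell rates
  dis <- base_counts(data.frame(
    cell_id = c("c1", "c2"), transcript_id = "t", position = c(0L, 1L),
    coverage = 10L, mutated = c(1L, 2L), condition = "treated",
    stringsAsFactors = FALSE))
  pb2 <- pseudobulk(dis, c("c1", "c2"), "treated", "t")
  expect_equal(pb2$rate, c(0.1, 0.2))

  # permutation invariance
  expect_equal(pseudobulk(counts, c("c2", "c1"), "treated", "t")$rate,
               pb$rate)
  expect_error(pseudobulk(counts, character(0), "treated", "t"),
               class = "scstructr_validation_error")
})

test_that("group delta reactivity is an antisymmetric pseudobulk contrast", {
  counts <- base_counts(data.frame(
    cell_id = rep(c("a1", "a2", "b1", "b2"), each = 2),
    transcript_id = "t", position = rep(0:1, 4),
    coverage = 100L,
    mutated = c(5L, 1L, 5L, 1L, 9L, 2L, 9L, 2L), condition = "treated",
    stringsAsFactors = FALSE))
  d <- group_delta_reactivity(counts, c("a1", "a2"), c("b1", "b2"),
                              "treated", "t")
  pa <- pseudobulk(counts, c("a1", "a2"), "treated", "t")
  pb <- pseudobulk(counts, c("b1", "b2"), "treated", "t")
  expect_equal(d, pa$rate - pb$rate)
  # identical count composition in both groups: delta 0
  d0 <- group_delta_reactivity(counts, "a1", "a2", "treated", "t")
  expect_equal(d0, c(0, 0))
  # antisymmetry
  expect_equal(group_delta_reactivity(counts, c("b1", "b2"), c("a1", "a2"),
                                      "treated", "t"), -d)
  expect_error(group_delta_reactivity(counts, "a1", "a1", "treated", "t"),
               "overlap", class = "scstructr_validation_error")
})

test_that("2-8% gene-level normalization matches a sort-slice oracle", {
  set.seed(8)
  r <- rexp(100)
  out <- gene_level_normalize(r)
  s <- sort(r, decreasing = TRUE)
  k2 <- ceiling(0.02 * 100); k8 <- ceiling(0.08 * 100)
  norm <- mean(s[(k2 + 1):(k2 + k8)])
  expect_equal(attr(out, "scale_factor"), norm)
  expect_equal(as.numeric(out), r / norm)

  # fixed point when the normalizer is already 1
  r1 <- r / norm
  out1 <- gene_level_normalize(r1)
  expect_equal(attr(out1, "scale_factor"), 1)
  expect_equal(as.numeric(out1), r1)

  # scale invariance
  out_c <- gene_level_normalize(r * 7.3)
  expect_equal(as.numeric(out_c), as.numeric(out))

  expect_error(gene_level_normalize(rexp(5)), ">= 10",
               class = "scstructr_validation_error")
  expect_error(gene_level_normalize(-rexp(50)), "nonpositive",
               class = "scstructr_validation_error")
})

test_that("quantile normalization equalizes distributions and fixes points", {
  set.seed(12)
  base <- sort(runif(20))
  mat <- rbind(base, base, base)
  expect_equal(unname(quantile_normalize(mat)), unname(mat))

  rnd <- matrix(rnorm(100), nrow = 5)
  qn <- quantile_normalize(rnd)
  sorted <- apply(qn, 1, sort)
  for (i in 2:5) expect_equal(sorted[, i], sorted[, 1])
  # rank order preserved within each cell
  for (i in 1:5) expect_equal(order(qn[i, ]), order(rnd[i, ]))

  # independent oracle: limma's quantile normalization (samples in columns)
  skip_if_not_installed("limma")
  expect_equal(unname(qn), unname(t(limma::normalizeQuantiles(t(rnd)))),
               tolerance = 1e-12)

  # cells with no unmasked values excluded with warning
  rnd2 <- rnd
  rnd2[2, ] <- NA
  expect_warning(qn2 <- quantile_normalize(rnd2), "excluded")
  expect_true(all(is.na(qn2[2, ])))
  expect_error(quantile_normalize(rnd[1, , drop = FALSE]),
               class = "scstructr_validation_error")
})

test_that("quantile normalization handles missing data and ties", {
  mat <- rbind(c(1, 2, 3, NA), c(4, NA, 2, 1), c(5, 5, 1, 2))
  qn <- quantile_normalize(mat)
  expect_equal(is.na(qn), is.na(mat))
  # ties map to equal outputs
  expect_equal(qn[3, 1], qn[3, 2])
  # within-cell order preserved (weakly for ties)
  expect_true(all(diff(qn[1, order(mat[1, ])][1:3]) >= 0))
})

test_that("binomial thinning preserves the expected mutation rate", {
  set.seed(5)
  n <- 10000
  cov <- rpois(n, 200) + 1L
  mut <- rbinom(n, cov, 0.03)
  counts <- base_counts(data.frame(
    cell_id = "c", transcript_id = "t", position = seq_len(n) - 1L,
    coverage = cov, mutated = mut, condition = "treated",
    stringsAsFactors = FALSE))

  keep_all <- subsample_counts(counts, fraction = 1, seed = 2)
  expect_equal(keep_all$coverage, counts$coverage)
  expect_equal(keep_all$mutated, counts$mutated)
  none <- subsample_counts(counts, fraction = 0, seed = 2)
  expect_true(all(none$coverage == 0) && all(none$mutated == 0))

  half <- subsample_counts(counts, fraction = 0.5, seed = 7)
  expect_true(all(half$mutated <= half$coverage))
  rate0 <- sum(counts$mutated) / sum(counts$coverage)
  rate1 <- sum(half$mutated) / sum(half$coverage)
  se <- sqrt(rate0 * (1 - rate0) / sum(half$coverage))
  expect_lt(abs(rate1 - rate0), 3 * se)

  # deterministic under seed
  expect_identical(subsample_counts(counts, fraction = 0.5, seed = 7),
                   half)
  expect_error(subsample_counts(counts, target_depth = sum(cov) + 1),
               "exceeds", class = "scstructr_validation_error")
  td <- subsample_counts(counts, target_depth = 1000, seed = 3)
  expect_lt(abs(sum(td$coverage) - 1000), 5 * sqrt(1000))
})
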