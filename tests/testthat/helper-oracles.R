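# Independent oracles used across the suite. Each recomputes a statistic by
# a different route than the implementation (normal equations, exhaustive
# enumeration, brute-force pair counting), on purpose.

# OLS slope/intercept/R2 by explicit normal equations
ols_oracle <- function(depth, mutant) {
  X <- cbind(1, depth)
  beta <- solve(t(X) %*% X, t(X) %*% mutant)
  fitted <- X %*% beta
  ss_res <- sum((mutant - fitted)^2)
  ss_tot <- sum((mutant - mean(mutant))^2)
  r2 <- 1 - ss_res / ss_tot
  n <- length(depth)
  list(slope = beta[2], intercept = beta[1], r2 = r2,
       adj = 1 - (1 - r2) * (n - 1) / (n - 2))
}

# AUC as the fraction of concordant (true, false) pairs, half credit to ties
auc_pair_oracle <- function(score, label) {
  pos <- score[label]; neg <- score[!label]
  cmp <- outer(pos, neg, `-`)
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(pos) * length(neg))
}

# Upper-tail hypergeometric P(X >= k) by direct summation of the pmf
hyper_tail_oracle <- function(k, K, n, N) {
  if (k > min(K, n)) return(0)
  js <- max(k, 0):min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments and
# recomputing the pair-count U for each from raw values (not ranks)
mw_exact_oracle <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, `>`)) + 0.5 * sum(outer(a, b, `==`))
  U_obs <- u_of(x, y)
  mu <- n1 * length(y) / 2
  combs <- utils::combn(length(pool), n1)
  Us <- apply(combs, 2, function(ix) u_of(pool[ix], pool[-ix]))
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# DTW cost by exhaustive recursive enumeration of all monotone alignment
# paths (feasible only for very short series)
dtw_exhaustive_oracle <- function(a, b) {
  rec <- function(i, j) {
    cost <- (a[i] - b[j])^2
    if (i == 1 && j == 1) return(cost)
    opts <- c(if (i > 1 && j > 1) rec(i - 1, j - 1) else Inf,
              if (i > 1) rec(i - 1, j) else Inf,
              if (j > 1) rec(i, j - 1) else Inf)
    cost + min(opts)
  }
  sqrt(rec(length(a), length(b)))
}

# best-matching agreement between two 2-group labelings
cluster_agreement <- function(found, truth) {
  found <- as.integer(factor(found)); truth <- as.integer(factor(truth))
  max(mean(found == truth), mean(found == 3 - truth))
}

# small valid base-count data.frame builder
make_counts <- function(cells, transcript = "tx1", positions = 0:9,
                        coverage = 100, rate = 0.02,
                        condition = "treated") {
  rows <- expand.grid(cell_id = cells, position = positions,
                      stringsAsFactors = FALSE)
  rows$transcript_id <- transcript
  rows$coverage <- coverage
  rows$mutated <- round(coverage * rate)
  rows$condition <- condition
  base_counts(rows[, c("cell_id", "transcript_id", "position",
                       "coverage", "mutated", "condition")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
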