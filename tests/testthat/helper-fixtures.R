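# Shared fixtures: small configs and independently computed oracles.

small_config <- function(seed = 11L, n_promoters = 400L, n_strains = 2L,
                         ...) {
  synthetic_config(seed = seed, n_promoters = n_promoters,
                   n_strains = n_strains, ...)
}

# Observable table with replicate means and total methylation appended.
prepared_data <- function(ds) {
  d <- ds$data
  d$basal <- (d$basal_rep1 + d$basal_rep2) / 2
  d$treated <- (d$treated_rep1 + d$treated_rep2) / 2
  d$meth_total <- rowSums(d[, paste0("meth_bin", 1:6)])
  d
}

# Brute-force oracles -------------------------------------------------------

# Position-by-position CG scan (independent of count_cpg's vectorized path).
oracle_cpg_scan <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  total <- 0L
  for (i in seq_len(length(chars) - 1L)) {
    if (chars[i] == "C" && chars[i + 1L] == "G") total <- total + 1L
  }
  total
}

# Exhaustive sign-flip enumeration of the one-sided signed-rank p-value.
oracle_signrank_p <- function(basal, treated) {
  d <- treated - basal
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- drop(signs %*% r)
  mean(W_all >= W_obs - 1e-9)
}

# Exact hypergeometric tails by direct summation of point masses.
oracle_hyper_tails <- function(k, n, K, N) {
  j <- max(0L, n - (N - K)):min(n, K)
  pmf <- choose(K, j) * choose(N - K, n - j) / choose(N, n)
  list(enrich_p = sum(pmf[j >= k]), deplete_p = sum(pmf[j <= k]))
}

# AUC as the pairwise concordance fraction, ties counted 1/2.
oracle_concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
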