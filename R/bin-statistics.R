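#' One-sided Wilcoxon signed-rank test for paired expression increase
#'
#' Tests whether post-treatment expression exceeds basal expression within
#' a promoter category (alternative: treated > basal). Zero differences
#' are dropped before ranking and ties among absolute differences receive
#' mid-ranks. For `n <= exact_max_n` non-zero pairs the p-value is exact,
#' computed from the full sign-flip null distribution of the positive-rank
#' sum (a convolution over the doubled mid-ranks, so ties are handled
#' exactly); for larger n a normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param basal,treated Paired numeric vectors of equal length.
#' @param exact_max_n Largest number of non-zero pairs for which the exact
#'   null distribution is used (default 25).
#' @return A list with `p_value` (one-sided, treated > basal), `statistic`
#'   (positive-rank sum W), `n_pairs` (after zero removal) and `exact`
#'   (logical).
#' @examples
#' wilcoxon_bin_test(basal = rep(1, 5), treated = 2:6)$p_value  # 1/32
#' @export
wilcoxon_bin_test <- function(basal, treated, exact_max_n = 25L) {
  stopifnot(length(basal) == length(treated), length(basal) >= 1L,
            all(is.finite(basal)), all(is.finite(treated)))
  d <- treated - basal
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(p_value = 1, statistic = 0, n_pairs = 0L, exact = TRUE))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max_n) {
    p <- signrank_upper_tail(r, W)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- stats::pnorm((W - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
    exact <- FALSE
  }
  list(p_value = min(max(p, .Machine$double.xmin), 1),
       statistic = W, n_pairs = n, exact = exact)
}

# Exact P(W >= w) for the signed-rank sum with arbitrary (mid-)ranks r:
# dynamic-programming convolution over doubled ranks (integers even with
# .5 mid-ranks), each rank included independently with probability 1/2.
signrank_upper_tail <- function(r, w) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (ri in r2) {
    g <- f
    g[(ri + 1L):(total + 1L)] <- g[(ri + 1L):(total + 1L)] +
      f[seq_len(total + 1L - ri)]
    f <- g / 2
  }
  w2 <- as.integer(round(2 * w))
  sum(f[(w2 + 1L):(total + 1L)])
}

#' Hypergeometric enrichment/depletion test for one grid cell
#'
#' Given `k` up-regulated records among the `n` records of a promoter
#' category, drawn from a universe of `N` records of which `K` are
#' up-regulated, computes one-sided tail probabilities under
#' `X ~ Hypergeometric(N, K, n)`: `enrich_p = P(X >= k)` and
#' `deplete_p = P(X <= k)`.
#'
#' @param k Up-regulated records in the cell.
#' @param n Records in the cell.
#' @param K Up-regulated records in the universe.
#' @param N Records in the universe.
#' @return A list with `enrich_p` and `deplete_p`.
#' @examples
#' hypergeometric_bin_test(3, 5, 6, 20)$enrich_p  # 2036/15504
#' @export
hypergeometric_bin_test <- function(k, n, K, N) {
  stopifnot(k >= 0, n >= 0, K >= 0, N >= 0,
            k <= n, k <= K, n <= N, K <= N, n - k <= N - K)
  list(enrich_p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       deplete_p = stats::phyper(k, K, N - K, n, lower.tail = TRUE))
}

#' Per-grid-cell statistics for the stratified promoter table
#'
#' For every occupied (methylation category x CpG category) cell, computes
#' the one-sided signed-rank p-value for expression increase, its
#' `-log10`, the cell's up-regulated count and percentage, and
#' hypergeometric enrichment/depletion tail probabilities against the
#' pooled universe.
#'
#' @param data data.frame with columns `meth_category`, `cpg_category`,
#'   `basal`, `treated` and logical `is_upregulated`.
#' @return data.frame with one row per occupied cell.
#' @export
bin_tests <- function(data) {
  req <- c("meth_category", "cpg_category", "basal", "treated",
           "is_upregulated")
  stopifnot(is.data.frame(data), all(req %in% names(data)), nrow(data) > 0L)
  N <- nrow(data)
  K <- sum(data$is_upregulated)
  cells <- unique(data[, c("meth_category", "cpg_category")])
  cells <- cells[order(cells$meth_category, cells$cpg_category), ]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- data$meth_category == cells$meth_category[i] &
      data$cpg_category == cells$cpg_category[i]
    sub <- data[sel, ]
    wt <- wilcoxon_bin_test(sub$basal, sub$treated)
    ht <- hypergeometric_bin_test(sum(sub$is_upregulated), nrow(sub), K, N)
    data.frame(
      meth_category = cells$meth_category[i],
      cpg_category = cells$cpg_category[i],
      n_records = nrow(sub),
      n_upregulated = sum(sub$is_upregulated),
      percent_upregulated = 100 * mean(sub$is_upregulated),
      wilcoxon_p = wt$p_value,
      neg_log10_p = -log10(wt$p_value),
      enrich_p = ht$enrich_p,
      deplete_p = ht$deplete_p
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assemble the grid summary with enrichment/depletion flags
#'
#' Adds significance flags to per-cell results. A cell is flagged
#' `enriched` (or `depleted`) when the two-sided hypergeometric p-value
#' (twice the smaller tail, capped at 1) passes the per-cell threshold;
#' with `correction = "bonferroni"` the family-wise level `alpha` is
#' divided by the number of cells. The `-log10(0.05)` reference used when
#' displaying signed-rank surfaces is attached as `reference_neg_log10`.
#'
#' @param results Per-cell results from [bin_tests()]; duplicate cells are
#'   an error.
#' @param alpha Family-wise significance level (default 0.05).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return A list of class `grid_summary` with elements `grid` (the
#'   flagged per-cell data.frame), `overall_percent_upregulated`, `alpha`,
#'   `correction`, `cell_alpha` and `reference_neg_log10`.
#' @export
build_summary_grid <- function(results, alpha = 0.05,
                               correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  stopifnot(is.data.frame(results), nrow(results) > 0L)
  key <- paste(results$meth_category, results$cpg_category)
  if (anyDuplicated(key)) stop("duplicate grid cells in results")
  m <- nrow(results)
  cell_alpha <- if (correction == "bonferroni") alpha / m else alpha
  two_sided <- pmin(1, 2 * pmin(results$enrich_p, results$deplete_p))
  results$flag <- ifelse(two_sided <= cell_alpha,
                         ifelse(results$enrich_p <= results$deplete_p,
                                "enriched", "depleted"),
                         "ns")
  overall <- sum(results$n_upregulated) / sum(results$n_records) * 100
  structure(list(grid = results,
                 overall_percent_upregulated = overall,
                 alpha = alpha, correction = correction,
                 cell_alpha = cell_alpha,
                 reference_neg_log10 = -log10(0.05)),
            class = "grid_summary")
}

#' @export
print.grid_summary <- function(x, ...) {
  cat("Promoter grid summary (", nrow(x$grid), " cells, ",
      sprintf("%.2f", x$overall_percent_upregulated),
      "% up-regulated overall)\n", sep = "")
  cat("flags at family alpha =", x$alpha, "with", x$correction,
      "correction:\n")
  print(table(flag = x$grid$flag))
  invisible(x)
}
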