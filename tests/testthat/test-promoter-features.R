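test_that("sub-bin grid partitions the 2,700-bp window without gaps", {
  g <- subbin_grid()
  expect_equal(nrow(g), 6L)
  expect_equal(sum(g$end - g$start), 2700L)
  expect_equal(g$start[-1], g$end[-6])        # contiguous half-open bins
  expect_equal(g$start[1], -2200L)
  expect_equal(g$end[6], 500L)
})

test_that("count_cpg counts CG dinucleotides by first-base sub-bin", {
  s <- paste0("CGCG", strrep("A", 2696))
  res <- count_cpg(s)
  expect_equal(res$total, 2L)
  expect_equal(res$per_subbin, c(2L, 0L, 0L, 0L, 0L, 0L))

  expect_equal(count_cpg(strrep("A", 2700))$total, 0L)

  # CG straddling the bin1/bin2 boundary (first base at window position 700)
  s2 <- paste0(strrep("A", 699), "CG", strrep("A", 1999))
  expect_equal(count_cpg(s2)$per_subbin, c(1L, 0L, 0L, 0L, 0L, 0L))
  # first base at position 701 belongs to bin2
  s3 <- paste0(strrep("A", 700), "CG", strrep("A", 1998))
  expect_equal(count_cpg(s3)$per_subbin, c(0L, 1L, 0L, 0L, 0L, 0L))

  # N never matches
  s4 <- paste0("CNGCG", strrep("N", 2695))
  expect_equal(count_cpg(s4)$total, 1L)

  expect_error(count_cpg("ACGT"), "length")
  expect_error(count_cpg(paste0("X", strrep("A", 2699))), "non-IUPAC")
})

test_that("count_cpg matches a position-by-position scan on random sequences", {
  set.seed(401)
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 2700, replace = TRUE,
                      prob = c(0.3, 0.25, 0.25, 0.15, 0.05)),
               collapse = "")
    res <- count_cpg(s)
    expect_identical(res$total, oracle_cpg_scan(s))
    expect_identical(sum(res$per_subbin), res$total)
  }
})

test_that("aggregate_methylation is the exact sub-bin sum", {
  expect_equal(aggregate_methylation(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)), 2.1)
  expect_equal(aggregate_methylation(rep(0, 6)), 0)
  v <- c(0.3, 0.05, 0.9, 0.12, 0.44, 0.21)
  expect_equal(aggregate_methylation(v), aggregate_methylation(rev(v)))
  m <- matrix(runif(60), ncol = 6)
  expect_equal(aggregate_methylation(m), rowSums(m))
  expect_error(aggregate_methylation(c(0.1, NA, 0.3, 0.4, 0.5, 0.6)),
               "missing")
  expect_error(aggregate_methylation(1:5), "6 sub-bin")
})

test_that("quantile categories are equal-count with ties to the lower bin", {
  cat5 <- assign_quantile_categories(1:100, 5)
  expect_equal(as.vector(table(cat5)), rep(20L, 5))
  expect_equal(cat5[20], 1L)   # boundary value takes the lower category
  expect_equal(cat5[21], 2L)

  # heavy ties: {1 x4, 2 x4}, k = 4 -> only two occupied categories
  cat_t <- assign_quantile_categories(c(1, 1, 1, 1, 2, 2, 2, 2), 4)
  expect_equal(sort(unique(cat_t)), c(1L, 3L))
  expect_equal(cat_t, c(1L, 1L, 1L, 1L, 3L, 3L, 3L, 3L))

  expect_warning(out <- assign_quantile_categories(rep(3, 10), 4),
                 "identical")
  expect_equal(out, rep(1L, 10))
})

test_that("category assignment is invariant under strictly monotone transforms", {
  set.seed(402)
  for (i in 1:20) {
    v <- rlnorm(500)
    k <- sample(4:5, 1)
    base_cat <- assign_quantile_categories(v, k)
    expect_identical(assign_quantile_categories(log(v), k), base_cat)
    expect_identical(assign_quantile_categories(rank(v, ties.method = "min"),
                                                k), base_cat)
    # monotone: a larger value never gets a smaller category
    ord <- order(v)
    expect_true(all(diff(base_cat[ord]) >= 0))
  }
})

test_that("90th-quantile scaling maps external onto the reference scale", {
  set.seed(403)
  ref <- rgamma(500, 2, 0.5)
  ext <- rpois(300, 4)
  scaled <- scale_methylation_to_reference(ext, ref)
  expect_equal(quantile(scaled, 0.9, names = FALSE),
               quantile(ref, 0.9, names = FALSE))
  expect_equal(scale_methylation_to_reference(ref, ref), ref)
  # ratio example: q90(ext) = 3, q90(ref) = 9 -> multiply by 3
  ext2 <- c(rep(1, 89), rep(3, 11))
  ref2 <- c(rep(3, 89), rep(9, 11))
  expect_equal(scale_methylation_to_reference(ext2, ref2), ext2 * 3)
  expect_error(scale_methylation_to_reference(rep(0, 10), ref),
               "degenerate")
})

test_that("absolute methylation categories use upper-inclusive bounds", {
  out <- categorize_methylation_absolute(c(0.5, 1, 6, 6.01, 7.5, 0))
  expect_equal(as.character(out),
               c("low", "low", "intermediate", "high", "high", "low"))
  expect_error(categorize_methylation_absolute(-0.1), ">= 0")
})

test_that("pooled binning of the full-scale dataset yields ~40,000 per methylation category", {
  ds <- generate_dataset(synthetic_config(seed = 19))
  d <- prepared_data(ds)
  binned <- assign_bins(d)
  sizes <- as.vector(table(binned$meth_category))
  expect_equal(length(sizes), 4L)
  expect_true(all(abs(sizes - 39942) <= 0.01 * 39942))
  # CpG counts are small integers, so boundary ties (all sent to the lower
  # category) can move whole tie groups; sizes must stay within that slack
  cpg_sizes <- as.vector(table(binned$cpg_category))
  expect_equal(length(cpg_sizes), 5L)
  srt <- sort(binned$cpg_count)
  boundary_vals <- srt[floor(1:4 * nrow(d) / 5)]
  tie_slack <- max(table(binned$cpg_count[binned$cpg_count %in%
                                            boundary_vals]))
  expect_true(all(abs(cpg_sizes - nrow(d) / 5) <= tie_slack))
})
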