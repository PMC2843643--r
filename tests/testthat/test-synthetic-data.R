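test_that("generator size bookkeeping and validation", {
  cfg <- small_config(seed = 1, n_promoters = 100L, n_strains = 2L)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$data), 200L)
  expect_equal(nrow(ds$truth), 200L)
  expect_equal(length(unique(ds$data$promoter_id)), 100L)
  expect_equal(length(unique(ds$data$strain_id)), 2L)

  expect_error(synthetic_config(n_promoters = 5), "n_promoters")
  expect_error(synthetic_config(effect_matrix = matrix(0.5, 3, 5)), "4 x 5")
  bad <- default_effect_matrix()
  bad[2, 2] <- 1.2
  expect_error(synthetic_config(effect_matrix = bad), "\\[0, 1\\]")
})

test_that("identical (seed, config) gives bit-identical tables; different seeds differ", {
  cfg <- small_config(seed = 5)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$data, ds2$data)
  expect_identical(ds1$truth, ds2$truth)

  ds3 <- generate_dataset(small_config(seed = 6))
  expect_false(identical(ds1$data$basal_rep1, ds3$data$basal_rep1))

  # written TSVs are byte-identical across repeated writes
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(ds1, d1)
  write_dataset(ds2, d2)
  expect_identical(tools::md5sum(file.path(d1, "data.tsv"))[[1]],
                   tools::md5sum(file.path(d2, "data.tsv"))[[1]])
})

test_that("adding strains does not perturb promoter-level or earlier-strain draws", {
  cfg2 <- small_config(seed = 9, n_promoters = 150L, n_strains = 2L)
  cfg4 <- small_config(seed = 9, n_promoters = 150L, n_strains = 4L)
  ds2 <- generate_dataset(cfg2)
  ds4 <- generate_dataset(cfg4)
  s12 <- ds2$data$strain_id %in% c("strain1", "strain2")
  s14 <- ds4$data$strain_id %in% c("strain1", "strain2")
  expect_identical(ds2$data$cpg_count[s12], ds4$data$cpg_count[s14])
  expect_identical(ds2$data$meth_bin1[s12], ds4$data$meth_bin1[s14])
  expect_identical(ds2$data$basal_rep1[s12], ds4$data$basal_rep1[s14])
})

test_that("generated values respect their support and CpG counts are shared across strains", {
  ds <- generate_dataset(small_config(seed = 13, n_promoters = 500L,
                                      n_strains = 3L))
  d <- ds$data
  meth <- as.matrix(d[, paste0("meth_bin", 1:6)])
  expect_true(all(meth > 0 & meth < 1))
  expect_true(all(d$basal_rep1 > 0 & d$basal_rep2 > 0 &
                    d$treated_rep1 > 0 & d$treated_rep2 > 0))
  expect_true(all(rowSums(d[, paste0("cpg_bin", 1:6)]) == d$cpg_count))
  by_strain <- split(d$cpg_count, d$strain_id)
  expect_identical(by_strain[[1]], by_strain[[2]])
  expect_identical(by_strain[[1]], by_strain[[3]])
})

test_that("truth-table responder count equals the responder-branch draw count", {
  ds <- generate_dataset(small_config(seed = 17, n_promoters = 1000L))
  expect_equal(sum(ds$truth$is_responder), ds$n_responders)
  # responder rows carry their drawn fold/delta; non-responders carry NA
  expect_true(all(!is.na(ds$truth$responder_fold[ds$truth$is_responder])))
  expect_true(all(is.na(ds$truth$responder_fold[!ds$truth$is_responder])))
  with_fold <- ds$truth$responder_fold[ds$truth$is_responder]
  expect_true(all(with_fold >= 2 & with_fold <= 4))
})

test_that("marginal structure: CpG correlates + with expression, - with methylation", {
  ds <- generate_dataset(small_config(seed = 23, n_promoters = 6000L,
                                      n_strains = 1L))
  d <- prepared_data(ds)
  expect_gt(cor(d$cpg_count, d$basal, method = "spearman"), 0.2)
  expect_lt(cor(d$cpg_count, d$meth_total, method = "spearman"), -0.2)
  # bimodal CpG content: both mixture components well represented
  expect_gt(mean(d$cpg_count < 60), 0.25)
  expect_gt(mean(d$cpg_count > 100), 0.25)
})

test_that("an all-zero effect matrix yields <1% threshold crossings from noise", {
  cfg <- synthetic_config(seed = 29, n_promoters = 10000L, n_strains = 1L,
                          effect_matrix = matrix(0, 4, 5))
  ds <- generate_dataset(cfg)
  expect_equal(ds$n_responders, 0L)
  calls <- call_upregulation(prepared_data(ds))
  expect_lt(mean(calls$is_upregulated), 0.01)
})

test_that("planted-signal oracle hits chance without signal and 1 under separation", {
  flat <- synthetic_config(seed = 31, n_promoters = 3000L, n_strains = 1L,
                           effect_matrix = matrix(0.1, 4, 5))
  expect_warning(flat_res <- planted_bayes_auc(flat, n_mc = 3000,
                                               apply_low_basal_filter = FALSE,
                                               label = "responder"),
                 "Monte-Carlo")
  expect_equal(flat_res$auc, 0.5)

  one_cell <- matrix(0, 4, 5)
  one_cell[4, 3] <- 1
  sep <- synthetic_config(seed = 32, n_promoters = 5000L, n_strains = 1L,
                          effect_matrix = one_cell)
  res <- suppressWarnings(planted_bayes_auc(sep, n_mc = 5000,
                                            label = "responder",
                                            apply_low_basal_filter = FALSE))
  expect_equal(res$auc, 1)

  # n_mc below 10^4 is flagged in the metadata
  expect_true(res$small_sample_warning)
  big <- planted_bayes_auc(flat, n_mc = 12000, label = "responder",
                           apply_low_basal_filter = FALSE)
  expect_false(big$small_sample_warning)

  # default surface: a real but imperfect planted signal
  res_def <- planted_bayes_auc(synthetic_config(seed = 33), n_mc = 20000)
  expect_gt(res_def$auc, 0.5)
  expect_lt(res_def$auc, 1.0)
})
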