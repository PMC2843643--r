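test_that("model fitting handles the canonical degenerate cases", {
  set.seed(601)
  n <- 2000
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "f"))
  y_noise <- rbinom(n, 1, 0.3)
  m <- fit_response_model(x, y_noise)
  auc <- roc_curve(predict(m, x), y_noise)$auc
  expect_lt(abs(auc - 0.5), 0.05)   # no-signal feature scores at chance

  # well-separated threshold labels -> near-perfect ranking (ridge fallback)
  y_sep <- as.numeric(x[, 1] > 0)
  expect_warning(m_sep <- fit_response_model(x, y_sep), "separation")
  expect_true(m_sep$ridge)
  expect_gt(roc_curve(predict(m_sep, x), y_sep)$auc, 0.999)

  # gaussian family on two points reproduces the least-squares line
  m_lin <- fit_response_model(matrix(c(0, 1), ncol = 1,
                                     dimnames = list(NULL, "x")),
                              c(0, 1), family = "gaussian")
  expect_equal(unname(m_lin$coefficients), c(0, 1))

  expect_error(fit_response_model(x, rep(1, n)), "single class")
})

test_that("trapezoid ROC AUC equals pairwise concordance with ties at 1/2", {
  set.seed(602)
  for (i in 1:25) {
    n <- sample(20:80, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- rnorm(n) + labels
    if (i %% 2 == 0) scores <- round(scores)   # force score ties
    roc <- roc_curve(scores, labels)
    expect_equal(roc$auc, oracle_concordance_auc(scores, labels),
                 tolerance = 1e-12)
  }
  # constant scores: chance-level line
  expect_equal(roc_curve(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
})

test_that("cross-validated ROC reproduces perfect, chance and worked-example AUCs", {
  set.seed(603)
  y <- rbinom(400, 1, 0.3)
  x_perfect <- matrix(y + 0, ncol = 1, dimnames = list(NULL, "s"))
  suppressWarnings(cv_p <- crossvalidated_roc(x_perfect, y, seed = 1))
  expect_equal(cv_p$fold_aucs, rep(1, 10))
  expect_equal(cv_p$se_auc, 0)

  y_big <- rbinom(10000, 1, 0.2)
  x_noise <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "z"))
  cv_n <- crossvalidated_roc(x_noise, y_big, seed = 2)
  expect_gt(cv_n$mean_auc, 0.47)
  expect_lt(cv_n$mean_auc, 0.53)

  # per-fold AUCs equal the concordance oracle on each held-out fold
  set.seed(604)
  x <- matrix(rnorm(300), ncol = 1, dimnames = list(NULL, "f"))
  y3 <- rbinom(300, 1, plogis(2 * x[, 1]))
  cv <- crossvalidated_roc(x, y3, k = 5, seed = 3)
  for (f in seq_len(5)) {
    test <- cv$folds == f
    m <- fit_response_model(x[!test, , drop = FALSE], y3[!test])
    expect_equal(cv$fold_aucs[f],
                 oracle_concordance_auc(predict(m, x[test, , drop = FALSE]),
                                        y3[test]),
                 tolerance = 1e-12)
  }
  expect_equal(cv$mean_auc, mean(cv$fold_aucs))
  expect_true(all(diff(cv$mean_tpr) >= -1e-12))   # vertical average monotone
})

test_that("stratified folds guarantee both classes per fold and respect the seed", {
  y <- c(rep(1, 15), rep(0, 85))
  folds <- with(list(), {
    set.seed(11)
    make_stratified_folds(y, 10)
  })
  for (f in 1:10) expect_true(any(y[folds == f] == 1))
  expect_error(make_stratified_folds(c(1, rep(0, 50)), 10), "at least k")

  x <- matrix(rnorm(100), ncol = 1, dimnames = list(NULL, "f"))
  cv1 <- crossvalidated_roc(x, y, k = 5, seed = 99)
  cv2 <- crossvalidated_roc(x, y, k = 5, seed = 99)
  expect_identical(cv1$fold_aucs, cv2$fold_aucs)
})

test_that("feature-set comparison shares folds and collapses without signal", {
  ds <- generate_dataset(small_config(seed = 61, n_promoters = 3000L))
  d <- prepared_data(ds)
  calls <- filter_low_basal(call_upregulation(d))
  fs <- compare_feature_sets(calls, seed = 5)
  expect_identical(fs$combined$folds, fs$cpg_only$folds)
  expect_named(fs, c("combined", "methylation_only", "cpg_only"))

  # determinism: same seed, same fold AUCs
  fs2 <- compare_feature_sets(calls, seed = 5)
  expect_identical(fs2$combined$fold_aucs, fs$combined$fold_aucs)

  # ablation: with the planted effect flat across methylation rows (CpG
  # columns only), methylation loses its edge over CpG. It does not fall
  # all the way to 0.5 because methylation and CpG content are correlated
  # by construction, so each proxies the other.
  flat <- synthetic_config(seed = 62, n_promoters = 8000L, n_strains = 2L,
                           effect_matrix = matrix(rep(c(0.02, 0.04, 0.07,
                                                        0.10, 0.13),
                                                      each = 4), 4, 5))
  dsf <- generate_dataset(flat)
  df <- prepared_data(dsf)
  callsf <- filter_low_basal(call_upregulation(df))
  fsf <- compare_feature_sets(callsf, seed = 6)
  expect_lt(fsf$methylation_only$mean_auc,
            fsf$cpg_only$mean_auc + 0.02)
  # whereas the default surface puts methylation clearly ahead of CpG
  expect_gt(fs$methylation_only$mean_auc, fs$cpg_only$mean_auc)
})

test_that("sub-bin sweep covers the seven promoter regions consistently", {
  ds <- generate_dataset(small_config(seed = 63, n_promoters = 4000L))
  d <- prepared_data(ds)
  calls <- filter_low_basal(call_upregulation(d))
  sw <- subbin_model_sweep(calls, seed = 7)
  expect_equal(nrow(sw$table), 7L)
  expect_equal(sw$table$region[1], "full_window")
  expect_equal(sw$table$label[2:7], subbin_grid()$label)

  # full-window row equals the combined feature-set run on the same folds
  fs <- compare_feature_sets(calls, seed = 7)
  expect_equal(sw$table$mean_auc[1], fs$combined$mean_auc, tolerance = 1e-12)
})

test_that("permutation null sits at chance and is reproducible", {
  ds <- generate_dataset(small_config(seed = 71, n_promoters = 2500L))
  d <- prepared_data(ds)
  calls <- filter_low_basal(call_upregulation(d))
  x <- calls[, c("meth_total", "cpg_count")]
  y <- calls$is_upregulated
  p1 <- permutation_null(x, y, n_perm = 3, seed = 123)
  p2 <- permutation_null(x, y, n_perm = 3, seed = 123)
  expect_identical(p1$permuted_aucs, p2$permuted_aucs)
  expect_equal(p1$mean_permuted_auc, mean(p1$permuted_aucs))
  expect_true(all(p1$permuted_aucs >= 0 & p1$permuted_aucs <= 1))
})

test_that("planted methylation effect yields a positive fitted coefficient", {
  hits <- 0L
  for (s in 1:10) {
    ds <- generate_dataset(small_config(seed = 700 + s, n_promoters = 3000L))
    d <- prepared_data(ds)
    calls <- filter_low_basal(call_upregulation(d))
    m <- fit_response_model(calls[, c("meth_total", "cpg_count")],
                            calls$is_upregulated)
    hits <- hits + (m$coefficients[["meth_total"]] > 0)
  }
  expect_gte(hits, 9L)
})
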