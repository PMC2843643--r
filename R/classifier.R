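#' Fit the promoter-response generalized linear model
#'
#' Fits `upregulated ~ promoter methylation + promoter CpG content` (or any
#' supplied feature matrix) by iteratively reweighted least squares. The
#' default binomial family is logistic regression; a gaussian
#' (linear-probability) family is available for comparison, and gives
#' nearly identical rankings for monotone features. On complete separation
#' or non-convergence the binomial fit falls back to a lightly
#' ridge-penalized IRLS with a warning.
#'
#' @param x Numeric matrix or data.frame of features (one column per
#'   feature).
#' @param y Binary labels (logical or 0/1); both classes must be present.
#' @param family `"binomial"` (default) or `"gaussian"`.
#' @return An object of class `response_model` with elements
#'   `coefficients` (intercept first), `family`, `feature_names` and
#'   `ridge` (logical, TRUE when the stabilized fallback was used).
#' @export
fit_response_model <- function(x, y, family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(is.finite(x)), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (family == "binomial" && (sum(y == 0) < 2L || sum(y == 1) < 2L)) {
    stop("need at least 2 records of each class")
  }
  X <- cbind(`(Intercept)` = 1, x)
  ridge <- FALSE
  if (family == "gaussian") {
    beta <- stats::lm.fit(X, y)$coefficients
  } else {
    separated <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-8,
                                                  maxit = 100L)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          separated <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    if (separated || !fit$converged) {
      warning("complete separation or non-convergence; ",
              "using ridge-stabilized logistic fit")
      beta <- ridge_logistic(X, y, lambda = 1e-3)
      ridge <- TRUE
    } else {
      beta <- fit$coefficients
    }
  }
  structure(list(coefficients = beta, family = family,
                 feature_names = colnames(x), ridge = ridge),
            class = "response_model")
}

# IRLS for logistic regression with an L2 penalty on the slopes
# (intercept unpenalized); used only as a separation fallback.
ridge_logistic <- function(X, y, lambda, maxit = 100L, tol = 1e-8) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta <- drop(beta)
  names(beta) <- colnames(X)
  beta
}

#' Score new records with a fitted response model
#'
#' Returns the linear predictor, a monotone transform of the fitted
#' response probability, so rankings (and hence ROC curves) are identical
#' to those of the probability scale.
#'
#' @param object A `response_model`.
#' @param newdata Matrix or data.frame with the model's feature columns.
#' @param ... Unused.
#' @return Numeric score vector.
#' @export
predict.response_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) &&
      !is.null(colnames(newdata)) &&
      all(object$feature_names %in% colnames(newdata))) {
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  drop(cbind(1, newdata) %*% object$coefficients)
}

#' Empirical ROC curve and trapezoid AUC
#'
#' Builds the ROC curve from scores and binary labels, collapsing tied
#' scores into single operating points (which makes the trapezoid-rule
#' area equal to the pairwise-concordance AUC with ties counted 1/2).
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels (logical or 0/1) with both classes present.
#' @return A list with `fpr`, `tpr` (curve points starting at (0,0) and
#'   ending at (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  P <- sum(labels == 1)
  Ng <- sum(labels == 0)
  if (P == 0L || Ng == 0L) stop("both classes required for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  tps <- cumsum(l)
  fps <- cumsum(1 - l)
  keep <- c(diff(s) != 0, TRUE)  # last index within each tied-score block
  tpr <- c(0, tps[keep] / P)
  fpr <- c(0, fps[keep] / Ng)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Stratified cross-validation folds
#'
#' Assigns each record to one of `k` folds, stratifying by label so every
#' fold contains both classes (requires at least `k` records per class).
#'
#' @param labels Binary label vector.
#' @param k Number of folds.
#' @return Integer fold assignment in `1..k`.
#' @export
make_stratified_folds <- function(labels, k = 10L) {
  labels <- as.numeric(labels)
  stopifnot(k >= 2L, all(labels %in% c(0, 1)))
  if (sum(labels == 1) < k || sum(labels == 0) < k) {
    stop("need at least k records of each class for stratified folds")
  }
  fold <- integer(length(labels))
  for (cls in c(0, 1)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Ten-fold cross-validated ROC summary
#'
#' Trains the response model on `k - 1` folds and scores the held-out
#' fold, repeating for each fold. Per-fold AUCs use the trapezoid rule;
#' fold ROC curves are vertically averaged by linear interpolation onto a
#' fixed 101-point false-positive-rate grid, with the standard error
#' across folds at each grid point (mean curve +/- 2 SE is the
#' conventional display).
#'
#' @param x Feature matrix/data.frame.
#' @param y Binary labels.
#' @param k Number of folds (default 10).
#' @param seed Optional integer seed for the fold draw (local RNG use; the
#'   caller's RNG state is restored).
#' @param family Model family, see [fit_response_model()].
#' @param folds Optional pre-computed fold assignment (overrides `k` and
#'   `seed`); used to share folds across feature sets.
#' @param fpr_grid Grid of false-positive rates for curve averaging.
#' @return A list of class `roc_summary`: `feature_names`, `fold_aucs`,
#'   `mean_auc`, `se_auc`, `fpr_grid`, `mean_tpr`, `se_tpr`, `folds`,
#'   `family`.
#' @export
crossvalidated_roc <- function(x, y, k = 10L, seed = NULL,
                               family = "binomial", folds = NULL,
                               fpr_grid = seq(0, 1, length.out = 101L)) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (is.null(folds)) {
    folds <- with_local_seed(seed, make_stratified_folds(y, k))
  }
  k <- max(folds)
  tpr_mat <- matrix(NA_real_, nrow = k, ncol = length(fpr_grid))
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    model <- fit_response_model(x[!test, , drop = FALSE], y[!test],
                                family = family)
    scores <- predict(model, x[test, , drop = FALSE])
    roc <- roc_curve(scores, y[test])
    aucs[f] <- roc$auc
    tpr_mat[f, ] <- stats::approx(roc$fpr, roc$tpr, xout = fpr_grid,
                                  ties = max, rule = 2)$y
  }
  structure(list(
    feature_names = colnames(x),
    fold_aucs = aucs,
    mean_auc = mean(aucs),
    se_auc = stats::sd(aucs) / sqrt(k),
    fpr_grid = fpr_grid,
    mean_tpr = colMeans(tpr_mat),
    se_tpr = apply(tpr_mat, 2, stats::sd) / sqrt(k),
    folds = folds,
    family = family
  ), class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat("Cross-validated ROC (", length(x$fold_aucs), " folds, ",
      x$family, " family): mean AUC = ", sprintf("%.3f", x$mean_auc),
      " (SE ", sprintf("%.3f", x$se_auc), ")\n", sep = "")
  cat("features:", paste(x$feature_names, collapse = " + "), "\n")
  invisible(x)
}

#' Compare combined, methylation-only and CpG-only feature sets
#'
#' Runs cross-validated ROC analyses for the three canonical feature sets
#' over the full promoter window, reusing identical folds so AUC
#' differences are paired comparisons.
#'
#' @param data data.frame with columns `meth_total`, `cpg_count` and
#'   logical `is_upregulated`; normally already restricted with
#'   [filter_low_basal()].
#' @param k,seed,family See [crossvalidated_roc()].
#' @return Named list of `roc_summary` objects: `combined`,
#'   `methylation_only`, `cpg_only`.
#' @export
compare_feature_sets <- function(data, k = 10L, seed = NULL,
                                 family = "binomial") {
  req <- c("meth_total", "cpg_count", "is_upregulated")
  stopifnot(is.data.frame(data), all(req %in% names(data)))
  y <- as.numeric(data$is_upregulated)
  folds <- with_local_seed(seed, make_stratified_folds(y, k))
  feats <- list(
    combined = c("meth_total", "cpg_count"),
    methylation_only = "meth_total",
    cpg_only = "cpg_count"
  )
  lapply(feats, function(cols) {
    crossvalidated_roc(data[, cols, drop = FALSE], y, folds = folds,
                       family = family)
  })
}

#' Sub-bin model sweep across the seven promoter regions
#'
#' Fits the combined (methylation + CpG) model for the full promoter
#' window and for each of the six TSS-distance sub-bins, using per-sub-bin
#' methylation and (when available) per-sub-bin CpG counts. Folds are
#' shared across regions.
#'
#' @param data data.frame with `meth_total`, `cpg_count`,
#'   `meth_bin1..meth_bin6` and optionally `cpg_bin1..cpg_bin6` columns,
#'   plus logical `is_upregulated`.
#' @param k,seed,family See [crossvalidated_roc()].
#' @param subbin_cpg Use per-sub-bin CpG counts when present (default
#'   TRUE); otherwise the total CpG count accompanies each sub-bin's
#'   methylation.
#' @return A list with `table` (data.frame of region label, mean AUC and
#'   SE) and `roc` (named list of `roc_summary` objects).
#' @export
subbin_model_sweep <- function(data, k = 10L, seed = NULL,
                               family = "binomial", subbin_cpg = TRUE) {
  grid <- subbin_grid()
  stopifnot(is.data.frame(data),
            all(c("meth_total", "cpg_count", "is_upregulated") %in% names(data)),
            all(paste0("meth_bin", 1:6) %in% names(data)))
  have_cpg_bins <- all(paste0("cpg_bin", 1:6) %in% names(data))
  y <- as.numeric(data$is_upregulated)
  folds <- with_local_seed(seed, make_stratified_folds(y, k))
  regions <- c(list(full_window = c("meth_total", "cpg_count")),
               stats::setNames(lapply(1:6, function(b) {
                 cpg_col <- if (subbin_cpg && have_cpg_bins) {
                   paste0("cpg_bin", b)
                 } else {
                   "cpg_count"
                 }
                 c(paste0("meth_bin", b), cpg_col)
               }), grid$bin))
  roc <- lapply(regions, function(cols) {
    crossvalidated_roc(data[, cols, drop = FALSE], y, folds = folds,
                       family = family)
  })
  tab <- data.frame(
    region = names(regions),
    label = c(paste(grid$start[1L], "to", paste0("+", grid$end[6L])),
              grid$label),
    mean_auc = vapply(roc, `[[`, numeric(1L), "mean_auc"),
    se_auc = vapply(roc, `[[`, numeric(1L), "se_auc"),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  list(table = tab, roc = roc)
}

#' Label-permutation null distribution of the cross-validated AUC
#'
#' Repeatedly permutes the class labels uniformly at random (features
#' fixed), re-runs the full k-fold cross-validation on each permuted label
#' vector with freshly drawn folds, and records the mean AUC. The mean
#' over permutations sits at chance level (~0.5) for a model with no
#' predictive power.
#'
#' @param x Feature matrix/data.frame.
#' @param y Binary labels.
#' @param n_perm Number of permutations (default 500).
#' @param k Folds per cross-validation (default 10).
#' @param seed Optional integer seed for the permutation stream.
#' @param family Model family.
#' @return A list of class `permutation_result`: `n_permutations`,
#'   `permuted_aucs`, `mean_permuted_auc`, `seed`.
#' @export
permutation_null <- function(x, y, n_perm = 500L, k = 10L, seed = NULL,
                             family = "binomial") {
  stopifnot(n_perm >= 1L)
  x <- as.matrix(x)
  y <- as.numeric(y)
  aucs <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      y_perm <- sample(y)
      crossvalidated_roc(x, y_perm, k = k, family = family)$mean_auc
    }, numeric(1L))
  })
  structure(list(n_permutations = n_perm,
                 permuted_aucs = aucs,
                 mean_permuted_auc = mean(aucs),
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Label-permutation null:", x$n_permutations,
      "permutations, mean AUC =",
      sprintf("%.4f", x$mean_permuted_auc), "\n")
  invisible(x)
}

# Run code under a temporary RNG state when a seed is given, restoring the
# caller's state afterwards; with seed = NULL the global stream is used.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
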