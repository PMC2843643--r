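#' Default planted response-probability matrix
#'
#' Probability of being a treatment responder for each of the 20
#' (methylation category x CpG category) grid cells; rows are methylation
#' categories 1 (least methylated) to 4 (most methylated), columns CpG
#' categories 1 (most CpG-sparse) to 5 (most CpG-dense). The default
#' surface peaks at high methylation with intermediate CpG content and the
#' peak shifts toward CpG-dense promoters as methylation decreases,
#' mirroring the response pattern seen in demethylation experiments.
#'
#' @return A 4 x 5 numeric matrix of probabilities.
#' @export
default_effect_matrix <- function() {
  matrix(c(
    0.012, 0.013, 0.016, 0.020, 0.027,   # low methylation
    0.021, 0.022, 0.028, 0.036, 0.048,
    0.047, 0.050, 0.062, 0.079, 0.055,
    0.140, 0.148, 0.180, 0.100, 0.040    # high methylation
  ), nrow = 4L, byrow = TRUE,
  dimnames = list(meth = paste0("meth", 1:4), cpg = paste0("cpg", 1:5)))
}

#' Configuration for the synthetic promoter dataset generator
#'
#' Defines every distributional choice of the generator: a two-component
#' log-normal mixture for promoter CpG counts (the bimodal CpG-sparse /
#' CpG-island structure of mammalian promoters), per-sub-bin beta
#' methylation whose expectation decreases with CpG density, log-normal
#' basal expression increasing with CpG content and decreasing with
#' methylation (calibrated so roughly 40% of records fall below 700 array
#' units), and a planted (methylation x CpG) response-probability matrix.
#' Responder post-treatment expression is `basal * fold + delta` with
#' `fold ~ U(fold_min, fold_max)` and log-normal `delta`, so planted
#' responders mostly — but not always — pass the two-criterion
#' up-regulation call (realistic label noise); non-responders receive
#' log-normal fold noise around 1.
#'
#' @param seed Integer seed; all randomness flows from it through named
#'   substreams (cpg / meth / expr / response), so adding strains does not
#'   perturb promoter-level draws.
#' @param n_promoters Promoters per strain (default 22824).
#' @param n_strains Number of cell strains (default 7).
#' @param cpg_mixture List: `weight_low` (mixture weight of the CpG-sparse
#'   component), `low_log_mean`, `low_log_sd`, `high_log_mean`,
#'   `high_log_sd` (log-scale parameters of the two count components).
#' @param meth_model List: `island_meth_mean`, `sparse_meth_mean`
#'   (expected per-sub-bin methylation for CpG-dense and CpG-sparse
#'   promoters), `beta_concentration`, `subbin_noise_sd`, and the logistic
#'   link `cpg_log_midpoint`/`cpg_log_scale` interpolating between the two
#'   means as a function of log CpG count.
#' @param expr_model List: `log_basal_base`, `log_basal_cpg_slope`,
#'   `log_basal_meth_slope`, `log_basal_sd`, `replicate_cv` (log-scale SD
#'   of replicate noise).
#' @param effect_matrix 4 x 5 matrix of responder probabilities per
#'   (methylation category, CpG category).
#' @param responder_fold List `fold_min`, `fold_max` for the uniform
#'   responder fold-change.
#' @param responder_delta_log_mean,responder_delta_log_sd Log-normal
#'   parameters of the responder delta expression (array units).
#' @param nonresponder_fold_sd Log-scale SD of non-responder fold noise.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_promoters = 22824L,
                             n_strains = 7L,
                             cpg_mixture = list(weight_low = 0.45,
                                                low_log_mean = log(25),
                                                low_log_sd = 0.55,
                                                high_log_mean = log(160),
                                                high_log_sd = 0.35),
                             meth_model = list(island_meth_mean = 0.15,
                                               sparse_meth_mean = 0.45,
                                               beta_concentration = 8,
                                               subbin_noise_sd = 0.05,
                                               cpg_log_midpoint = log(70),
                                               cpg_log_scale = 1.0),
                             expr_model = list(log_basal_base = 6.55,
                                               log_basal_cpg_slope = 0.55,
                                               log_basal_meth_slope = -0.25,
                                               log_basal_sd = 1.0,
                                               replicate_cv = 0.15),
                             effect_matrix = default_effect_matrix(),
                             responder_fold = list(fold_min = 2,
                                                   fold_max = 4),
                             responder_delta_log_mean = log(8000),
                             responder_delta_log_sd = 0.8,
                             nonresponder_fold_sd = 0.25) {
  cfg <- list(seed = as.integer(seed), n_promoters = as.integer(n_promoters),
              n_strains = as.integer(n_strains), cpg_mixture = cpg_mixture,
              meth_model = meth_model, expr_model = expr_model,
              effect_matrix = effect_matrix,
              responder_fold = responder_fold,
              responder_delta_log_mean = responder_delta_log_mean,
              responder_delta_log_sd = responder_delta_log_sd,
              nonresponder_fold_sd = nonresponder_fold_sd)
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_promoters < 20L) stop("n_promoters must be >= 20")
  if (cfg$n_strains < 1L) stop("n_strains must be >= 1")
  em <- cfg$effect_matrix
  if (!is.matrix(em) || !all(dim(em) == c(4L, 5L))) {
    stop("effect_matrix must be a 4 x 5 matrix")
  }
  if (any(em < 0) || any(em > 1)) {
    stop("effect_matrix probabilities must lie in [0, 1]")
  }
  with(cfg$responder_fold, stopifnot(fold_min > 0, fold_max >= fold_min))
  stopifnot(cfg$expr_model$replicate_cv >= 0,
            cfg$meth_model$beta_concentration > 0,
            cfg$cpg_mixture$weight_low >= 0, cfg$cpg_mixture$weight_low <= 1)
  invisible(cfg)
}

# Named, index-offset substreams derived from the master seed, kept below
# 2^31 - 1 so they are valid set.seed() inputs.
substream_seed <- function(seed, name, index = 0L) {
  offs <- c(cpg = 101, meth = 211, expr = 307, response = 401,
            fasta = 503, bayes = 601, folds = 701, perm = 809)
  if (!name %in% names(offs)) stop("unknown substream: ", name)
  as.integer((abs(as.numeric(seed)) * 7919 + offs[[name]] * 10007 +
                as.numeric(index) * 97) %% 2147483647)
}

# Expected per-sub-bin methylation as a function of CpG count: logistic
# interpolation from the CpG-sparse mean down to the CpG-island mean.
meth_mu_from_cpg <- function(cpg, mm) {
  w_island <- stats::plogis((log(cpg + 1) - mm$cpg_log_midpoint) /
                              mm$cpg_log_scale)
  mm$sparse_meth_mean + (mm$island_meth_mean - mm$sparse_meth_mean) * w_island
}

# Multinomial split of each promoter's CpG count across the six sub-bins,
# vectorized over promoters via sequential binomial thinning.
split_cpg_subbins <- function(cpg, grid = subbin_grid()) {
  lens <- grid$end - grid$start
  n <- length(cpg)
  out <- matrix(0L, nrow = n, ncol = 6L)
  remaining <- cpg
  rem_len <- sum(lens)
  for (b in 1:5) {
    out[, b] <- stats::rbinom(n, remaining, lens[b] / rem_len)
    remaining <- remaining - out[, b]
    rem_len <- rem_len - lens[b]
  }
  out[, 6L] <- remaining
  out
}

#' Generate a seeded synthetic promoter dataset
#'
#' Produces the observable per-(promoter, strain) table — CpG counts
#' (shared across strains for a promoter, with a per-sub-bin breakdown),
#' six sub-bin methylation values, and two replicates each of basal and
#' post-treatment expression — together with a hidden truth table carrying
#' each record's responder flag, generating grid cell and planted
#' response probability. Output is bit-identical for identical
#' (seed, config).
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_dataset` with elements `data`
#'   (observable data.frame), `truth` (hidden truth data.frame),
#'   `n_responders` (count of records drawn from the responder branch) and
#'   `config`.
#' @export
generate_dataset <- function(config) {
  validate_synthetic_config(config)
  np <- config$n_promoters
  ns <- config$n_strains
  mix <- config$cpg_mixture
  mm <- config$meth_model
  em <- config$expr_model

  promoter_id <- sprintf("P%06d", seq_len(np))
  strain_id <- paste0("strain", seq_len(ns))

  # --- promoter-level CpG content (shared across strains) ---
  set.seed(substream_seed(config$seed, "cpg"))
  low <- stats::runif(np) < mix$weight_low
  log_mu <- ifelse(low, mix$low_log_mean, mix$high_log_mean)
  log_sd <- ifelse(low, mix$low_log_sd, mix$high_log_sd)
  cpg <- pmax(1L, as.integer(round(exp(stats::rnorm(np, log_mu, log_sd)))))
  cpg_bins <- split_cpg_subbins(cpg)
  mu_meth <- meth_mu_from_cpg(cpg, mm)

  # --- per-strain methylation ---
  meth <- vector("list", ns)
  for (s in seq_len(ns)) {
    set.seed(substream_seed(config$seed, "meth", s))
    mu_sb <- pmin(pmax(rep(mu_meth, times = 6L) +
                         stats::rnorm(np * 6L, 0, mm$subbin_noise_sd),
                       0.005), 0.995)
    m <- stats::rbeta(np * 6L, mu_sb * mm$beta_concentration,
                      (1 - mu_sb) * mm$beta_concentration)
    meth[[s]] <- matrix(m, nrow = np, ncol = 6L)
  }
  meth_total <- vapply(meth, rowSums, numeric(np))

  # --- per-strain basal expression ---
  log_cpg_c <- log(cpg + 1) - 4       # fixed centering constants
  basal_true <- matrix(0, np, ns)
  basal_rep1 <- basal_rep2 <- matrix(0, np, ns)
  for (s in seq_len(ns)) {
    set.seed(substream_seed(config$seed, "expr", s))
    lb <- em$log_basal_base + em$log_basal_cpg_slope * log_cpg_c +
      em$log_basal_meth_slope * (meth_total[, s] - 2) +
      stats::rnorm(np, 0, em$log_basal_sd)
    basal_true[, s] <- exp(lb)
    basal_rep1[, s] <- basal_true[, s] *
      exp(stats::rnorm(np, 0, em$replicate_cv))
    basal_rep2[, s] <- basal_true[, s] *
      exp(stats::rnorm(np, 0, em$replicate_cv))
  }

  # --- planted response: grid cell from pooled quantile categories ---
  cpg_cat <- assign_quantile_categories(rep(cpg, ns), 5L)[seq_len(np)]
  meth_cat <- assign_quantile_categories(as.vector(meth_total), 4L)
  meth_cat <- matrix(meth_cat, np, ns)
  treated_true <- matrix(0, np, ns)
  treated_rep1 <- treated_rep2 <- matrix(0, np, ns)
  responder <- matrix(FALSE, np, ns)
  p_response <- matrix(0, np, ns)
  fold_drawn <- delta_drawn <- matrix(NA_real_, np, ns)
  for (s in seq_len(ns)) {
    set.seed(substream_seed(config$seed, "response", s))
    p <- config$effect_matrix[cbind(meth_cat[, s], cpg_cat)]
    p_response[, s] <- p
    resp <- stats::runif(np) < p
    responder[, s] <- resp
    fold <- stats::runif(np, config$responder_fold$fold_min,
                         config$responder_fold$fold_max)
    delta <- exp(stats::rnorm(np, config$responder_delta_log_mean,
                              config$responder_delta_log_sd))
    noise_fold <- exp(stats::rnorm(np, 0, config$nonresponder_fold_sd))
    treated_true[, s] <- ifelse(resp,
                                basal_true[, s] * fold + delta,
                                basal_true[, s] * noise_fold)
    fold_drawn[resp, s] <- fold[resp]
    delta_drawn[resp, s] <- delta[resp]
    treated_rep1[, s] <- treated_true[, s] *
      exp(stats::rnorm(np, 0, em$replicate_cv))
    treated_rep2[, s] <- treated_true[, s] *
      exp(stats::rnorm(np, 0, em$replicate_cv))
  }

  meth_cols <- do.call(rbind, meth)
  colnames(meth_cols) <- paste0("meth_bin", 1:6)
  cpg_bin_cols <- cpg_bins[rep(seq_len(np), ns), , drop = FALSE]
  colnames(cpg_bin_cols) <- paste0("cpg_bin", 1:6)
  data <- data.frame(
    promoter_id = rep(promoter_id, ns),
    strain_id = rep(strain_id, each = np),
    cpg_count = rep(cpg, ns),
    cpg_bin_cols,
    meth_cols,
    basal_rep1 = as.vector(basal_rep1),
    basal_rep2 = as.vector(basal_rep2),
    treated_rep1 = as.vector(treated_rep1),
    treated_rep2 = as.vector(treated_rep2),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    promoter_id = rep(promoter_id, ns),
    strain_id = rep(strain_id, each = np),
    is_responder = as.vector(responder),
    response_prob = as.vector(p_response),
    meth_category = as.vector(meth_cat),
    cpg_category = rep(cpg_cat, ns),
    responder_fold = as.vector(fold_drawn),
    responder_delta = as.vector(delta_drawn),
    stringsAsFactors = FALSE
  )
  structure(list(data = data, truth = truth,
                 n_responders = sum(responder), config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic promoter dataset:", x$config$n_promoters, "promoters x",
      x$config$n_strains, "strains (", nrow(x$data), "records,",
      x$n_responders, "planted responders)\n")
  invisible(x)
}

#' Write a synthetic dataset to TSV + JSON
#'
#' Writes the observable table (`data.tsv`), the hidden truth table
#' (`truth.tsv`) and the generating configuration (`config.json`) into a
#' directory. Repeated writes of the same dataset are byte-identical.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(data = file.path(dir, "data.tsv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.json"))
  write_tsv(dataset$data, paths[["data"]])
  write_tsv(dataset$truth, paths[["truth"]])
  cfg <- dataset$config
  cfg$effect_matrix <- as.data.frame(cfg$effect_matrix)
  jsonlite::write_json(unclass(cfg), paths[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Emit promoter FASTA + BED matching the synthetic CpG counts
#'
#' Constructs, for each promoter, a 2,700-bp sequence (in transcription
#' orientation) containing exactly the promoter's per-sub-bin CpG counts:
#' a CG-free random background is generated and CG dinucleotides are then
#' planted at non-adjacent positions inside each sub-bin. The companion
#' BED treats each promoter as its own plus-strand contig, so the
#' FASTA/BED pair round-trips through the sequence feature extractors.
#' Intended for exercising sequence-based feature extraction at small
#' scale rather than for full-size datasets.
#'
#' @param dataset A `synthetic_dataset`.
#' @param fasta_file,bed_file Output paths (`NULL` to skip the BED).
#' @return Invisibly, the FASTA path.
#' @export
write_promoter_fasta <- function(dataset, fasta_file, bed_file = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  grid <- subbin_grid()
  lens <- grid$end - grid$start
  first <- dataset$data$strain_id == dataset$data$strain_id[1L]
  cpg_bins <- as.matrix(dataset$data[first, paste0("cpg_bin", 1:6)])
  ids <- dataset$data$promoter_id[first]
  set.seed(substream_seed(dataset$config$seed, "fasta"))
  lines <- character(0L)
  for (i in seq_len(nrow(cpg_bins))) {
    seq_chars <- random_cg_free_background(sum(lens))
    offset <- 0L
    for (b in 1:6) {
      cnt <- min(cpg_bins[i, b], floor((lens[b] - 1L) / 2L))
      if (cnt > 0L) {
        pos <- sort(sample.int(lens[b] - 1L - (cnt - 1L), cnt)) +
          0:(cnt - 1L) + offset
        seq_chars[pos] <- "C"
        seq_chars[pos + 1L] <- "G"
      }
      offset <- offset + lens[b]
    }
    lines <- c(lines, paste0(">", ids[i]), paste(seq_chars, collapse = ""))
  }
  writeLines(lines, fasta_file)
  if (!is.null(bed_file)) {
    bed <- data.frame(chrom = ids, start = 0L, end = sum(lens),
                      name = ids, score = 0L, strand = "+")
    utils::write.table(bed, bed_file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta_file)
}

# Random A/C/G/T background containing no CG dinucleotide: after a C the
# next base is drawn from {A, C, T}.
random_cg_free_background <- function(len) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  repeat {
    bad <- which(chars[-len] == "C" & chars[-1L] == "G")
    if (!length(bad)) break
    chars[bad + 1L] <- sample(c("A", "C", "T"), length(bad), replace = TRUE)
  }
  chars
}

#' Monte-Carlo oracle AUC of the planted response signal
#'
#' Estimates the AUC attainable by the true generative response
#' probability — the Bayes-optimal score given the promoter's grid cell —
#' on a fresh synthetic sample. This upper-bounds what any classifier
#' trained on (methylation, CpG) features can reach and serves as the
#' recovery target for the cross-validated model.
#'
#' @param config A [synthetic_config()]; the Monte-Carlo sample uses an
#'   independent substream of its seed.
#' @param n_mc Number of Monte-Carlo records (>= 10^4 recommended; smaller
#'   values are flagged in the result metadata).
#' @param thresholds [response_thresholds()] used to label the fresh
#'   sample when `label = "call"` and to apply the low-basal filter.
#' @param label `"call"` (default): score against the two-criterion
#'   up-regulation label, the quantity the classifier predicts; or
#'   `"responder"`: score against the hidden responder flag.
#' @param apply_low_basal_filter Restrict to records with basal expression
#'   below the classifier cutoff (default TRUE, matching the classifier's
#'   training subset).
#' @return A list of class `bayes_auc` with `auc`, `n_used`, `n_mc`,
#'   `label` and `small_sample_warning` (TRUE when `n_mc < 10^4`).
#' @export
planted_bayes_auc <- function(config, n_mc = 20000L,
                              thresholds = response_thresholds(),
                              label = c("call", "responder"),
                              apply_low_basal_filter = TRUE) {
  label <- match.arg(label)
  validate_synthetic_config(config)
  small <- n_mc < 1e4
  if (small) {
    warning("n_mc < 10^4; Monte-Carlo error may be large")
  }
  cfg <- config
  cfg$n_promoters <- as.integer(ceiling(n_mc / config$n_strains))
  cfg$seed <- substream_seed(config$seed, "bayes")
  class(cfg) <- "synthetic_config"
  ds <- generate_dataset(cfg)
  df <- ensure_expression_means(ds$data)
  df$score <- ds$truth$response_prob
  df$y <- if (label == "call") {
    call_upregulation(df, thresholds)$is_upregulated
  } else {
    ds$truth$is_responder
  }
  if (apply_low_basal_filter) {
    df <- df[df$basal < thresholds$low_expression_cutoff, , drop = FALSE]
  }
  auc <- if (length(unique(df$y)) < 2L) {
    NA_real_
  } else {
    roc_curve(df$score, df$y)$auc
  }
  structure(list(auc = auc, n_used = nrow(df), n_mc = n_mc, label = label,
                 small_sample_warning = small),
            class = "bayes_auc")
}

#' @export
print.bayes_auc <- function(x, ...) {
  cat("Planted-signal oracle AUC:", sprintf("%.3f", x$auc),
      "(", x$n_used, "records, label =", x$label, ")\n")
  invisible(x)
}
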