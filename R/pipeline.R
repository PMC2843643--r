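#' End-to-end pipeline configuration
#'
#' Bundles every stage option: the synthetic generator (or paths to
#' pre-computed observable tables), calling thresholds, binning and
#' classifier settings, and the master seed from which all stage
#' substreams derive.
#'
#' @param seed Master seed (integer).
#' @param synthetic A [synthetic_config()]; its seed is forced to `seed`.
#' @param input_tsv Optional path to an observable table TSV with the
#'   generator's schema; when given, the simulate stage loads it instead
#'   of generating.
#' @param thresholds A [response_thresholds()].
#' @param k_cpg,k_meth,cpg_binning Binning options, see [assign_bins()].
#' @param family,feature_representation Classifier options
#'   (`"binomial"`/`"gaussian"`; `"continuous"` uses raw `meth_total` and
#'   `cpg_count`, `"categorical"` the grid category codes).
#' @param k_folds Cross-validation folds (default 10).
#' @param n_perm Label permutations (default 500; 0 skips the stage).
#' @param classifier_strain Strain used for the classifier stage:
#'   `"auto"` picks the strain with the most up-regulated calls (the
#'   selection rule used for single-strain modeling), or give a strain id.
#' @param verbose Emit per-stage log messages (default TRUE).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            synthetic = synthetic_config(seed = seed),
                            input_tsv = NULL,
                            thresholds = response_thresholds(),
                            k_cpg = 5L, k_meth = 4L,
                            cpg_binning = "quantile",
                            family = "binomial",
                            feature_representation = c("continuous",
                                                       "categorical"),
                            k_folds = 10L,
                            n_perm = 500L,
                            classifier_strain = "auto",
                            verbose = TRUE) {
  feature_representation <- match.arg(feature_representation)
  synthetic$seed <- as.integer(seed)
  validate_synthetic_config(synthetic)
  structure(list(seed = as.integer(seed), synthetic = synthetic,
                 input_tsv = input_tsv, thresholds = thresholds,
                 k_cpg = k_cpg, k_meth = k_meth, cpg_binning = cpg_binning,
                 family = family,
                 feature_representation = feature_representation,
                 k_folds = k_folds, n_perm = as.integer(n_perm),
                 classifier_strain = classifier_strain, verbose = verbose),
            class = "pipeline_config")
}

stage_log <- function(config, stage, ...) {
  if (isTRUE(config$verbose)) {
    message("[", stage, "] ", ...)
  }
}

#' Run the full promoter-response pipeline
#'
#' Executes simulate (or load) -> features/binning -> up-regulation
#' calling -> grid statistics -> classifier (feature-set comparison and
#' sub-bin sweep) -> label-permutation null, writing each stage's
#' artifacts plus a deterministic run manifest (row counts and MD5
#' checksums) into `out_dir`. A stage failure halts the run with the
#' failing stage named.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # simulate / load
  truth <- NULL
  data <- run_stage("simulate", {
    if (!is.null(config$input_tsv)) {
      stage_log(config, "simulate", "loading ", config$input_tsv)
      read_tsv(config$input_tsv)
    } else {
      ds <- generate_dataset(config$synthetic)
      truth <- ds$truth
      write_tsv(ds$truth, file.path(out_dir, "truth.tsv"))
      stage_log(config, "simulate", nrow(ds$data), " records (",
                ds$n_responders, " planted responders)")
      ds$data
    }
  })
  write_tsv(data, file.path(out_dir, "data.tsv"))
  counts$records <- nrow(data)

  # features + binning
  features <- run_stage("features", {
    df <- ensure_expression_means(data)
    df$meth_total <- aggregate_methylation(df[, paste0("meth_bin", 1:6)])
    assign_bins(df, k_cpg = config$k_cpg, k_meth = config$k_meth,
                cpg_binning = config$cpg_binning)
  })
  jsonlite::write_json(attr(features, "boundaries"),
                       file.path(out_dir, "bin_boundaries.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv(features, file.path(out_dir, "features.tsv"))
  stage_log(config, "features", nrow(features), " records binned into ",
            config$k_meth, " x ", config$k_cpg, " grid")

  # up-regulation calls
  pooled <- run_stage("call", {
    calls <- call_upregulation(features, config$thresholds)
    pool_calls(calls)
  })
  write_tsv(pooled$calls[, c("promoter_id", "strain_id", "fold_change",
                             "delta", "is_upregulated")],
            file.path(out_dir, "calls.tsv"))
  counts$upregulated_pairs <- pooled$n_upregulated_pairs
  stage_log(config, "call", pooled$n_upregulated_pairs,
            " up-regulated (promoter, strain) pairs; ",
            pooled$n_upregulated_genes, " unique promoters")

  # grid statistics
  summary_grid <- run_stage("enrich", {
    build_summary_grid(bin_tests(pooled$calls))
  })
  write_tsv(summary_grid$grid, file.path(out_dir, "grid.tsv"))

  # classifier
  strain <- config$classifier_strain
  classifier_data <- run_stage("classify-prepare", {
    if (identical(strain, "auto")) {
      ps <- pooled$per_strain
      strain <- ps$strain_id[which.max(ps$n_upregulated)]
    }
    sub <- pooled$calls[pooled$calls$strain_id == strain, , drop = FALSE]
    flt <- filter_low_basal(sub, config$thresholds)
    stage_log(config, "classify", "strain ", strain, ": ", nrow(flt),
              " low-basal records (", sprintf("%.1f",
              100 * attr(flt, "retained_fraction")), "% retained)")
    flt
  })
  counts$classifier_records <- nrow(classifier_data)
  if (config$feature_representation == "categorical") {
    classifier_data$meth_total <- as.numeric(classifier_data$meth_category)
    classifier_data$cpg_count <- as.numeric(classifier_data$cpg_category)
  }
  fs <- run_stage("classify", {
    compare_feature_sets(classifier_data, k = config$k_folds,
                         seed = substream_seed(config$seed, "folds"),
                         family = config$family)
  })
  sweep <- run_stage("classify-subbins", {
    subbin_model_sweep(classifier_data, k = config$k_folds,
                       seed = substream_seed(config$seed, "folds"),
                       family = config$family)
  })
  auc_tab <- data.frame(
    feature_set = names(fs),
    mean_auc = vapply(fs, `[[`, numeric(1L), "mean_auc"),
    se_auc = vapply(fs, `[[`, numeric(1L), "se_auc")
  )
  write_tsv(auc_tab, file.path(out_dir, "feature_set_aucs.tsv"))
  write_tsv(sweep$table, file.path(out_dir, "subbin_aucs.tsv"))
  roc_points <- do.call(rbind, lapply(names(fs), function(nm) {
    data.frame(feature_set = nm, fpr = fs[[nm]]$fpr_grid,
               mean_tpr = fs[[nm]]$mean_tpr, se_tpr = fs[[nm]]$se_tpr)
  }))
  write_tsv(roc_points, file.path(out_dir, "roc_points.tsv"))

  # permutation null
  perm <- NULL
  if (config$n_perm > 0L) {
    perm <- run_stage("permute", {
      permutation_null(classifier_data[, c("meth_total", "cpg_count")],
                       classifier_data$is_upregulated,
                       n_perm = config$n_perm, k = config$k_folds,
                       seed = substream_seed(config$seed, "perm"),
                       family = config$family)
    })
    write_tsv(data.frame(permutation = seq_len(perm$n_permutations),
                         auc = perm$permuted_aucs),
              file.path(out_dir, "permutation_aucs.tsv"))
    stage_log(config, "permute", perm$n_permutations,
              " permutations, mean AUC ",
              sprintf("%.4f", perm$mean_permuted_auc))
  } else {
    stage_log(config, "permute", "n_perm = 0; permutation stage skipped")
  }

  # config + manifest (deterministic: no timestamps)
  cfg_json <- config
  cfg_json$synthetic$effect_matrix <-
    as.data.frame(cfg_json$synthetic$effect_matrix)
  jsonlite::write_json(lapply(unclass(cfg_json), unclass),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  artifacts <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    stages = c("simulate", "features", "call", "enrich", "classify",
               if (config$n_perm > 0L) "permute"),
    row_counts = counts,
    classifier_strain = strain,
    checksums = as.list(tools::md5sum(file.path(out_dir, artifacts)))
  )
  names(manifest$checksums) <- artifacts
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(data = data, truth = truth, features = features,
                 pooled = pooled, summary_grid = summary_grid,
                 feature_sets = fs, subbin_sweep = sweep,
                 permutation = perm, manifest = manifest))
}

#' Harmonize an external methylation/response dataset onto the reference
#'
#' Rescales an external methylation distribution onto the reference scale
#' by matching 90th quantiles, applies the absolute low/intermediate/high
#' methylation categories, restricts to genes whose expression fold-change
#' meets `fold_min`, and cross-tabulates the responsive genes by
#' methylation category (and by CpG category when provided). This is the
#' cross-dataset workflow used to check the response pattern in an
#' independent cell line whose methylation is measured on a different
#' platform.
#'
#' @param external data.frame with columns `gene`, `meth`
#'   (platform-native methylation), `fold_change`, and optionally
#'   `cpg_category`.
#' @param reference_meth Numeric vector of reference-scale methylation
#'   values (the pooled promoter methylation distribution).
#' @param fold_min Minimum fold-change for a responsive gene (default 2).
#' @return A list of class `harmonized_external`: `scaled` (the external
#'   table with `meth_scaled` and `meth_abs_category`), `responsive`
#'   (filtered table), `counts` (responsive genes per methylation
#'   category) and `crosstab` (methylation x CpG category counts, or NULL).
#' @export
harmonize_external_dataset <- function(external, reference_meth,
                                       fold_min = 2) {
  stopifnot(is.data.frame(external),
            all(c("gene", "meth", "fold_change") %in% names(external)),
            nrow(external) > 0L, length(reference_meth) > 0L)
  external$meth_scaled <- scale_methylation_to_reference(external$meth,
                                                         reference_meth)
  external$meth_abs_category <-
    categorize_methylation_absolute(external$meth_scaled)
  responsive <- external[external$fold_change >= fold_min, , drop = FALSE]
  if (nrow(responsive) == 0L) {
    warning("no genes pass the fold-change filter")
  }
  counts <- table(responsive$meth_abs_category)
  crosstab <- NULL
  if ("cpg_category" %in% names(external) && nrow(responsive) > 0L) {
    crosstab <- table(responsive$meth_abs_category, responsive$cpg_category)
  }
  structure(list(scaled = external, responsive = responsive,
                 counts = counts, crosstab = crosstab),
            class = "harmonized_external")
}

#' @export
print.harmonized_external <- function(x, ...) {
  cat("External dataset harmonization:", nrow(x$responsive),
      "responsive genes\n")
  print(x$counts)
  invisible(x)
}
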