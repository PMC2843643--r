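#' Thresholds for the two-criterion up-regulation call
#'
#' A promoter counts as up-regulated when the replicate-averaged
#' post-treatment expression shows a fold-change of at least `fold_min`
#' AND an absolute increase of at least `delta_min` array units. The
#' delta criterion exists to remove the bias by which a pure fold-change
#' rule favors promoters with low basal expression (which are enriched
#' for low CpG content). `low_expression_cutoff` is the basal-expression
#' ceiling (strict `<`) used to focus the classifier on silenced genes.
#'
#' @param fold_min Minimum post/pre expression ratio (inclusive, default 2).
#' @param delta_min Minimum post - pre expression increase in array units
#'   (inclusive, default 5000).
#' @param low_expression_cutoff Basal expression cutoff for the classifier
#'   subset, strict less-than (default 700 array units).
#' @return A list of class `response_thresholds`.
#' @export
response_thresholds <- function(fold_min = 2, delta_min = 5000,
                                low_expression_cutoff = 700) {
  stopifnot(fold_min > 0, delta_min > 0, low_expression_cutoff > 0)
  structure(list(fold_min = fold_min, delta_min = delta_min,
                 low_expression_cutoff = low_expression_cutoff),
            class = "response_thresholds")
}

ensure_expression_means <- function(profiles) {
  if (!("basal" %in% names(profiles))) {
    stopifnot(all(c("basal_rep1", "basal_rep2") %in% names(profiles)))
    profiles$basal <- (profiles$basal_rep1 + profiles$basal_rep2) / 2
  }
  if (!("treated" %in% names(profiles))) {
    stopifnot(all(c("treated_rep1", "treated_rep2") %in% names(profiles)))
    profiles$treated <- (profiles$treated_rep1 + profiles$treated_rep2) / 2
  }
  profiles
}

#' Call up-regulation with the fold-change + delta-expression rule
#'
#' Applies the inclusive two-criterion rule to replicate-averaged
#' expression: `treated / basal >= fold_min` and
#' `treated - basal >= delta_min`.
#'
#' @param profiles data.frame with columns `promoter_id`, `strain_id` and
#'   either `basal`/`treated` means or `basal_rep1`,`basal_rep2`,
#'   `treated_rep1`,`treated_rep2` (means are then computed as the
#'   arithmetic replicate average). Extra columns are carried through.
#' @param thresholds A [response_thresholds()] object.
#' @return The input with columns `fold_change`, `delta` and logical
#'   `is_upregulated` appended.
#' @examples
#' p <- data.frame(promoter_id = "P1", strain_id = "S1",
#'                 basal = 1000, treated = 6000)
#' call_upregulation(p)$is_upregulated  # TRUE (fold 6, delta 5000)
#' @export
call_upregulation <- function(profiles, thresholds = response_thresholds()) {
  stopifnot(is.data.frame(profiles), nrow(profiles) > 0L,
            inherits(thresholds, "response_thresholds"))
  profiles <- ensure_expression_means(profiles)
  if (any(profiles$basal <= 0) || any(profiles$treated <= 0)) {
    stop("non-positive expression value; fold-change undefined — ",
         "reject the offending records upstream")
  }
  profiles$fold_change <- profiles$treated / profiles$basal
  profiles$delta <- profiles$treated - profiles$basal
  profiles$is_upregulated <- profiles$fold_change >= thresholds$fold_min &
    profiles$delta >= thresholds$delta_min
  profiles
}

#' Pool per-strain calls and summarize counts
#'
#' @param calls data.frame of calls from [call_upregulation()], one row per
#'   (promoter, strain); duplicated keys are an error.
#' @return A list of class `pooled_calls` with elements `calls`,
#'   `per_strain` (data.frame of per-strain record and up-regulated
#'   counts), `n_upregulated_pairs` (pooled (promoter, strain) pairs
#'   passing), `n_upregulated_genes` (unique promoters passing in at least
#'   one strain), and — when the calls carry `cpg_category`/`meth_category`
#'   columns — `grid_percent`, the per-grid-cell percent up-regulated.
#' @export
pool_calls <- function(calls) {
  if (!is.data.frame(calls) || nrow(calls) == 0L) {
    stop("no calls to pool")
  }
  stopifnot(all(c("promoter_id", "strain_id", "is_upregulated") %in%
                  names(calls)))
  key <- paste(calls$promoter_id, calls$strain_id, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (promoter, strain) keys")
  per_strain <- stats::aggregate(is_upregulated ~ strain_id, data = calls,
                          FUN = function(x) c(n = length(x), up = sum(x)))
  per_strain <- data.frame(strain_id = per_strain$strain_id,
                           n_records = per_strain$is_upregulated[, "n"],
                           n_upregulated = per_strain$is_upregulated[, "up"],
                           stringsAsFactors = FALSE)
  out <- list(
    calls = calls,
    per_strain = per_strain,
    n_upregulated_pairs = sum(calls$is_upregulated),
    n_upregulated_genes = length(unique(calls$promoter_id[calls$is_upregulated]))
  )
  if (all(c("cpg_category", "meth_category") %in% names(calls))) {
    tab_n <- table(calls$meth_category, calls$cpg_category)
    tab_up <- table(calls$meth_category[calls$is_upregulated],
                    calls$cpg_category[calls$is_upregulated])
    pct <- 100 * as.matrix(tab_up)[rownames(tab_n), colnames(tab_n),
                                   drop = FALSE] / as.matrix(tab_n)
    out$grid_percent <- pct
  }
  class(out) <- "pooled_calls"
  out
}

#' @export
print.pooled_calls <- function(x, ...) {
  cat("Pooled up-regulation calls:", nrow(x$calls), "records,",
      x$n_upregulated_pairs, "up-regulated (promoter, strain) pairs,",
      x$n_upregulated_genes, "unique promoters\n")
  invisible(x)
}

#' Restrict to promoters with low basal expression
#'
#' Keeps records whose basal expression is strictly below the
#' `low_expression_cutoff` threshold (default 700 array units), the subset
#' on which the response classifier is trained. The retained fraction is
#' attached as attribute `"retained_fraction"`.
#'
#' @param profiles data.frame with a `basal` column (or replicate columns
#'   from which it is computed).
#' @param thresholds A [response_thresholds()] object.
#' @return The filtered data.frame.
#' @export
filter_low_basal <- function(profiles, thresholds = response_thresholds()) {
  stopifnot(is.data.frame(profiles))
  profiles <- ensure_expression_means(profiles)
  keep <- profiles$basal < thresholds$low_expression_cutoff
  out <- profiles[keep, , drop = FALSE]
  attr(out, "retained_fraction") <- mean(keep)
  out
}
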