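#' TSS-anchored sub-bin grid for the promoter window
#'
#' The promoter window runs from 2,200 bp upstream to 500 bp downstream of
#' the transcription start site (TSS), in transcription orientation, and is
#' partitioned into six half-open sub-bins. Offsets are 0-based relative to
#' the TSS, so the window is `[-2200, +500)` and spans exactly 2,700 bases.
#'
#' @return A data.frame with one row per sub-bin and columns `bin`
#'   (`"bin1"`..`"bin6"`), `label` (human-readable distance range), `start`
#'   and `end` (half-open offsets relative to the TSS).
#' @examples
#' g <- subbin_grid()
#' sum(g$end - g$start)  # 2700
#' @export
subbin_grid <- function() {
  data.frame(
    bin = paste0("bin", 1:6),
    label = c("-2200 to -1500", "-1500 to -1000", "-1000 to -500",
              "-500 to -200", "-200 to +100", "+100 to +500"),
    start = c(-2200L, -1500L, -1000L, -500L, -200L, 100L),
    end = c(-1500L, -1000L, -500L, -200L, 100L, 500L),
    stringsAsFactors = FALSE
  )
}

window_length <- function(grid = subbin_grid()) sum(grid$end - grid$start)

#' Count CpG dinucleotides in a promoter window
#'
#' Counts occurrences of the dinucleotide `CG` in a promoter sequence given
#' in transcription orientation, both in total and per sub-bin. A CG whose
#' two bases straddle a sub-bin boundary is assigned to the sub-bin of its
#' first base. `N` bases never match.
#'
#' @param sequence A single character string over the alphabet A/C/G/T/N,
#'   whose length equals the grid's window length (2,700 for the default
#'   grid), 5' to 3' in transcription orientation.
#' @param grid Sub-bin grid, as returned by [subbin_grid()].
#' @return A list with `total` (integer) and `per_subbin` (integer vector of
#'   length `nrow(grid)` named by bin).
#' @examples
#' s <- paste0("CGCG", strrep("A", 2696))
#' count_cpg(s)$total  # 2
#' @export
count_cpg <- function(sequence, grid = subbin_grid()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  len <- window_length(grid)
  if (nchar(sequence) != len) {
    stop("sequence must have length ", len, ", got ", nchar(sequence))
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% c("A", "C", "G", "T", "N"))
  if (any(bad)) {
    stop("non-IUPAC-DNA characters in sequence: ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  starts <- which(chars[-len] == "C" & chars[-1L] == "G")
  # half-open cumulative bin ends in window coordinates (1-based first base)
  bin_ends <- cumsum(grid$end - grid$start)
  bin_idx <- findInterval(starts - 1L, c(0L, bin_ends[-length(bin_ends)] ))
  per <- tabulate(bin_idx, nbins = nrow(grid))
  names(per) <- grid$bin
  list(total = length(starts), per_subbin = as.integer(per))
}

#' Aggregate sub-bin methylation into a single promoter-level value
#'
#' The promoter-level methylation measurement is the exact sum of the six
#' sub-bin relative methylation values. Records with any missing or
#' non-finite sub-bin value are rejected rather than imputed.
#'
#' @param meth_subbin Either a numeric vector of length 6 or a numeric
#'   matrix/data.frame with 6 columns (one row per record).
#' @return A single numeric value, or a numeric vector with one sum per row.
#' @examples
#' aggregate_methylation(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))  # 2.1
#' @export
aggregate_methylation <- function(meth_subbin) {
  if (is.data.frame(meth_subbin)) meth_subbin <- as.matrix(meth_subbin)
  if (is.matrix(meth_subbin)) {
    if (ncol(meth_subbin) != 6L) stop("expected 6 sub-bin columns")
    if (any(!is.finite(meth_subbin))) {
      stop("missing or non-finite sub-bin methylation value; ",
           "records with incomplete sub-bin data must be dropped upstream")
    }
    return(rowSums(meth_subbin))
  }
  if (length(meth_subbin) != 6L) stop("expected 6 sub-bin values")
  if (any(!is.finite(meth_subbin))) {
    stop("missing or non-finite sub-bin methylation value")
  }
  sum(meth_subbin)
}

#' Assign equal-count quantile categories
#'
#' Splits a pooled value vector into `k` categories holding (up to
#' tie-slack) equal numbers of records. Category boundaries are order
#' statistics at positions `floor(i * n / k)`; values tied at a boundary all
#' receive the lower category, so heavy ties can leave categories empty.
#' Category labels are `1..k` with `k` the largest values.
#'
#' @param values Numeric vector (finite), `length(values) >= k`.
#' @param k Number of categories (5 for CpG content, 4 for methylation in
#'   the default pipeline).
#' @return Integer vector of categories in `1..k`, same length as `values`.
#' @examples
#' table(assign_quantile_categories(1:100, 5))  # 20 each
#' @export
assign_quantile_categories <- function(values, k) {
  stopifnot(is.numeric(values), length(k) == 1L, k >= 1L)
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  if (n < k) stop("need at least k values (n = ", n, ", k = ", k, ")")
  if (length(unique(values)) == 1L) {
    warning("all values identical; assigning a single category")
    return(rep(1L, n))
  }
  s <- sort(values)
  breaks <- s[floor(seq_len(k - 1L) * n / k)]
  # ties at a boundary go to the lower category: category = 1 + #{breaks < x}
  cat <- rep(1L, n)
  for (b in breaks) cat <- cat + (values > b)
  as.integer(cat)
}

#' Assign equal-width categories
#'
#' Alternative binning that splits the observed value range into `k`
#' intervals of equal width (upper-inclusive except the first interval,
#' which includes its lower edge).
#'
#' @inheritParams assign_quantile_categories
#' @return Integer vector of categories in `1..k`.
#' @export
assign_width_categories <- function(values, k) {
  stopifnot(is.numeric(values), length(k) == 1L, k >= 1L)
  if (any(!is.finite(values))) stop("values must be finite")
  rng <- range(values)
  if (diff(rng) == 0) {
    warning("all values identical; assigning a single category")
    return(rep(1L, length(values)))
  }
  brk <- seq(rng[1L], rng[2L], length.out = k + 1L)
  as.integer(cut(values, breaks = brk, include.lowest = TRUE, labels = FALSE))
}

#' Assign promoter grid categories (CpG x methylation)
#'
#' Computes the 5-level CpG-content category and the 4-level methylation
#' category for a pooled feature table (all strains together, matching the
#' pooled "~40,000 promoters per methylation category" construction).
#'
#' @param features data.frame with at least columns `cpg_count` and
#'   `meth_total`.
#' @param k_cpg Number of CpG categories (default 5; 5 = most CpG-dense).
#' @param k_meth Number of methylation categories (default 4; 4 = most
#'   methylated).
#' @param cpg_binning `"quantile"` (equal-count, default) or `"width"`
#'   (equal-width) binning for CpG content; methylation is always
#'   equal-count.
#' @return The input data.frame with integer columns `cpg_category` and
#'   `meth_category` appended. The category boundaries used are attached as
#'   attribute `"boundaries"` (a list suitable for JSON serialization).
#' @export
assign_bins <- function(features, k_cpg = 5L, k_meth = 4L,
                        cpg_binning = c("quantile", "width")) {
  cpg_binning <- match.arg(cpg_binning)
  stopifnot(is.data.frame(features),
            all(c("cpg_count", "meth_total") %in% names(features)))
  features$cpg_category <- switch(cpg_binning,
    quantile = assign_quantile_categories(features$cpg_count, k_cpg),
    width = assign_width_categories(features$cpg_count, k_cpg))
  features$meth_category <- assign_quantile_categories(features$meth_total,
                                                       k_meth)
  bounds <- list(
    k_cpg = k_cpg, k_meth = k_meth, cpg_binning = cpg_binning,
    cpg_upper = as.numeric(tapply(features$cpg_count, features$cpg_category, max)),
    meth_upper = as.numeric(tapply(features$meth_total, features$meth_category, max))
  )
  attr(features, "boundaries") <- bounds
  features
}

#' Rescale an external methylation distribution onto a reference scale
#'
#' Matches the 90th quantile of an external methylation data set (for
#' example sequencing-read counts from another platform) to the 90th
#' quantile of the reference (array-derived) distribution, so absolute
#' category thresholds defined on the reference scale can be applied.
#'
#' @param external_values Non-negative numeric vector to rescale.
#' @param reference_values Non-negative numeric vector defining the target
#'   scale; its 90th quantile must be positive.
#' @return `external_values * q90(reference) / q90(external)`.
#' @export
scale_methylation_to_reference <- function(external_values, reference_values) {
  stopifnot(length(external_values) > 0L, length(reference_values) > 0L)
  if (any(external_values < 0, na.rm = TRUE) ||
      any(reference_values < 0, na.rm = TRUE)) {
    stop("methylation values must be non-negative")
  }
  q_ext <- stats::quantile(external_values, 0.9, names = FALSE, na.rm = TRUE)
  q_ref <- stats::quantile(reference_values, 0.9, names = FALSE, na.rm = TRUE)
  if (q_ref <= 0) stop("reference 90th quantile must be positive")
  if (q_ext <= 0) stop("degenerate external distribution: 90th quantile is 0")
  external_values * (q_ref / q_ext)
}

#' Absolute methylation categories (low / intermediate / high)
#'
#' Categorizes promoter methylation on the reference scale into low
#' `[0, 1]`, intermediate `(1, 6]`, and high `(6, Inf)`. Boundaries are
#' upper-inclusive, the only reading consistent with "high" being strictly
#' greater than 6.
#'
#' @param values Non-negative numeric vector.
#' @param low_max Upper bound of the low category (default 1).
#' @param intermediate_max Upper bound of the intermediate category
#'   (default 6).
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @examples
#' categorize_methylation_absolute(c(0.5, 6, 6.01, 7.5))
#' @export
categorize_methylation_absolute <- function(values, low_max = 1,
                                            intermediate_max = 6) {
  stopifnot(is.numeric(values))
  if (any(values < 0, na.rm = TRUE)) stop("methylation values must be >= 0")
  cut(values, breaks = c(-Inf, low_max, intermediate_max, Inf),
      labels = c("low", "intermediate", "high"), right = TRUE)
}
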