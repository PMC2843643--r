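---
title: "Modeling demethylation-induced up-regulation from promoter CpG content and methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling demethylation-induced up-regulation from promoter CpG content and methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demethpred)
```

## The scientific question

Demethylating agents such as decitabine (5-aza-2'-deoxycytidine) inhibit
DNA methyltransferase and can re-activate genes silenced by promoter
hypermethylation, but only a subset of silenced loci actually respond.
`demethpred` implements an analysis of which *promoter characteristics*
predict that response, using two covariates that are measurable genome-wide
before treatment:

* **CpG content** — the number of CG dinucleotides in the promoter window
  running from 2,200 bp upstream to 500 bp downstream of the transcription
  start site (2,700 bp, in transcription orientation). Mammalian promoters
  are bimodal on this axis: CpG-sparse promoters versus CpG-island
  promoters.
* **Basal methylation** — relative methylation (e.g., MeDIP-array derived)
  reported for six sub-bins partitioning the same window
  (`-2200..-1500`, `-1500..-1000`, `-1000..-500`, `-500..-200`,
  `-200..+100`, `+100..+500`), summarized as the *sum* of the six values.

The pipeline has four statistical stages:

1. **Stratification.** Promoters pooled across all cell strains are cut
   into a 4 (methylation) x 5 (CpG) grid by equal-count quantile binning
   (so each methylation category holds roughly a quarter of the pooled
   records).
2. **Response calling.** A record is up-regulated when
   post/pre expression $\ge 2$ **and** post $-$ pre $\ge 5{,}000$ array
   units. The second criterion removes the bias by which a pure
   fold-change rule favors genes with low basal expression — a set
   enriched for CpG-sparse promoters.
3. **Per-cell statistics.** Each grid cell gets a one-sided Wilcoxon
   signed-rank test of expression increase and one-sided hypergeometric
   tail tests for enrichment/depletion of up-regulated records against
   the pooled universe.
4. **Response classification.** A generalized linear model
   (`upregulated ~ methylation + CpG content`) is trained on the
   low-basal-expression subset (basal $< 700$ units, about 40% of
   records) of a single strain, evaluated by stratified ten-fold
   cross-validated ROC/AUC, compared across feature sets and promoter
   sub-regions, and checked against a label-permutation null.

## Binning semantics

Equal-count categories use order-statistic boundaries at positions
$\lfloor i\,n/k \rfloor$; values tied at a boundary all take the lower
category. For continuous methylation sums this yields four categories
within a fraction of a percent of $n/4$ (159,768 pooled records give
39,942 per category). For integer CpG counts, tie groups at boundaries can
shift category sizes by up to one tie-group; the tie rule is deterministic
and category assignment is invariant under any strictly monotone transform
of the values. "Five equal categories" of CpG content is read as
equal-count quantiles for symmetry with the methylation binning
(equal-width binning is available via `assign_bins(cpg_binning =
"width")`); equal-count avoids empty CpG categories under bimodality, and
per-bin percentages are meaningful under either convention.

Boundary conventions elsewhere in the pipeline, chosen once and applied
inclusively as printed: up-regulation thresholds are inclusive ($\ge 2$,
$\ge 5{,}000$), the low-expression filter is strict ($< 700$), and the
absolute methylation categories used for cross-dataset harmonization are
upper-inclusive (low $[0,1]$, intermediate $(1,6]$, high $> 6$) — the only
reading consistent with "high" being strictly greater than 6.

## Test statistics

**Signed-rank.** Zero paired differences are dropped; ties among absolute
differences get mid-ranks. For $n \le 25$ the one-sided p-value
$P(W \ge w)$ is computed exactly by convolving the doubled mid-ranks
(exact even under ties, which `stats::wilcox.test` does not offer); larger
cells use the normal approximation with tie-corrected variance and
continuity correction. A cell whose differences are all zero reports
$p = 1$ with a warning.

**Hypergeometric.** With $k$ up-regulated among $n$ cell records, drawn
from $N$ pooled records of which $K$ are up-regulated, the cell's
enrichment p-value is $P(X \ge k)$ and depletion $P(X \le k)$ for
$X \sim \mathrm{Hypergeom}(N, K, n)$, evaluated by `stats::phyper` (which
works on log scale internally for large $N$). Because no multiple-testing
rule is standard for this 20-cell display, the default flag uses the
two-sided tail (twice the smaller one-sided tail, capped at 1) against a
Bonferroni-corrected family level of $\alpha = 0.05$ over the occupied
cells; `build_summary_grid(correction = "none")` gives raw per-cell
flags.

## The classifier

"Logistic regression" is taken at face value: the default family is
binomial, fitted by iteratively reweighted least squares (tolerance
$10^{-8}$, up to 100 iterations), with a ridge-stabilized IRLS fallback
under complete separation. A gaussian (linear-probability) family is also
provided; because ROC analysis only uses the ranking of scores, the two
families give nearly identical AUCs for monotone feature effects, which is
why both are offered. Features default to the raw continuous `meth_total`
and `cpg_count` (the model formula uses the raw variables); a categorical
representation using the grid category codes is available through the
pipeline configuration.

Folds are stratified by label — at ~5–7% prevalence after the low-basal
filter, unstratified folds can degenerate to single-class test sets — and
are shared across feature sets and sub-bin regions so AUC comparisons are
paired. Per-fold AUC is the trapezoid-rule area of the empirical ROC with
tied scores collapsed to single operating points, which makes it exactly
the pairwise-concordance statistic (ties counted 1/2); the mean ROC curve
is a vertical average over a fixed 101-point false-positive-rate grid with
a standard error per grid point. The headline AUC is the mean of the ten
fold AUCs ("mean across ten runs"); pooling out-of-fold scores instead is
a trivial variation not taken by default. The permutation null permutes
labels only, drawing a fresh permutation and fresh folds per iteration
from a seeded stream.

## What the synthetic generator emulates

The generator (`synthetic_config()` / `generate_dataset()`) reproduces, at
the default scale of 22,824 promoters x 7 strains (159,768 records), the
marginal structure the analysis relies on:

* **Bimodal CpG content**: a two-component log-normal mixture (45%
  CpG-sparse around 25 CpGs, 55% CpG-island around 160 CpGs per window),
  shared across strains for each promoter and split multinomially across
  the six sub-bins by length.
* **Methylation anticorrelated with CpG density**: per-sub-bin beta
  variables whose expectation interpolates logistically (midpoint
  $\log 70$ CpGs, scale 1.0 on log counts) from 0.45 for sparse promoters
  down to 0.15 for islands. The beta concentration (8) and sub-bin jitter
  (SD 0.05) are set so that all 20 grid cells are occupied at full scale —
  in real tumor data even CpG-dense promoters are sometimes heavily
  methylated — giving a pooled Spearman correlation of about $-0.7$.
* **Expression increasing with CpG content** (log-normal, slope 0.55 per
  log CpG) and decreasing with methylation (slope $-0.25$ per
  methylation-sum unit), calibrated so that ~43% of records fall below
  700 array units, matching the "approximately 40%" retained by the
  classifier filter. Replicates carry 15% log-normal noise.
* **A planted response surface**: each record is a responder with
  probability `effect_matrix[meth_category, cpg_category]`. The default
  surface peaks at high methylation / intermediate CpG (0.18) and the
  peak shifts toward CpG-dense promoters as methylation decreases, with
  responses rare (~1–3%) for low-methylation CpG-sparse promoters. Over
  the cells that dominate the low-basal subset the surface is
  logit-linear in the cells' mean continuous features, so the planted
  signal is recoverable by the two-feature linear model; the
  high-methylation/high-CpG decline is confined to cells that the
  low-basal filter largely removes.
* **Responder expression**: post-treatment = basal x fold + delta with
  fold ~ U(2, 4) and delta log-normal (median 8,000 units, log-SD 0.8), so
  planted responders usually — but not always (~85%) — pass the
  two-criterion call: label noise is realistic rather than clean.
  Non-responders receive log-normal fold noise (SD 0.25), which lets a
  small fraction (<1%) cross the call thresholds by chance.

All randomness flows from one seed through named substreams (cpg / meth /
expr / response), so adding strains never perturbs promoter-level draws,
and identical (seed, config) pairs give bit-identical tables. The hidden
truth table (responder flags, drawn folds/deltas, generating cell and
probability) is emitted separately from the observable table.

`planted_bayes_auc()` turns the generative model into a recovery target:
on a fresh Monte-Carlo sample it scores records by their true cell
response probability — the Bayes-optimal score given the grid cell — and
computes the AUC against the same up-regulation labels and low-basal
filter the classifier sees. The trained two-feature model should land
within a few hundredths of this oracle; it can even slightly exceed it,
because the thresholded call labels carry extra basal-expression signal
that the cell probability ignores but correlated continuous features pick
up.

**What the generator does not emulate**: probe-level array structure, dye
bias, MeDIP enrichment chemistry, normalization artifacts, gene-level
correlation along chromosomes, or any pathway structure among responders.
Passing tests on synthetic data therefore demonstrate the correctness and
statistical behavior of the pipeline, not biological conclusions about
any particular dataset.

## Numerical and design choices

* Sequence handling is 0-based half-open; minus-strand windows are
  reverse-complemented before CpG counting so "upstream" always means
  upstream in transcription orientation (this is what makes the
  $-2200/+500$ asymmetry meaningful). A CG dinucleotide straddling a
  sub-bin boundary counts in the sub-bin of its first base.
* Records with missing sub-bin methylation are rejected, not imputed;
  non-positive expression is rejected (fold-change undefined) rather than
  clamped, so upstream normalization problems surface instead of being
  hidden.
* Replicate averaging is the plain arithmetic mean of the two replicates;
  no outlier handling is applied.
* The strain used for single-strain classification defaults to the one
  with the most up-regulated calls (mirroring the choice of the most
  responsive cell strain); any strain id can be forced through
  `pipeline_config(classifier_strain = ...)`.
* External methylation scales are harmonized by matching 90th quantiles
  (`scale_methylation_to_reference()`), then categorized absolutely; a
  degenerate external distribution (90th quantile zero) is an error.
* Sub-bin models default to per-sub-bin CpG counts alongside per-sub-bin
  methylation (falling back to the total count when sub-bin counts are
  absent); the observable synthetic table therefore carries
  `cpg_bin1..cpg_bin6` columns beyond the minimal schema.

## Simulation sizes used by the test suite

The packaged checks run at sizes chosen to make their Monte-Carlo error
small relative to the asserted margins: full default scale (159,768
records) for the binning contract, the classifier recovery check, the
permutation null (100 permutations of the ~9,700-record low-basal subset
of the most responsive strain) and the 30-replicate power check of the
planted enrichment peak; a 3,000 x 2 scale with a uniform 5% response
probability for the 200-replicate type-I check of the enrichment flags.
The type-I design stays at moderate scale deliberately: with very large
cells the enrichment test becomes sensitive to a second-order confound of
the generator itself (threshold-passing probability rises slightly with
basal expression, hence with CpG content, even under a flat response
surface), which is a property of the calling rule, not a failure of the
hypergeometric test.

## Known limitations

* The pipeline treats records across strains as exchangeable when pooling
  (as the grid statistics require) and ignores promoter identity across
  strains everywhere except bookkeeping; there is no random-effect
  structure for repeated measurements of the same promoter.
* The enrichment flags' Bonferroni correction treats the 20 cells as the
  whole family; the signed-rank surface is displayed against the
  conventional $-\log_{10}(0.05)$ reference without correction.
* Expression is modeled in arbitrary "array units" matched in scale to
  the 5,000- and 700-unit thresholds; no absolute physical calibration is
  implied.
* Real-data loaders are deliberately thin adapters over a documented TSV
  schema (`promoter_id`, `strain_id`, `cpg_count`, `meth_bin1..6`,
  replicate expression columns); platform-specific normalization is out
  of scope.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  seed = 1,
  synthetic = synthetic_config(seed = 1, n_promoters = 2000, n_strains = 2),
  n_perm = 20
)
res <- run_pipeline(cfg, "pipeline_out")
res$feature_sets$combined        # cross-validated ROC summary
res$summary_grid                 # 4 x 5 grid with enrichment flags
res$permutation$mean_permuted_auc
```
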