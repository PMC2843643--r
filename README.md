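# demethpred

Promoter CpG content, basal methylation, and the response to
demethylating-agent treatment.

Demethylating drugs such as decitabine (5-aza-2'-deoxycytidine) inhibit
DNA methyltransferase and can re-express genes silenced by promoter
hypermethylation — but most silenced loci do not respond. `demethpred`
implements a complete, tested pipeline for asking *which promoters
respond*, using two pre-treatment covariates computed over the promoter
window from 2,200 bp upstream to 500 bp downstream of the TSS:

* **CpG content**: the count of CG dinucleotides in the 2,700-bp window
  (and per sub-bin: `-2200..-1500`, `-1500..-1000`, `-1000..-500`,
  `-500..-200`, `-200..+100`, `+100..+500`);
* **methylation**: the sum of the six sub-bin relative methylation
  values.

The pipeline stratifies pooled promoters into a 4 (methylation quartile)
× 5 (CpG quintile) grid, labels a record up-regulated when

```
post / pre >= 2   AND   post - pre >= 5,000 array units
```

(the delta criterion removes the low-basal-expression bias of pure
fold-change calling), tests each grid cell with a one-sided Wilcoxon
signed-rank test and hypergeometric enrichment/depletion tails, and
trains a ten-fold cross-validated logistic model

```
upregulated ~ promoter methylation + promoter CpG content
```

on the low-basal subset (basal < 700 units) of the most responsive
strain, with per-sub-bin model sweeps, paired feature-set comparisons
(combined vs methylation-only vs CpG-only), and a label-permutation null
of the cross-validated AUC. A seeded synthetic-data generator with a
plantable (methylation × CpG) response-probability surface makes the
whole pipeline reproducible and testable offline; `planted_bayes_auc()`
computes the generative-model oracle AUC that the trained classifier is
expected to approach.

## Worked example

```r
library(demethpred)

cfg <- synthetic_config(seed = 1)        # 22,824 promoters x 7 strains
ds  <- generate_dataset(cfg)
d   <- ds$data
d$basal      <- (d$basal_rep1 + d$basal_rep2) / 2
d$treated    <- (d$treated_rep1 + d$treated_rep2) / 2
d$meth_total <- aggregate_methylation(d[, paste0("meth_bin", 1:6)])

binned <- assign_bins(d)                 # pooled 4 x 5 quantile grid
calls  <- call_upregulation(binned)
pool_calls(calls)
#> Pooled up-regulation calls: 159768 records, 8667 up-regulated
#> (promoter, strain) pairs, 7277 unique promoters

build_summary_grid(bin_tests(calls))
#> Promoter grid summary (20 cells, 5.42% up-regulated overall)
#> flags at family alpha = 0.05 with bonferroni correction:
#> flag
#> depleted enriched       ns
#>       11        5        4
```

The percent of up-regulated records in the high-methylation row peaks at
intermediate CpG content (10.8, 12.0, **15.0**, 8.2, 3.1% across the five
CpG categories), the planted response pattern.

```r
pooled <- pool_calls(calls)
best <- pooled$per_strain$strain_id[which.max(pooled$per_strain$n_upregulated)]
flt  <- filter_low_basal(calls[calls$strain_id == best, ])  # 9,762 records
fs   <- compare_feature_sets(flt, seed = 10)
fs$combined
#> Cross-validated ROC (10 folds, binomial family): mean AUC = 0.699 (SE 0.011)
#> features: meth_total + cpg_count
```

Methylation-only and CpG-only models reach mean AUCs of 0.701 and 0.614
on the same folds — methylation carries most of the planted signal — and
the per-sub-bin sweep is uniform across the six bins (AUC 0.626–0.635),
all below the full-window model, because the planted effect acts through
the window-level summaries. The permutation null confirms calibration:

```r
perm <- permutation_null(flt[, c("meth_total", "cpg_count")],
                         flt$is_upregulated, n_perm = 100, seed = 11)
perm
#> Label-permutation null: 100 permutations, mean AUC = 0.5004

planted_bayes_auc(cfg, n_mc = 50000)
#> Planted-signal oracle AUC: 0.687 ( 21308 records, label = call )
```

The trained combined model (0.699) sits at the generative oracle (0.687),
i.e. it recovers essentially all of the recoverable planted signal.

An end-to-end run with artifacts, logging and a checksummed manifest:

```r
res <- run_pipeline(pipeline_config(seed = 1), "pipeline_out")
```

or from a shell, `Rscript inst/scripts/run-pipeline.R --seed 1 --out
pipeline_out` (see `--help` for thresholds, family, scale and permutation
options). `harmonize_external_dataset()` maps an external methylation
scale onto the reference distribution by 90th-quantile matching and
cross-tabulates responsive genes by absolute methylation category
(low [0,1] / intermediate (1,6] / high >6).

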