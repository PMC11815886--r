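# pairclass

Rank-based gene-pair features for cross-platform prediction of
transcriptomic cluster labels, with survival stratification of the
predicted groups and a single-cell check of where a pair's signal lives.

## The problem

Molecular subtype labels are usually defined once, on one platform — often
legacy microarray cohorts — while new samples arrive as bulk or single-cell
RNA-seq. Expression values are not comparable across platforms, and
cross-sample normalization destroys exactly the information a portable
model needs. `pairclass` sidesteps the problem with features of the form

> *is gene A expressed below gene B in this sample?*

For an oriented pair (a, b) and sample s the feature is I{x_as < x_bs}.
It depends only on the ordering of two values inside one sample, so it is
exactly invariant to any strictly increasing per-sample transform — which
is what platform changes, within-sample normalizations, and monotone
distortions are. A classifier built on such features can be trained on an
array cohort and applied to RNA-seq counts unchanged.

Pairs are found per cluster C by the **proportion difference**

    PD = P(x_a < x_b | s in C) - P(x_a < x_b | s not in C),

filtered at PD >= 0.5, and ranked by the **gene pair score**
`|PD| * (-Q * R)`, where Q and R are the mean within-sample differences
x_a − x_b inside and outside the cluster: the score is positive exactly
when the ordering genuinely reverses and rewards reversals that are also
large in expression space. A greedy walk selects 10 pairs per cluster
subject to a 0.85 correlation cap between member genes. The classifier is
an ensemble: per cluster, 11 gradient-boosted binary learners on 80%
stratified subsamples, median-aggregated, feeding a final boosted
meta-predictor that emits the **best call**.

The package includes synthetic-cohort generators with planted ground truth
(gene-pair reversals of controlled strength, matched platform-distorted
views, cluster-dependent survival, zero-inflated single-cell counts), so
every claim — selection recovery, no-leakage cross-validation, platform
transfer, round-trip label validation, cross-dataset feature aggregation,
survival separation, single-cell localization — is tested end to end.

## Worked example

```r
library(pairclass)

co <- generate_cohort(seed = 1)       # 140 samples, 5 clusters (14/30/30/33/33),
                                      # 10 planted pair reversals per cluster
lx <- log2(co$expression + 1)         # scoring works on the log scale
ranked <- rank_pairs(lx, co$labels, pd_min = 0.5)
fs <- select_features(ranked, lx, k_per_cluster = 10, labels = co$labels)

# train on an array-like view, predict an RNA-seq-like view of the cohort
arr <- platform_distort(co, "array_like", 1, seed = 101)
rna <- platform_distort(co, "rnaseq_like", 1, seed = 201)
tr <- transfer_predict(arr, co$labels, fs, model_params(seed = 1),
                       rna, co$labels)
tr$report
#> <classification_report> accuracy 0.964 macro F1 0.969
#>     predicted
#> true c1 c2 c3 c4 c5
#>   c1 14  0  0  0  0
#>   c2  0 30  0  0  0
#>   c3  0  0 30  0  0
#>   c4  0  3  0 30  0
#>   c5  0  2  0  0 31

sm <- survival_summary(co$survival, tr$predictions$best_call,
                       protective = co$truth$protective_cluster)
sm$logrank_protective$p_value
#> [1] 0.0005689713
```

The transferred model recovers 96% of the labels across the platform
change — all 14 members of the small protective cluster among them — and
the predicted protective cluster separates in survival (log-rank p =
0.00057 against the rest).

The `analysis/` directory holds the full workflow as numbered drivers —
`01_simulate.R` (cohort + platform views + single-cell data),
`02_select_features.R`, `03_cross_validation.R` (with a pure-noise
negative control), `04_platform_transfer.R` (transfer, round trip,
cross-platform refinement), `05_survival.R`, `06_single_cell.R` — each
writing its tables under `results/`. File formats (genes-in-rows TSV for
expression, `sample_id`/`cluster` labels, `sample_id`/`time`/`event`
survival, `cluster`/`gene_a`/`gene_b` pair lists, matrix-market triples
with cells in rows for single cell) are documented in the reader/writer
help pages.

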