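---
title: "Rank-based gene-pair features for cross-platform cluster prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based gene-pair features for cross-platform cluster prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Transcriptomic subtype labels defined on one platform (say, expression
microarrays) are hard to carry to another (bulk RNA-seq, single cell)
because each platform measures expression on its own scale, with its own
noise floor, saturation, and normalization. Cross-sample normalization does
not help -- it rescales each gene by factors derived from the cohort at
hand, so a model trained on one cohort's normalized values does not apply
to another's.

`pairclass` builds classifiers from *within-sample comparisons*: the binary
feature for an oriented gene pair $(a, b)$ in sample $s$ is
$I\{x_{a,s} < x_{b,s}\}$. A comparison of two values inside one sample is
unchanged by any strictly increasing transform of that sample's values, so
the feature -- and everything downstream of it -- is exactly invariant to
per-sample monotone distortions. That is the formal version of "the data
become within-sample normalized", and it is the entire reason models
transfer across platforms. Ties count as *not less than*: on count data
this makes the indicator deterministic and keeps orientation-swapping exact
up to ties.

### Scoring a pair for a cluster

For a target cluster $C$ over the labeled samples, with $s \in C$ and
$t \notin C$:

* $p_{in} = P_{s \in C}(x_a < x_b)$, $p_{out} = P_{t \notin C}(x_a < x_b)$,
  and the **proportion difference** $PD = p_{in} - p_{out} \in [-1, 1]$ —
  a cluster-purity measure of the pair's ordering reversal;
* $Q$ and $R$, the mean of $x_a - x_b$ inside and outside the cluster —
  effect-size terms: a reversal that is also large in expression space is
  more likely to survive platform noise;
* the **gene pair score** $|PD| \cdot (-Q \cdot R)$, positive exactly when
  $Q$ and $R$ have opposite signs (the ordering truly reverses) and
  $PD \neq 0$;
* the **updated score** $|PD| \cdot |PD_{val}| \cdot (-Q \cdot R)$, which
  folds in the proportion difference of the same pair recomputed on a second
  dataset. When the two PDs disagree in sign the pair is not transferable
  and the updated score is defined as 0 — scoring discordant pairs by
  magnitude alone would up-rank exactly the features one is trying to
  remove.

Ranking enumerates each unordered pair once, orients it so that $PD \ge 0$
in the target cluster (the larger PD wins when ties make both orientations
non-negative), drops pairs with $PD$ below `pd_min` (default 0.5), and
sorts by score with ties broken by $|PD|$ and then gene names, so output is
deterministic.

Selection walks the ranking greedily and accepts a pair only if neither
member gene has absolute Pearson correlation above `corr_max` (default
0.85) with any already-selected gene of that cluster; since a gene is
perfectly correlated with itself, pairs reusing a selected gene are
rejected automatically. Ten pairs per cluster is the default budget.

### The working scale

$PD$, $p_{in}$, $p_{out}$, and all pair indicators are scale-free. $Q$, $R$
and the selection correlations are not; `rank_pairs()` and
`select_features()` compute them on whatever matrix they are given. The
package convention, applied by the analysis drivers and by `cross_validate()`
and `aggregate_features()` (`log_scale` option, on by default), is
$\log_2(x + 1)$ expression: expression effect sizes and gene-gene
correlations are conventionally assessed on the log scale, magnitudes are
then stable across the dynamic range, and heavy-tailed linear-scale values
do not dominate means or Pearson correlations.

### The classifier

Pairs selected for all clusters are pooled and binarized. Each cluster gets
a one-vs-rest stack of `ensemble_size` gradient-boosted binary learners
(defaults: 11 learners, tree depth 12, learning rate 0.3, 50 rounds, L2
regularization 1), each trained on an independent random 80% subsample.
Subsampling is stratified with at least one positive guaranteed: with a
14-sample cluster, plain 80% sampling would occasionally lose every
positive. The per-cluster score of a sample is the *median* of its stack's
probabilities; a final multi-class boosted learner over the per-cluster
median scores emits the best call, with ties broken by the highest median
score and then label order. Every learner's seed derives from the single
`seed` in `model_params()` through a fixed schedule, so training and
prediction are reproducible, and single-threaded boosting keeps them
bit-stable.

Cross-validation is stratified by cluster and refuses more folds than the
smallest cluster. When a feature-selection config is passed, ranking and
selection are re-run inside every training fold; on pure-noise data this
yields chance-level accuracy, which is the operational guard against the
classic leakage of selecting features on the full dataset before
cross-validating them.

`grid_search()` evaluates a parameter grid exhaustively by cross-validated
macro F1 and breaks ties toward shallower trees, then fewer rounds, then
grid order. Feature importance reports, per cluster, the median across the
stack of each feature's total split gain, in the boosting library's native
gain units.

## What the synthetic cohorts emulate

`generate_cohort()` plants ground truth into a log-normal expression model:

* cluster sizes default to 14/30/30/33/33 over 140 samples — a strongly
  unbalanced cohort whose smallest cluster is the protective one;
* each cluster owns `pairs_per_cluster` disjoint gene pairs; on the log
  scale the two genes sit at `base ± effect_size * noise_sd / 2`, with the
  sign flipped between in- and out-of-cluster samples (direction
  randomized per pair). `effect_size` is expressed in noise-sd units so
  separation strength is independent of the measurement scale;
  `noise_sd = 0.25` models ~25% multiplicative measurement noise;
* the two genes of a pair share a per-sample *co-expression module* factor
  (log-scale sd `pair_module_sd`, default 12 noise-sds). This emulates what
  real informative pairs look like: each member gene varies enormously
  across samples and platforms while the within-pair ordering stays put.
  It is also what makes the planted pairing identifiable to selection — without
  it, any "low-in-cluster" gene paired with any "high-in-cluster" gene of
  the same cluster forms an equally perfect feature, and no scoring rule
  could prefer the planted matching. The module level is centered within
  each cluster so that module activity itself carries no cluster signal;
  otherwise, with 14-sample clusters, chance module/cluster alignment
  blurs the ground truth;
* survival is exponential per cluster (default baseline hazard 1/365 per
  day; hazard ratio 0.35 for the protective cluster) with independent
  uniform censoring on [0, 5 years]. The generative survival model is a
  package choice — the method consumes only (time, event) pairs;
* `platform_distort()` applies an independent strictly increasing transform
  per sample (random scale and power), which alone leaves every pair
  indicator untouched; on top of that, `array_like` compresses and
  perturbs the bottom 20% of each sample (a noise floor) and softly
  saturates the top 5%, while `rnaseq_like` redraws each value from a
  negative-binomial count model (library scaled so a median gene sits near
  100 counts; dispersion grows with `distort_strength`);
* `generate_single_cell()` draws zero-inflated Poisson counts in which the
  planted pair's median ordering flips between the two condition groups
  only in the pattern cell type, with broadly expressed distractor genes
  across the other cell types.

What the generator does **not** emulate: probe-level physics, GC and gene
length bias, batch structure, correlated censoring, doublets or ambient
RNA. Passing the synthetic suite therefore demonstrates the method's
internal consistency and its monotone-transform invariance, not performance
on any real cohort.

## Numerical and design choices

* Ties in the pair indicator count as "not less" (exactness on counts).
* Canonical pair orientation is the direction with $PD \ge 0$ in the
  target cluster; aggregation across datasets identifies pairs up to
  orientation.
* The updated score zeroes sign-discordant cross-dataset PDs.
* Within-platform gene-gene correlation uses Pearson (on the log scale by
  convention); cross-platform refinement uses Spearman over matched
  samples, robust to the platform's monotone distortion. Both are
  configurable.
* Missing feature genes error by default; the "drop" policy removes
  affected pairs but refuses when more than 25% of any cluster's pairs
  would vanish.
* Degenerate inputs are errors, not silent repairs: NA expression cells,
  duplicate sample ids, clusters with fewer than 2 samples, log-rank with
  a single group or zero events.
* The log-rank p-value uses the chi-square approximation, matching
  standard survival practice; the Kaplan-Meier estimator and both tests
  are computed via the `survival` package behind the module's interface.
* The single-cell "pattern" is operationalized as a median-ordering
  reversal with a percent-expressing support floor (default 10%), turning
  a visual dotplot judgment into a testable criterion; raw counts are the
  default scale since the comparison is between two genes over the same
  cells.

### Problem sizes used in the test suite

The packaged tests run the full design at the default cohort shape (140
samples, 500 genes, 10 pairs per cluster) for selection recovery,
cross-validation, transfer, round-trip, and aggregation (5 planted pairs
per cluster there, matching the ~5-per-cluster aggregated sets the method
produces), with 5 seeds for stochastic checks, 500 null replicates for
log-rank calibration, and 100 for power. Smaller 60-sample cohorts back
the fast unit tests. These sizes are the package's chosen balance between
statistical resolution and a test suite that runs in minutes.

## Known limitations

* Full pair enumeration is $O(G^2 \cdot n)$; beyond a few thousand genes a
  candidate-gene pre-filter (`candidate_genes`) is advisable.
* Q and R — hence scores — depend on the working scale; only PD and the
  indicators are transform-invariant.
* The greedy correlation-capped selection is order-dependent by design
  (it mirrors the stepping-down procedure it implements); it does not
  globally optimize the feature set.
* Chance-level behavior of the no-leakage guard is asserted at the
  cohort shapes above; very small clusters with very many genes can still
  produce optimistic folds by chance.
* The boosted learners' gain units are the library's own; gains are
  comparable within a model, not across libraries or encodings.
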