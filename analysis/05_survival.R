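#!/usr/bin/env Rscript
# Survival stratification of predicted cluster labels: Kaplan-Meier curves
# per predicted cluster on the transferred RNA-seq-like view, the all-groups
# log-rank test, and the protective-cluster-vs-rest test.

suppressMessages(library(pairclass))
dir.create("results", showWarnings = FALSE)

labels <- read_labels("results/cohort/labels.tsv")
surv <- read_survival("results/cohort/survival.tsv")
arr <- read_expression("results/cohort/expression_array_view.tsv")
rna <- read_expression("results/cohort/expression_rnaseq_view.tsv")
fs <- read_pairs("results/selected_pairs.tsv")
seed <- 20260930L

tr <- transfer_predict(arr, labels, fs, model_params(seed = seed), rna)
co <- generate_cohort(seed = seed)
sm <- survival_summary(surv, tr$predictions$best_call,
                       protective = co$truth$protective_cluster)
print(sm)

medians <- data.frame(cluster = names(sm$medians),
                      median_survival_days = unname(sm$medians))
utils::write.table(medians, "results/survival_medians.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
tests <- data.frame(
  test = c("all_groups", "protective_vs_rest"),
  statistic = c(sm$logrank_all$statistic,
                sm$logrank_protective$statistic),
  df = c(sm$logrank_all$df, sm$logrank_protective$df),
  p_value = c(sm$logrank_all$p_value, sm$logrank_protective$p_value))
utils::write.table(tests, "results/survival_logrank.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
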