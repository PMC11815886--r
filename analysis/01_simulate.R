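#!/usr/bin/env Rscript
# Simulate the study cohort: 140 samples in five clusters (14/30/30/33/33,
# the protective cluster smallest), 500 genes with 10 planted gene-pair
# reversals per cluster at effect size 4, cluster-dependent survival, and
# two additional platform views (array-like, RNA-seq-like counts) of the
# same cohort. Writes all tables in the package's TSV/MTX formats.

suppressMessages(library(pairclass))
dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)

seed <- 20260930L
co <- generate_cohort(seed = seed)

write_expression(co$expression, "results/cohort/expression.tsv")
write_labels(co$labels, "results/cohort/labels.tsv")
write_survival(co$survival, "results/cohort/survival.tsv")
write_pairs(feature_set(co$truth$planted_pairs[, c("cluster", "gene_a",
                                                   "gene_b")],
                        list(role = "planted truth", seed = seed)),
            "results/cohort/planted_pairs.tsv")

arr <- platform_distort(co, "array_like", distort_strength = 1,
                        seed = seed + 1L)
rna <- platform_distort(co, "rnaseq_like", distort_strength = 1,
                        seed = seed + 2L)
write_expression(arr, "results/cohort/expression_array_view.tsv")
write_expression(rna, "results/cohort/expression_rnaseq_view.tsv")

sc <- generate_single_cell(
  c(tumor = 400, immune = 400, stromal = 300, oligodendrocyte = 300),
  pattern_cell_type = "tumor", seed = seed)
write_single_cell(sc, "results/cohort/sc_counts.mtx",
                  "results/cohort/sc_genes.txt",
                  "results/cohort/sc_meta.tsv")

cat("cohort:", ncol(co$expression), "samples,",
    nrow(co$expression), "genes; protective cluster",
    co$truth$protective_cluster, "\n")
cat("single cell:", nrow(sc$counts), "cells x", ncol(sc$counts), "genes\n")
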