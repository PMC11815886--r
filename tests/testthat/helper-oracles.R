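# Shared fixtures and independent oracles used across the test files.

# naive double-loop oracle for pair statistics: loops over samples and pairs,
# no vectorization, kept deliberately independent of the package internals
oracle_pair_stats <- function(expr, labels, cluster, gene_a, gene_b) {
  samples <- intersect(colnames(expr), names(labels$assignments))
  n_in <- 0; n_out <- 0; c_in <- 0; c_out <- 0
  q_sum <- 0; r_sum <- 0
  for (s in samples) {
    va <- expr[gene_a, s]; vb <- expr[gene_b, s]
    if (labels$assignments[[s]] == cluster) {
      n_in <- n_in + 1
      if (va < vb) c_in <- c_in + 1
      q_sum <- q_sum + (va - vb)
    } else {
      n_out <- n_out + 1
      if (va < vb) c_out <- c_out + 1
      r_sum <- r_sum + (va - vb)
    }
  }
  list(p_in = c_in / n_in, p_out = c_out / n_out,
       pd = c_in / n_in - c_out / n_out,
       q = q_sum / n_in, r = r_sum / n_out)
}

# brute-force log-rank statistic for two groups: walk event times, accumulate
# observed minus expected and the hypergeometric variance
oracle_logrank_2g <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# orientation-free identity for comparing selected vs planted pairs
pair_id <- function(cluster, a, b) paste(cluster, pmin(a, b), pmax(a, b))

planted_ids <- function(cohort) {
  tp <- cohort$truth$planted_pairs
  pair_id(tp$cluster, tp$gene_a, tp$gene_b)
}

selected_ids <- function(fs) {
  pair_id(fs$pairs$cluster, fs$pairs$gene_a, fs$pairs$gene_b)
}

# random labeled expression matrix for oracle-equivalence checks
random_cohort_matrix <- function(n_genes = 15, n_samples = 30, k = 3,
                                 seed = 1) {
  set.seed(seed)
  x <- matrix(exp(rnorm(n_genes * n_samples)), n_genes,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              sprintf("s%02d", 1:n_samples)))
  lab <- cluster_labels(setNames(
    sample(paste0("c", 1:k), n_samples, replace = TRUE,
           prob = rep(1, k)), colnames(x)))
  # ensure every cluster has at least 2 members
  while (min(table(lab$assignments)) < 2) {
    lab <- cluster_labels(setNames(
      sample(paste0("c", 1:k), n_samples, replace = TRUE), colnames(x)))
  }
  list(expr = x, labels = lab)
}

# strictly increasing per-sample transform drawn at random
random_monotone <- function(expr, seed) {
  set.seed(seed)
  out <- expr
  for (s in seq_len(ncol(expr))) {
    a <- exp(rnorm(1, 0, 0.5))
    g <- runif(1, 0.5, 2)
    b <- runif(1, 0, 2)
    out[, s] <- a * expr[, s]^g + b * log1p(expr[, s])
  }
  out
}

# small cohort for ensemble tests (fast to train on)
small_cohort <- function(seed = 1, effect_size = 4) {
  generate_cohort(n_samples = 60,
                  cluster_sizes = c(c1 = 10, c2 = 24, c3 = 26),
                  n_genes = 60, pairs_per_cluster = 3,
                  effect_size = effect_size, seed = seed)
}

fast_params <- function(seed = 1) {
  model_params(ensemble_size = 3, nrounds = 20, seed = seed)
}

select_from_cohort <- function(cohort, k_per_cluster = 10, pd_min = 0.5) {
  lx <- log2(cohort$expression + 1)
  rk <- rank_pairs(lx, cohort$labels, pd_min = pd_min)
  suppressWarnings(select_features(rk, lx, k_per_cluster = k_per_cluster,
                                   labels = cohort$labels))
}
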