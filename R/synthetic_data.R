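# Synthetic cohort generators with planted ground truth.
#
# The generative model is deliberately simple: gene expression is log-normal
# with gene-specific baselines, planted gene-pair reversals are parameterized
# in noise-sd units on the log scale, survival is exponential per cluster with
# independent uniform censoring. The method's core claim is invariance to
# within-sample monotone transforms, so platform views are built from random
# strictly increasing per-sample transforms plus platform-flavored noise.

#' Generate a synthetic cohort with planted gene-pair reversals
#'
#' Produces an expression matrix, cluster labels, survival outcomes and the
#' planted truth. For each cluster, `pairs_per_cluster` disjoint gene pairs
#' (A, B) are planted so that on the log scale
#' `mean(A) - mean(B) = +effect_size * noise_sd` inside the cluster and
#' `-effect_size * noise_sd` outside (sign flipped for direction
#' `"in_cluster_a_greater_b"`). Independent Gaussian noise with sd `noise_sd`
#' is added on the log scale and the result exponentiated, so all values are
#' positive. Remaining genes are uninformative log-normal background.
#'
#' The two genes of a planted pair additionally share a per-sample
#' co-expression factor (log-scale sd `pair_module_sd`), emulating
#' co-regulated gene modules: each gene's absolute level varies strongly
#' from sample to sample, while the within-pair ordering -- the signal the
#' method rides on -- stays stable. This mirrors real informative pairs,
#' whose member genes look noisy across samples and platforms even though
#' their comparison is consistent, and it is what makes the planted pairing
#' identifiable: a "cross pair" built from genes of two different planted
#' modules picks up both modules' independent fluctuations, so its
#' proportion difference stays low. The module level is centered within each
#' cluster, so module activity itself carries no cluster signal beyond the
#' planted reversal.
#'
#' Survival times are exponential with a per-cluster hazard: the protective
#' cluster (by default the smallest, mirroring a small protective subgroup in
#' an unbalanced cohort) gets `hazard * protective_hr`, all others `hazard`.
#' Censoring is independent uniform on `[0, censor_horizon]`; `event = 0`
#' when censored.
#'
#' @param n_samples total samples; must equal `sum(cluster_sizes)`.
#' @param cluster_sizes named integer vector of per-cluster sizes. Default
#'   mirrors a 140-sample cohort with a 14-sample protective cluster.
#' @param n_genes total genes (planted pair genes plus background).
#' @param pairs_per_cluster planted pairs per cluster.
#' @param effect_size planted log-scale separation in units of `noise_sd`;
#'   `0` yields a pure-noise cohort (no reversal), negative values error.
#' @param noise_sd log-scale Gaussian measurement noise sd (> 0).
#' @param pair_module_sd log-scale sd of the per-sample co-expression factor
#'   shared by the two genes of a planted pair.
#' @param seed integer seed; the cohort is a deterministic function of it.
#' @param hazard baseline hazard (1/days) for non-protective clusters.
#' @param protective_hr hazard ratio (< 1) of the protective cluster.
#' @param protective_cluster label of the protective cluster; default the
#'   smallest cluster.
#' @param censor_horizon upper bound (days) of the uniform censoring time.
#' @return object of class `synthetic_cohort`: list with `expression`
#'   (matrix), `labels` ([cluster_labels()]), `survival` (data.frame),
#'   `truth` (list: `planted_pairs` data.frame with cluster/gene_a/gene_b/
#'   direction/effect_size, `hazards`, `protective_cluster`), `seed`.
#' @export
generate_cohort <- function(n_samples = 140,
                            cluster_sizes = c(c1 = 14, c2 = 30, c3 = 30,
                                              c4 = 33, c5 = 33),
                            n_genes = 500,
                            pairs_per_cluster = 10,
                            effect_size = 4,
                            noise_sd = 0.25,
                            pair_module_sd = 12 * noise_sd,
                            seed = 1,
                            hazard = 1 / 365,
                            protective_hr = 0.35,
                            protective_cluster = NULL,
                            censor_horizon = 1825) {
  if (is.null(names(cluster_sizes)) || anyDuplicated(names(cluster_sizes)))
    stop("cluster_sizes must be uniquely named")
  if (sum(cluster_sizes) != n_samples)
    stop("sum(cluster_sizes) must equal n_samples")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  k <- length(cluster_sizes)
  if (n_genes < 2 * pairs_per_cluster * k + 2)
    stop("n_genes too small for the requested planted pairs")
  protective_cluster <- protective_cluster %||%
    names(cluster_sizes)[which.min(cluster_sizes)]
  if (!protective_cluster %in% names(cluster_sizes))
    stop("protective_cluster not in cluster_sizes")

  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- sprintf("s%04d", seq_len(n_samples))
  lab <- rep(names(cluster_sizes), cluster_sizes)
  # shuffle sample order so cluster blocks are not contiguous
  ord <- sample.int(n_samples)
  lab <- lab[ord]
  labels <- cluster_labels(stats::setNames(lab, samples),
                           label_set = names(cluster_sizes))

  # plant disjoint pairs: each gene belongs to at most one pair globally
  n_pairs <- pairs_per_cluster * k
  pair_genes <- sample(genes, 2L * n_pairs)
  planted <- data.frame(
    cluster = rep(names(cluster_sizes), each = pairs_per_cluster),
    gene_a = pair_genes[seq(1, 2 * n_pairs, by = 2)],
    gene_b = pair_genes[seq(2, 2 * n_pairs, by = 2)],
    direction = sample(c("in_cluster_a_less_b", "in_cluster_a_greater_b"),
                       n_pairs, replace = TRUE),
    effect_size = effect_size,
    stringsAsFactors = FALSE
  )

  mu <- matrix(rep(stats::rnorm(n_genes, mean = 2, sd = 0.75), n_samples),
               nrow = n_genes, dimnames = list(genes, samples))
  delta <- effect_size * noise_sd / 2
  for (i in seq_len(n_pairs)) {
    pr <- planted[i, ]
    inc <- lab == pr$cluster
    s <- if (pr$direction == "in_cluster_a_less_b") -1 else 1
    base <- stats::rnorm(1, mean = 2, sd = 0.75)
    # shared by A and B; centered within every cluster so module activity
    # carries no cluster information beyond the planted reversal (otherwise
    # finite-sample module/cluster alignment blurs the planted ground truth)
    module <- stats::rnorm(n_samples, 0, pair_module_sd)
    module <- module - stats::ave(module, lab)
    mu[pr$gene_a, ] <- base + module + ifelse(inc, s * delta, -s * delta)
    mu[pr$gene_b, ] <- base + module - ifelse(inc, s * delta, -s * delta)
  }
  expr <- exp(mu + matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                          nrow = n_genes))
  dimnames(expr) <- list(genes, samples)

  hazards <- stats::setNames(rep(hazard, k), names(cluster_sizes))
  hazards[protective_cluster] <- hazard * protective_hr
  death <- stats::rexp(n_samples, rate = hazards[lab])
  cens <- stats::runif(n_samples, 0, censor_horizon)
  surv <- data.frame(sample_id = samples,
                     time = pmin(death, cens),
                     event = as.integer(death <= cens),
                     group = lab,
                     stringsAsFactors = FALSE)

  structure(list(
    expression = expr,
    labels = labels,
    survival = surv,
    truth = list(planted_pairs = planted, hazards = hazards,
                 protective_cluster = protective_cluster),
    seed = seed
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$expression), "genes x",
      ncol(x$expression), "samples,",
      length(x$labels$label_set), "clusters, protective =",
      x$truth$protective_cluster, "\n")
  invisible(x)
}

#' Plant a gene-pair reversal into an existing expression matrix
#'
#' Overwrites the two genes' rows with a freshly drawn planted-pair pattern
#' (same model as [generate_cohort()]): useful for injecting dataset-specific
#' signal pairs when emulating multi-cohort feature aggregation.
#'
#' @param expr expression matrix (positive values).
#' @param labels [cluster_labels()] covering the matrix's samples.
#' @param cluster target cluster label.
#' @param gene_a,gene_b genes to overwrite (must exist in `expr`).
#' @param effect_size,noise_sd as in [generate_cohort()].
#' @param seed integer seed.
#' @return modified expression matrix.
#' @export
inject_pair_reversal <- function(expr, labels, cluster, gene_a, gene_b,
                                 effect_size = 4, noise_sd = 0.25,
                                 pair_module_sd = 12 * noise_sd, seed = 1) {
  stopifnot(gene_a %in% rownames(expr), gene_b %in% rownames(expr),
            cluster %in% labels$label_set)
  set.seed(seed)
  lab <- labels$assignments[colnames(expr)]
  inc <- !is.na(lab) & lab == cluster
  delta <- effect_size * noise_sd / 2
  base <- stats::rnorm(1, 2, 0.75)
  n <- ncol(expr)
  grp <- ifelse(inc, "in", "out")
  module <- stats::rnorm(n, 0, pair_module_sd)
  module <- module - stats::ave(module, grp)
  expr[gene_a, ] <- exp(base + module + ifelse(inc, -delta, delta) +
                          stats::rnorm(n, sd = noise_sd))
  expr[gene_b, ] <- exp(base + module + ifelse(inc, delta, -delta) +
                          stats::rnorm(n, sd = noise_sd))
  expr
}

#' Distort a cohort into a second platform view
#'
#' Applies an independent strictly increasing transform to every sample
#' (random positive scale `a_s` and power `gamma_s`: `y = a_s * x^gamma_s`),
#' which preserves within-sample rank order exactly. With
#' `distort_strength = 0` that is all that happens, for either mode, so every
#' pair indicator is unchanged. With positive strength:
#' * `array_like` adds a noise floor (values below the 20% within-sample
#'   quantile are compressed toward the floor and perturbed) and soft
#'   saturation above the 95% quantile -- mimicking microarray background
#'   noise and signal saturation;
#' * `rnaseq_like` resamples each value through a negative-binomial count
#'   model with mean proportional to the transformed value (library scaled so
#'   a median-expression gene gets ~100 counts) and dispersion growing with
#'   strength, returning integer counts.
#'
#' @param cohort a `synthetic_cohort` or an expression matrix (non-negative;
#'   zeros pass through as zeros).
#' @param mode `"array_like"` or `"rnaseq_like"`.
#' @param distort_strength non-negative noise strength.
#' @param seed integer seed.
#' @return expression matrix (genes x samples), same dimnames.
#' @export
platform_distort <- function(cohort, mode = c("array_like", "rnaseq_like"),
                             distort_strength = 1, seed = 1) {
  mode <- match.arg(mode)
  X <- if (inherits(cohort, "synthetic_cohort")) cohort$expression else cohort
  if (!is.matrix(X) || !is.numeric(X)) stop("need an expression matrix")
  if (any(X < 0)) stop("expression must be non-negative")
  if (distort_strength < 0) stop("distort_strength must be >= 0")
  set.seed(seed)
  n <- ncol(X)
  a <- exp(stats::rnorm(n, 0, 0.3))
  gam <- stats::runif(n, 0.7, 1.4)
  Y <- sweep(sweep(X, 2, gam, `^`), 2, a, `*`)
  if (distort_strength > 0) {
    if (mode == "array_like") {
      for (s in seq_len(n)) {
        v <- Y[, s]
        lo <- stats::quantile(v, 0.2)
        hi <- stats::quantile(v, 0.95)
        low <- v < lo
        if (any(low)) {
          v[low] <- lo + (v[low] - lo) / (1 + distort_strength) +
            stats::rnorm(sum(low), 0, 0.3 * distort_strength * max(lo, 1e-8))
        }
        high <- v > hi
        v[high] <- hi + (v[high] - hi) / (1 + 2 * distort_strength)
        Y[, s] <- pmax(v, 0)
      }
    } else {
      # library scaled so a median-expression gene lands near 100 counts;
      # dispersion models platform/technical noise (biological variation is
      # already in the generator)
      sf <- 100 / pmax(apply(Y, 2, stats::median), 1e-12)
      mu <- sweep(Y, 2, sf, `*`)
      size <- 10 / distort_strength
      Y[] <- stats::rnbinom(length(mu), mu = mu, size = size)
    }
  }
  dimnames(Y) <- dimnames(X)
  Y
}

#' Generate a synthetic single-cell dataset with a cell-type-specific reversal
#'
#' Counts follow a zero-inflated Poisson model. The planted pair's
#' median-expression ordering is opposite between the two condition groups
#' only inside `pattern_cell_type`; in every other cell type the ordering is
#' identical across conditions. Distractor genes are broadly expressed across
#' the non-pattern cell types (emulating markers shared across, e.g., immune
#' populations) so the pattern check has something to reject.
#'
#' @param n_cells_per_type named integer vector, cells per cell type (types
#'   with 0 cells are absent from the output metadata).
#' @param conditions length-2 character vector of condition labels
#'   (default `c("mutant", "wildtype")`, as for a binary tumor genotype).
#' @param planted_pair length-2 character vector `(gene_a, gene_b)`.
#' @param pattern_cell_type the single cell type carrying the reversal.
#' @param seed integer seed.
#' @param n_distractors number of broadly expressed distractor genes.
#' @param dropout zero-inflation probability.
#' @param high_mean,low_mean Poisson means for the high/low member of the pair.
#' @return [single_cell_dataset()] with `cell_meta` columns `cell_id`,
#'   `cell_type`, `condition`, `donor`.
#' @export
generate_single_cell <- function(n_cells_per_type,
                                 conditions = c("mutant", "wildtype"),
                                 planted_pair = c("GENEA", "GENEB"),
                                 pattern_cell_type,
                                 seed = 1,
                                 n_distractors = 8,
                                 dropout = 0.3,
                                 high_mean = 10,
                                 low_mean = 0.2) {
  if (is.null(names(n_cells_per_type)))
    stop("n_cells_per_type must be named by cell type")
  if (length(conditions) != 2) stop("need exactly 2 condition labels")
  n_cells_per_type <- n_cells_per_type[n_cells_per_type > 0]
  if (!pattern_cell_type %in% names(n_cells_per_type))
    stop("unknown pattern_cell_type: ", pattern_cell_type)
  set.seed(seed)

  types <- rep(names(n_cells_per_type), n_cells_per_type)
  n <- length(types)
  # split each type evenly across the two conditions
  cond <- unlist(lapply(n_cells_per_type, function(m)
    rep(conditions, length.out = m)), use.names = FALSE)
  genes <- c(planted_pair, sprintf("DIST%02d", seq_len(n_distractors)))
  mu <- matrix(0.05, nrow = n, ncol = length(genes),
               dimnames = list(NULL, genes))

  pat <- types == pattern_cell_type
  ga <- planted_pair[1]; gb <- planted_pair[2]
  in_a <- cond == conditions[1]
  # pattern cell type: ordering flips between conditions
  mu[pat & in_a, ga] <- high_mean; mu[pat & in_a, gb] <- low_mean
  mu[pat & !in_a, ga] <- low_mean; mu[pat & !in_a, gb] <- high_mean
  # other cell types: same ordering in both conditions
  mu[!pat, ga] <- high_mean / 2
  mu[!pat, gb] <- low_mean
  # distractors: broadly expressed across non-pattern types, condition-blind
  for (d in seq_len(n_distractors)) {
    g <- genes[2 + d]
    on_types <- sample(setdiff(names(n_cells_per_type), pattern_cell_type),
                       size = max(1, ceiling((length(n_cells_per_type) - 1) / 2)))
    mu[types %in% on_types, g] <- stats::runif(1, 2, 6)
  }

  counts <- matrix(stats::rpois(n * length(genes), lambda = mu) *
                     stats::rbinom(n * length(genes), 1, 1 - dropout),
                   nrow = n)
  meta <- data.frame(cell_id = sprintf("cell%05d", seq_len(n)),
                     cell_type = types,
                     condition = cond,
                     donor = sprintf("d%02d", 1 + (seq_len(n) %% 4)),
                     stringsAsFactors = FALSE)
  single_cell_dataset(Matrix::Matrix(counts, sparse = TRUE), genes, meta)
}
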