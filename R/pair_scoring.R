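# Gene-pair statistics, ranking, and feature selection.
#
# For an oriented pair (a, b) and a target cluster C over labeled samples S:
#   p_in  = fraction of in-cluster samples with value(a) <  value(b)
#   p_out = the same fraction among out-of-cluster samples
#   PD    = p_in - p_out                               (proportion difference)
#   Q     = mean(value(a) - value(b)) over in-cluster samples
#   R     = mean(value(a) - value(b)) over out-of-cluster samples
#   score = |PD| * (-1 * Q * R)                        (gene pair score)
# Ties (value(a) == value(b)) count as NOT satisfying the strict inequality;
# this makes the indicator deterministic on count data. Q and R are computed
# on the input matrix's scale as given.

#' Proportion difference and pair statistics for one oriented gene pair
#'
#' @param expr expression matrix (genes x samples).
#' @param labels [cluster_labels()]; only labeled samples participate.
#' @param cluster target cluster label.
#' @param pair length-2 character vector `(gene_a, gene_b)`; orientation is
#'   significant (the indicator is `value(gene_a) < value(gene_b)`).
#' @return object of class `pair_stats`: list with `gene_a`, `gene_b`,
#'   `cluster`, `p_in`, `p_out`, `pd`, `q`, `r`, and `score` (NA until
#'   [pair_score()] is applied).
#' @export
proportion_difference <- function(expr, labels, cluster, pair) {
  stopifnot(length(pair) == 2)
  miss <- setdiff(pair, rownames(expr))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  samples <- intersect(colnames(expr), names(labels$assignments))
  lab <- labels$assignments[samples]
  inc <- lab == cluster
  if (!any(inc) || all(inc))
    stop("cluster '", cluster, "' needs >= 1 sample in and >= 1 sample out")
  va <- expr[pair[1], samples]
  vb <- expr[pair[2], samples]
  less <- va < vb
  diff <- va - vb
  structure(list(
    gene_a = pair[1], gene_b = pair[2], cluster = cluster,
    p_in = mean(less[inc]), p_out = mean(less[!inc]),
    pd = mean(less[inc]) - mean(less[!inc]),
    q = mean(diff[inc]), r = mean(diff[!inc]),
    score = NA_real_
  ), class = "pair_stats")
}

#' Gene pair score: `|PD| * (-1 * Q * R)`
#'
#' Positive exactly when the mean difference reverses sign between the
#' in-cluster and out-of-cluster groups (Q and R of opposite signs) and the
#' proportion difference is non-zero.
#'
#' @param stats a `pair_stats` object with `pd`, `q`, `r` filled.
#' @return the score (numeric scalar).
#' @export
pair_score <- function(stats) {
  abs(stats$pd) * (-1 * stats$q * stats$r)
}

#' Updated gene pair score using a second dataset's proportion difference
#'
#' `|PD| * |PD_val| * (-1 * Q * R)` where `PD_val` is the proportion
#' difference of the same oriented pair computed on a second (validation)
#' dataset. When the two PDs have discordant signs the pair is not
#' transferable across datasets and the score is 0 rather than a product of
#' magnitudes.
#'
#' @param stats a `pair_stats` object.
#' @param pd_val proportion difference from the second dataset, in `[-1, 1]`.
#' @return the updated score (numeric scalar).
#' @export
updated_pair_score <- function(stats, pd_val) {
  if (!is.finite(pd_val) || pd_val < -1 || pd_val > 1)
    stop("pd_val must lie in [-1, 1]")
  if (pd_val != 0 && stats$pd != 0 && sign(pd_val) != sign(stats$pd))
    return(0)
  abs(stats$pd) * abs(pd_val) * (-1 * stats$q * stats$r)
}

#' Rank all gene pairs per cluster by the gene pair score
#'
#' Enumerates every unordered pair of candidate genes once, chooses the
#' canonical orientation as the direction giving `PD >= 0` within the target
#' cluster (the larger PD when ties make both orientations non-negative),
#' drops pairs with `PD < pd_min`, and sorts survivors by score descending
#' with ties broken by `|PD|` descending then lexicographic gene names.
#'
#' @param expr expression matrix.
#' @param labels [cluster_labels()].
#' @param pd_min minimum proportion difference to keep a pair (default 0.5).
#' @param candidate_genes optional gene subset (default: all genes).
#' @return named list (one element per cluster with both in- and out-group
#'   samples) of data.frames with columns `cluster`, `gene_a`, `gene_b`,
#'   `p_in`, `p_out`, `pd`, `q`, `r`, `score`. Clusters where no pair
#'   survives get a 0-row data.frame (with a warning).
#' @export
rank_pairs <- function(expr, labels, pd_min = 0.5, candidate_genes = NULL) {
  genes <- candidate_genes %||% rownames(expr)
  if (length(genes) < 2) stop("need >= 2 candidate genes")
  miss <- setdiff(genes, rownames(expr))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  samples <- intersect(colnames(expr), names(labels$assignments))
  if (!length(samples)) stop("no labeled samples in the expression matrix")
  lab <- labels$assignments[samples]
  X <- expr[genes, samples, drop = FALSE]
  G <- length(genes)
  clusters <- labels$label_set[labels$label_set %in% lab]

  # count, per cluster, of samples with X[i, s] < X[j, s] over all (i, j)
  cin <- lapply(clusters, function(cl) matrix(0, G, G))
  names(cin) <- clusters
  for (s in seq_along(samples)) {
    cl <- lab[s]
    cin[[cl]] <- cin[[cl]] + outer(X[, s], X[, s], `<`)
  }
  ctot <- Reduce(`+`, cin)
  nin <- table(factor(lab, levels = clusters))

  iu <- which(upper.tri(ctot), arr.ind = TRUE) # i < j, each unordered pair once
  ij <- iu; ji <- iu[, c(2, 1), drop = FALSE]

  out <- stats::setNames(vector("list", length(clusters)), clusters)
  for (cl in clusters) {
    n_in <- as.numeric(nin[[cl]]); n_out <- length(samples) - n_in
    if (n_in == 0 || n_out == 0) next
    p_in <- cin[[cl]] / n_in
    p_out <- (ctot - cin[[cl]]) / n_out
    pdm <- p_in - p_out
    m_in <- rowMeans(X[, lab == cl, drop = FALSE])
    m_out <- rowMeans(X[, lab != cl, drop = FALSE])

    pd_ij <- pdm[ij]; pd_ji <- pdm[ji]
    flip <- pd_ji > pd_ij  # canonical orientation: larger (>= 0) PD
    a <- ifelse(flip, ij[, 2], ij[, 1])
    b <- ifelse(flip, ij[, 1], ij[, 2])
    pd <- ifelse(flip, pd_ji, pd_ij)
    keep <- pd >= pd_min
    if (!any(keep)) {
      warning("no pair with PD >= ", pd_min, " for cluster ", cl)
      out[[cl]] <- data.frame(cluster = character(), gene_a = character(),
                              gene_b = character(), p_in = numeric(),
                              p_out = numeric(), pd = numeric(),
                              q = numeric(), r = numeric(), score = numeric())
      next
    }
    a <- a[keep]; b <- b[keep]; pd <- pd[keep]
    q <- m_in[a] - m_in[b]
    r <- m_out[a] - m_out[b]
    df <- data.frame(cluster = cl,
                     gene_a = genes[a], gene_b = genes[b],
                     p_in = p_in[cbind(a, b)], p_out = p_out[cbind(a, b)],
                     pd = pd, q = unname(q), r = unname(r),
                     score = abs(pd) * (-q * r),
                     stringsAsFactors = FALSE)
    ord <- order(-df$score, -abs(df$pd), df$gene_a, df$gene_b)
    out[[cl]] <- df[ord, , drop = FALSE]
    rownames(out[[cl]]) <- NULL
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Greedy correlation-capped selection of top-ranked pairs
#'
#' Walks each cluster's ranking top-down and accepts a pair iff neither
#' member gene's expression has absolute Pearson correlation above `corr_max`
#' (across labeled samples) with any gene already selected for that cluster.
#' A gene that was itself already selected has self-correlation 1, so pairs
#' reusing a selected gene are rejected automatically.
#'
#' @param ranked per-cluster ranking from [rank_pairs()].
#' @param expr expression matrix the correlations are computed on.
#' @param k_per_cluster pairs to select per cluster (default 10).
#' @param corr_max correlation cap (default 0.85).
#' @param labels optional [cluster_labels()]; when given, correlations use
#'   labeled samples only.
#' @return [feature_set()] with selection provenance. If fewer than
#'   `k_per_cluster` pairs are available for a cluster, what was found is
#'   returned with a warning; if nothing is selectable anywhere the
#'   feature set is empty (warning), not an error.
#' @export
select_features <- function(ranked, expr, k_per_cluster = 10,
                            corr_max = 0.85, labels = NULL) {
  samples <- colnames(expr)
  if (!is.null(labels))
    samples <- intersect(samples, names(labels$assignments))
  Xt <- t(expr[, samples, drop = FALSE]) # samples x genes for cor()
  sel <- list()
  for (cl in names(ranked)) {
    rk <- ranked[[cl]]
    chosen <- integer(0)
    sel_genes <- character(0)
    for (i in seq_len(nrow(rk))) {
      if (length(chosen) >= k_per_cluster) break
      ga <- rk$gene_a[i]; gb <- rk$gene_b[i]
      if (ga %in% sel_genes || gb %in% sel_genes) next
      if (length(sel_genes)) {
        cc <- abs(stats::cor(Xt[, c(ga, gb), drop = FALSE],
                             Xt[, sel_genes, drop = FALSE]))
        if (any(cc > corr_max, na.rm = TRUE)) next
      }
      chosen <- c(chosen, i)
      sel_genes <- c(sel_genes, ga, gb)
    }
    if (length(chosen) < k_per_cluster)
      warning("cluster ", cl, ": only ", length(chosen), " of ",
              k_per_cluster, " pairs available")
    if (length(chosen))
      sel[[cl]] <- rk[chosen, c("cluster", "gene_a", "gene_b"), drop = FALSE]
  }
  if (!length(sel)) {
    warning("no pairs selected for any cluster")
    sel <- list(data.frame(cluster = character(), gene_a = character(),
                           gene_b = character()))
  }
  feature_set(do.call(rbind, sel),
              provenance = list(k_per_cluster = k_per_cluster,
                                corr_max = corr_max,
                                n_samples = length(samples)))
}

#' Filter a feature set by cross-platform gene correlation
#'
#' Drops pairs where either member gene's Spearman correlation between the
#' two platforms (over matched sample ids) falls below `corr_min`. Genes
#' absent from the secondary matrix are treated as failing the filter.
#'
#' @param fs [feature_set()].
#' @param expr_primary,expr_secondary expression matrices sharing >= 3 sample
#'   ids.
#' @param corr_min minimum cross-platform Spearman correlation.
#' @return filtered [feature_set()]; dropped pairs reported via `message`.
#' @export
cross_platform_refine <- function(fs, expr_primary, expr_secondary,
                                  corr_min = 0.5) {
  stopifnot(inherits(fs, "feature_set"))
  matched <- intersect(colnames(expr_primary), colnames(expr_secondary))
  if (length(matched) < 3)
    stop("need >= 3 matched samples across platforms, got ", length(matched))
  if (!nrow(fs$pairs)) return(fs)
  genes <- unique(c(fs$pairs$gene_a, fs$pairs$gene_b))
  cc <- stats::setNames(rep(-Inf, length(genes)), genes)
  present <- genes[genes %in% rownames(expr_primary) &
                     genes %in% rownames(expr_secondary)]
  for (g in present)
    cc[g] <- stats::cor(expr_primary[g, matched], expr_secondary[g, matched],
                        method = "spearman")
  ok <- cc[fs$pairs$gene_a] >= corr_min & cc[fs$pairs$gene_b] >= corr_min
  ok[is.na(ok)] <- FALSE
  if (any(!ok))
    message("cross_platform_refine: dropped ", sum(!ok), " pair(s): ",
            paste(fs$pairs$gene_a[!ok], fs$pairs$gene_b[!ok],
                  sep = "-", collapse = ", "))
  prov <- fs$provenance
  prov$cross_platform_corr_min <- corr_min
  feature_set(fs$pairs[ok, , drop = FALSE], prov)
}
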