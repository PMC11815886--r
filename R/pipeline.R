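# Experiment designs: platform transfer, round-trip label validation, and
# cross-dataset aggregation of informative features.

#' Train on one dataset and predict another (platform transfer)
#'
#' Trains a pair ensemble on the source matrix and predicts the target. When
#' target labels are supplied, a [classification_report()] is attached. With
#' `missing = "drop"`, pairs whose genes are absent from either matrix are
#' dropped up-front (refusing when more than 25% of any cluster's pairs
#' would be lost), mirroring real cross-cohort use.
#'
#' @param train_expr,train_labels source data.
#' @param fs [feature_set()].
#' @param params [model_params()].
#' @param target_expr target expression matrix.
#' @param target_labels optional [cluster_labels()] for the target.
#' @param missing missing-gene policy, `"error"` or `"drop"`.
#' @return object of class `transfer_result`: list with `model`,
#'   `predictions` (`pair_prediction`), and `report` (NULL when no target
#'   labels).
#' @export
transfer_predict <- function(train_expr, train_labels, fs,
                             params = model_params(), target_expr,
                             target_labels = NULL,
                             missing = c("error", "drop")) {
  missing <- match.arg(missing)
  if (missing == "drop") {
    both <- intersect(rownames(train_expr), rownames(target_expr))
    absent <- !(fs$pairs$gene_a %in% both & fs$pairs$gene_b %in% both)
    if (any(absent)) {
      frac <- tapply(absent, fs$pairs$cluster, mean)
      if (any(frac > 0.25))
        stop("refusing to drop > 25% of pairs for cluster(s): ",
             paste(names(frac)[frac > 0.25], collapse = ", "))
      warning("dropping ", sum(absent), " pair(s) with genes missing ",
              "from one platform")
      fs <- feature_set(fs$pairs[!absent, , drop = FALSE], fs$provenance)
    }
  }
  model <- train_ensemble(binarize_pairs(train_expr, fs), train_labels,
                          params)
  pred <- stats::predict(model, target_expr)
  rep <- if (!is.null(target_labels))
    classification_report(target_labels, pred) else NULL
  structure(list(model = model, predictions = pred, report = rep),
            class = "transfer_result")
}

#' Round-trip label validation across two datasets
#'
#' Stage 1 predicts labels on `other_expr` with a model trained on
#' (`train_expr`, `train_labels`). Stage 2 trains a fresh model on
#' `other_expr` using those predicted labels (clusters that received no, or a
#' single, prediction are skipped with a warning). Stage 3 predicts back onto
#' `train_expr` and scores against the known labels. High back-prediction
#' accuracy indicates the label-defining patterns survived the transfer.
#'
#' @param train_expr,train_labels the labeled source dataset.
#' @param fs [feature_set()].
#' @param params [model_params()].
#' @param other_expr the unlabeled second dataset.
#' @return list with `other_prediction` (stage-1 `pair_prediction`),
#'   `back_prediction` (stage-3), `back_report` ([classification_report()]).
#' @export
round_trip <- function(train_expr, train_labels, fs,
                       params = model_params(), other_expr) {
  m1 <- train_ensemble(binarize_pairs(train_expr, fs), train_labels, params)
  p_other <- stats::predict(m1, other_expr)
  counts <- table(factor(p_other$best_call, levels = train_labels$label_set))
  usable <- names(counts)[counts >= 2]
  dropped <- setdiff(train_labels$label_set, usable)
  if (length(dropped))
    warning("no (or a single) sample predicted for cluster(s) ",
            paste(dropped, collapse = ", "),
            "; skipped in stage-2 training")
  if (length(usable) < 2)
    stop("fewer than 2 clusters received predictions; cannot retrain")
  keep <- p_other$best_call %in% usable
  labels2 <- cluster_labels(p_other$best_call[keep], usable)
  m2 <- train_ensemble(
    binarize_pairs(other_expr[, names(labels2$assignments), drop = FALSE], fs),
    labels2, params)
  p_back <- stats::predict(m2, train_expr)
  rep <- classification_report(train_labels, p_back)
  list(other_prediction = p_other, back_prediction = p_back,
       back_report = rep)
}

#' Aggregate informative gene-pair features across datasets
#'
#' For every dataset, selects features (in-dataset pair ranking + greedy
#' selection), trains an ensemble, and extracts each cluster's `top_n`
#' features by median information gain. Pairs (identified by cluster and
#' unordered gene pair, so both orientations count as one feature) found in
#' the informative lists of at least `min_datasets` datasets -- always
#' including the reference dataset -- form the aggregated feature set, with
#' orientation and order taken from the reference.
#'
#' @param datasets list of lists, each with elements `expr` (matrix),
#'   `labels` ([cluster_labels()]; given or predicted), `id` (string).
#' @param feature_selection list of selection settings (`pd_min`,
#'   `k_per_cluster`, `corr_max`, `candidate_genes`).
#' @param params [model_params()].
#' @param top_n informative features kept per cluster and dataset.
#' @param min_datasets minimum number of datasets a pair must appear in.
#' @param reference id of the reference dataset.
#' @return object of class `aggregated_features`: list with `report` (per
#'   pair: cluster, genes, `dataset_count`, per-dataset median gains) and
#'   `selected` ([feature_set()]).
#' @export
aggregate_features <- function(datasets, feature_selection = list(),
                               params = model_params(), top_n = 10,
                               min_datasets = 3, reference) {
  ids <- vapply(datasets, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("dataset ids must be unique")
  if (!reference %in% ids) stop("reference dataset '", reference,
                                "' not among: ", paste(ids, collapse = ", "))
  if (length(datasets) < min_datasets)
    stop("need at least min_datasets (", min_datasets, ") datasets")
  cfg <- feature_selection

  # per dataset: (cluster, unordered pair key) -> gain, plus reference pairs
  informative <- list()
  for (d in datasets) {
    sx <- d$expr
    if (isTRUE(cfg$log_scale %||% TRUE)) sx <- log2(sx + 1)
    rk <- rank_pairs(sx, d$labels, pd_min = cfg$pd_min %||% 0.5,
                     candidate_genes = cfg$candidate_genes)
    fs <- suppressWarnings(
      select_features(rk, sx, k_per_cluster = cfg$k_per_cluster %||% 10,
                      corr_max = cfg$corr_max %||% 0.85, labels = d$labels))
    model <- train_ensemble(binarize_pairs(d$expr, fs), d$labels, params)
    imp <- feature_importance(model)
    rows <- list()
    for (cl in names(imp)) {
      own <- imp[[cl]][startsWith(imp[[cl]]$feature_id, paste0(cl, ":")), ]
      own <- utils::head(own, top_n)
      pr <- strsplit(sub("^[^:]*:", "", own$feature_id), "<", fixed = TRUE)
      rows[[cl]] <- data.frame(
        cluster = cl,
        gene_a = vapply(pr, `[`, character(1), 1),
        gene_b = vapply(pr, `[`, character(1), 2),
        gain = own$median_gain,
        stringsAsFactors = FALSE)
    }
    rows <- do.call(rbind, rows)
    rows$key <- pair_key(rows$cluster, rows$gene_a, rows$gene_b)
    informative[[d$id]] <- rows
  }

  ref <- informative[[reference]]
  all_keys <- unique(unlist(lapply(informative, `[[`, "key")))
  count <- vapply(all_keys, function(k)
    sum(vapply(informative, function(t) k %in% t$key, logical(1))),
    numeric(1))
  gain_tab <- vapply(ids, function(id) {
    t <- informative[[id]]
    g <- stats::setNames(rep(NA_real_, length(all_keys)), all_keys)
    g[t$key] <- t$gain
    g
  }, numeric(length(all_keys)))
  colnames(gain_tab) <- paste0("gain_", ids)

  sel_keys <- ref$key[ref$key %in% all_keys[count >= min_datasets]]
  sel <- ref[match(sel_keys, ref$key), c("cluster", "gene_a", "gene_b")]
  report <- data.frame(
    ref[match(all_keys, ref$key, nomatch = NA),
        c("cluster", "gene_a", "gene_b")],
    dataset_count = count, gain_tab, row.names = NULL, check.names = FALSE)
  # pairs absent from the reference list: recover identity from any dataset
  na_rows <- which(is.na(report$cluster))
  for (i in na_rows) {
    k <- all_keys[i]
    for (t in informative) {
      j <- match(k, t$key)
      if (!is.na(j)) {
        report[i, c("cluster", "gene_a", "gene_b")] <-
          t[j, c("cluster", "gene_a", "gene_b")]
        break
      }
    }
  }
  selected <- feature_set(sel, provenance = list(
    top_n = top_n, min_datasets = min_datasets, reference = reference,
    datasets = paste(ids, collapse = ",")))
  structure(list(report = report[order(report$cluster,
                                       -report$dataset_count), ],
                 selected = selected),
            class = "aggregated_features")
}

# orientation-free identity of a pair within a cluster
pair_key <- function(cluster, a, b) {
  paste0(cluster, "|", pmin(a, b), "|", pmax(a, b))
}
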