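# Classification metrics, stratified cross-validation, and grid search.

#' Confusion matrix and per-cluster classification metrics
#'
#' Per-cluster one-vs-rest sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, and F1 (`2PR/(P+R)`, defined as 0 when `P + R = 0`),
#' plus overall accuracy and macro-averaged F1.
#'
#' @param true [cluster_labels()] or named character vector of true labels.
#' @param pred a `pair_prediction` or named character vector of predicted
#'   labels. Sample sets must match exactly.
#' @return object of class `classification_report`: list with `confusion`
#'   (true x predicted), `accuracy`, `per_cluster` (data.frame with
#'   sensitivity, specificity, precision, f1), `macro_f1`.
#' @export
classification_report <- function(true, pred) {
  tl <- if (inherits(true, "cluster_labels")) true$assignments else true
  pl <- if (inherits(pred, "pair_prediction")) pred$best_call else pred
  if (!length(intersect(names(tl), names(pl))))
    stop("no overlapping samples between true and predicted labels")
  if (!setequal(names(tl), names(pl)))
    stop("true and predicted labels must cover the same samples")
  pl <- pl[names(tl)]
  lset <- if (inherits(true, "cluster_labels")) true$label_set else
    sort(unique(c(tl, pl)))
  lset <- union(lset, unique(c(tl, pl)))
  cm <- table(factor(tl, levels = lset), factor(pl, levels = lset))
  names(dimnames(cm)) <- c("true", "predicted")
  n <- sum(cm)
  per <- lapply(lset, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- n - tp - fn - fp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
    data.frame(cluster = cl, sensitivity = sens, specificity = spec,
               precision = prec, f1 = f1, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  structure(list(confusion = cm,
                 accuracy = sum(diag(cm)) / n,
                 per_cluster = per,
                 macro_f1 = mean(per$f1)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> accuracy", round(x$accuracy, 3),
      "macro F1", round(x$macro_f1, 3), "\n")
  print(x$confusion)
  print(x$per_cluster, digits = 3)
  invisible(x)
}

# stratified fold assignment: within each cluster, shuffled round-robin
stratified_folds <- function(lab, n_folds, seed) {
  set.seed(seed)
  fold <- stats::setNames(integer(length(lab)), names(lab))
  for (cl in unique(lab)) {
    idx <- sample(names(lab)[lab == cl])
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the pair ensemble
#'
#' Folds are stratified by cluster. When a `feature_selection` config is
#' given, pair ranking and selection are re-run inside every training fold so
#' no information from held-out samples leaks into the features; otherwise a
#' fixed `feature_set` is used. A fold in which no pair survives selection
#' (possible on uninformative data) falls back to predicting the training
#' prior, with a warning. Predictions from all folds are collated
#' before one report is computed.
#'
#' @param expr expression matrix.
#' @param labels [cluster_labels()].
#' @param params [model_params()].
#' @param n_folds number of folds (default 10); must not exceed the smallest
#'   cluster size.
#' @param seed seed for fold assignment (learner seeds come from `params`).
#' @param feature_set fixed [feature_set()] (used when `feature_selection`
#'   is NULL).
#' @param feature_selection optional list of scoring/selection settings:
#'   `pd_min`, `k_per_cluster`, `corr_max`, `candidate_genes`, `log_scale`
#'   (default TRUE: score magnitudes and selection correlations are computed
#'   on `log2(x + 1)`-transformed expression, the field's working scale;
#'   pair indicators are unaffected by any monotone transform).
#' @return list with `prediction` (collated `pair_prediction`), `report`
#'   ([classification_report()]), `folds` (named fold assignment).
#' @export
cross_validate <- function(expr, labels, params = model_params(),
                           n_folds = 10, seed = 1,
                           feature_set = NULL, feature_selection = NULL) {
  samples <- intersect(colnames(expr), names(labels$assignments))
  lab <- labels$assignments[samples]
  sizes <- table(lab)
  if (n_folds > min(sizes))
    stop("n_folds (", n_folds, ") exceeds the smallest cluster size (",
         min(sizes), "); folds would lack that cluster")
  if (is.null(feature_set) && is.null(feature_selection))
    stop("provide either a feature_set or a feature_selection config")
  fold <- stratified_folds(lab, n_folds, seed)

  all_scores <- list(); all_prob <- list(); all_best <- character(0)
  for (f in seq_len(n_folds)) {
    tr <- names(fold)[fold != f]
    te <- names(fold)[fold == f]
    tr_labels <- cluster_labels(labels$assignments[tr], labels$label_set)
    fs <- feature_set
    if (!is.null(feature_selection)) {
      cfg <- feature_selection
      sx <- expr[, tr, drop = FALSE]
      if (isTRUE(cfg$log_scale %||% TRUE)) sx <- log2(sx + 1)
      rk <- rank_pairs(sx, tr_labels,
                       pd_min = cfg$pd_min %||% 0.5,
                       candidate_genes = cfg$candidate_genes)
      fs <- suppressWarnings(
        select_features(rk, sx,
                        k_per_cluster = cfg$k_per_cluster %||% 10,
                        corr_max = cfg$corr_max %||% 0.85,
                        labels = tr_labels))
    }
    if (nrow(fs$pairs) == 0) {
      # no informative pair survived in-fold selection: fall back to the
      # training prior (majority class, class-frequency scores)
      warning("fold ", f, ": no features selected; predicting the prior")
      freq <- table(factor(tr_labels$assignments, labels$label_set))
      freq <- freq / sum(freq)
      sc <- matrix(rep(as.numeric(freq), each = length(te)),
                   nrow = length(te),
                   dimnames = list(te, paste0("score_",
                                              labels$label_set)))
      all_scores[[f]] <- sc
      pb <- sc
      colnames(pb) <- labels$label_set
      all_prob[[f]] <- pb
      all_best <- c(all_best,
                    stats::setNames(rep(names(freq)[which.max(freq)],
                                        length(te)), te))
    } else {
      model <- train_ensemble(binarize_pairs(expr[, tr, drop = FALSE], fs),
                              tr_labels, params)
      p <- stats::predict(model, expr[, te, drop = FALSE])
      all_scores[[f]] <- p$scores
      all_prob[[f]] <- p$prob
      all_best <- c(all_best, p$best_call)
    }
  }
  scores <- do.call(rbind, all_scores)[samples, , drop = FALSE]
  prob <- do.call(rbind, all_prob)[samples, , drop = FALSE]
  pred <- structure(list(sample_ids = samples, scores = scores, prob = prob,
                         best_call = all_best[samples],
                         label_set = labels$label_set),
                    class = "pair_prediction")
  rep <- classification_report(
    cluster_labels(lab, labels$label_set), pred)
  list(prediction = pred, report = rep, folds = fold)
}

#' Exhaustive grid search over ensemble parameters
#'
#' Evaluates every combination in `grid` by cross-validation with a fixed
#' feature set and returns the parameters maximizing macro F1. Ties are
#' broken by smaller `max_depth`, then smaller `nrounds`, then first in grid
#' order. The full evaluation table is returned for audit.
#'
#' @param expr,labels,feature_set,n_folds,seed as in [cross_validate()].
#' @param grid named list mapping parameter names (fields of
#'   [model_params()]) to candidate values.
#' @return list with `best_params` ([model_params()]) and `table`
#'   (data.frame: one row per grid point plus `macro_f1`).
#' @export
grid_search <- function(expr, labels, feature_set, grid,
                        n_folds = 10, seed = 1) {
  if (!length(grid)) stop("grid must be non-empty")
  valid <- setdiff(names(formals(model_params)), "seed")
  bad <- setdiff(names(grid), valid)
  if (length(bad))
    stop("invalid parameter name(s): ", paste(bad, collapse = ", "))
  tab <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$macro_f1 <- NA_real_
  for (i in seq_len(nrow(tab))) {
    p <- do.call(model_params,
                 c(as.list(tab[i, names(grid), drop = FALSE]),
                   list(seed = seed)))
    cv <- cross_validate(expr, labels, params = p, n_folds = n_folds,
                         seed = seed, feature_set = feature_set)
    tab$macro_f1[i] <- cv$report$macro_f1
  }
  depth <- if ("max_depth" %in% names(tab)) tab$max_depth else
    rep(formals(model_params)$max_depth, nrow(tab))
  rounds <- if ("nrounds" %in% names(tab)) tab$nrounds else
    rep(formals(model_params)$nrounds, nrow(tab))
  ord <- order(-tab$macro_f1, depth, rounds, seq_len(nrow(tab)))
  best <- ord[1]
  best_params <- do.call(model_params,
                         c(as.list(tab[best, names(grid), drop = FALSE]),
                           list(seed = seed)))
  list(best_params = best_params, table = tab)
}
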