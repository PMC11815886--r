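# Robust ensemble classifier over binarized gene-pair features.
#
# One stack of `ensemble_size` binary gradient-boosted learners per cluster
# (one-vs-rest), each trained on an independent stratified random subsample;
# the per-cluster score is the median of the stack's positive-class
# probabilities, and a final multi-class boosted meta-predictor over the
# per-cluster median scores emits the "best call".

#' Model parameters for the pair ensemble
#'
#' Defaults follow the grid-searched operating point of the method:
#' 11 learners per cluster, tree depth 12, 80% stratified subsampling,
#' median aggregation. `eta`, `nrounds`, `lambda`, `alpha` are the underlying
#' booster's learning rate, boosting rounds, and L2/L1 regularization.
#'
#' @param ensemble_size odd number of binary learners per cluster.
#' @param subsample_fraction fraction of training samples per learner.
#' @param max_depth tree depth of the boosted trees.
#' @param eta learning rate.
#' @param nrounds boosting rounds.
#' @param lambda,alpha L2 / L1 regularization.
#' @param seed base seed; every learner's seed is derived from it.
#' @return list of class `model_params`.
#' @export
model_params <- function(ensemble_size = 11, subsample_fraction = 0.8,
                         max_depth = 12, eta = 0.3, nrounds = 50,
                         lambda = 1, alpha = 0, seed = 1) {
  if (ensemble_size < 1 || ensemble_size %% 2 == 0)
    stop("ensemble_size must be odd and >= 1")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must be in (0, 1]")
  if (max_depth < 1) stop("max_depth must be >= 1")
  structure(list(ensemble_size = as.integer(ensemble_size),
                 subsample_fraction = subsample_fraction,
                 max_depth = as.integer(max_depth), eta = eta,
                 nrounds = as.integer(nrounds), lambda = lambda,
                 alpha = alpha, seed = as.integer(seed)),
            class = "model_params")
}

#' Binarize expression into gene-pair indicator features
#'
#' Feature `cluster:gene_a<gene_b` is 1 for a sample iff
#' `value(gene_a) < value(gene_b)` in that sample (ties give 0). Features are
#' pooled across all clusters' pair lists. Because each feature depends only
#' on a within-sample ordering, the matrix is invariant to strictly
#' increasing per-sample transforms of `expr`.
#'
#' @param expr expression matrix.
#' @param fs [feature_set()].
#' @param missing `"error"` (default) to fail when a feature gene is absent
#'   from `expr`; `"drop"` to drop affected pairs from all clusters (with a
#'   warning), refusing when more than 25% of any cluster's pairs would go.
#' @return object of class `pair_feature_matrix`: list with `sample_ids`,
#'   `feature_ids`, `values` (samples x features 0/1 matrix), `pairs` (the
#'   pairs actually used).
#' @export
binarize_pairs <- function(expr, fs, missing = c("error", "drop")) {
  missing <- match.arg(missing)
  stopifnot(inherits(fs, "feature_set"))
  pairs <- fs$pairs
  absent <- !(pairs$gene_a %in% rownames(expr) &
                pairs$gene_b %in% rownames(expr))
  if (any(absent)) {
    if (missing == "error")
      stop("feature gene(s) missing from expression matrix: ",
           paste(setdiff(unique(c(pairs$gene_a, pairs$gene_b)),
                         rownames(expr)), collapse = ", "))
    frac <- tapply(absent, pairs$cluster, mean)
    if (any(frac > 0.25))
      stop("refusing to drop > 25% of pairs for cluster(s): ",
           paste(names(frac)[frac > 0.25], collapse = ", "))
    warning("dropping ", sum(absent), " pair(s) with missing genes")
    pairs <- pairs[!absent, , drop = FALSE]
  }
  vals <- matrix(0L, nrow = ncol(expr), ncol = nrow(pairs))
  for (i in seq_len(nrow(pairs)))
    vals[, i] <- as.integer(expr[pairs$gene_a[i], ] < expr[pairs$gene_b[i], ])
  ids <- sprintf("%s:%s<%s", pairs$cluster, pairs$gene_a, pairs$gene_b)
  dimnames(vals) <- list(colnames(expr), ids)
  structure(list(sample_ids = colnames(expr), feature_ids = ids,
                 values = vals, pairs = pairs),
            class = "pair_feature_matrix")
}

# deterministic per-learner seed schedule derived from params$seed
learner_seeds <- function(seed, n_clusters, ensemble_size) {
  set.seed(seed)
  list(stack = matrix(sample.int(.Machine$integer.max,
                                 n_clusters * ensemble_size),
                      nrow = n_clusters),
       final = sample.int(.Machine$integer.max, 1))
}

xgb_binary <- function(x, y, p) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = p$max_depth,
                  eta = p$eta, lambda = p$lambda, alpha = p$alpha,
                  nthread = 1),
    data = xgboost::xgb.DMatrix(x, label = y), nrounds = p$nrounds,
    verbose = 0)
}

#' Train the per-cluster ensemble and best-call meta-predictor
#'
#' For each cluster, `ensemble_size` binary learners are trained on
#' independent stratified subsamples (`subsample_fraction` of positives and
#' of negatives, always keeping >= 1 positive -- naive subsampling can lose
#' all members of a 14-sample cluster). The final multi-class learner is
#' trained on the per-cluster median scores of the full training set. All
#' randomness derives from `params$seed` through a fixed per-learner seed
#' schedule, so training is reproducible.
#'
#' @param features [binarize_pairs()] output.
#' @param labels [cluster_labels()]; every cluster in `label_set` must have
#'   >= 2 labeled samples among the feature matrix's samples.
#' @param params [model_params()].
#' @return object of class `pair_ensemble`; the per-cluster stacks and the
#'   meta-predictor are held as serialized booster bytes, so the model is a
#'   plain R object that can be saved and reloaded.
#' @export
train_ensemble <- function(features, labels, params = model_params()) {
  stopifnot(inherits(features, "pair_feature_matrix"))
  if (!inherits(params, "model_params")) params <- do.call(model_params, params)
  samples <- intersect(features$sample_ids, names(labels$assignments))
  miss <- setdiff(names(labels$assignments), features$sample_ids)
  if (length(miss))
    stop("labeled sample(s) missing from feature matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  lab <- labels$assignments[samples]
  X <- features$values[samples, , drop = FALSE]
  lset <- labels$label_set
  sizes <- table(factor(lab, levels = lset))
  if (any(sizes < 2))
    stop("cluster(s) with < 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))

  K <- length(lset); E <- params$ensemble_size
  seeds <- learner_seeds(params$seed, K, E)
  stacks <- stats::setNames(vector("list", K), lset)
  med <- matrix(NA_real_, nrow = length(samples), ncol = K,
                dimnames = list(samples, lset))
  for (k in seq_len(K)) {
    cl <- lset[k]
    y <- as.numeric(lab == cl)
    pos <- which(y == 1); neg <- which(y == 0)
    stack <- vector("list", E)
    preds <- matrix(NA_real_, nrow = length(samples), ncol = E)
    for (e in seq_len(E)) {
      set.seed(seeds$stack[k, e])
      idx <- c(sample(pos, max(1L, round(params$subsample_fraction * length(pos)))),
               sample(neg, max(1L, round(params$subsample_fraction * length(neg)))))
      bst <- xgb_binary(X[idx, , drop = FALSE], y[idx], params)
      # learners are stored as serialized bytes: plain R vectors are stable
      # across sessions and not tied to live external-pointer handles
      stack[[e]] <- xgboost::xgb.save.raw(bst)
      preds[, e] <- stats::predict(bst, xgboost::xgb.DMatrix(X))
    }
    stacks[[cl]] <- stack
    med[, k] <- apply(preds, 1, stats::median)
  }
  colnames(med) <- paste0("score_", lset)
  set.seed(seeds$final)
  final <- xgboost::xgb.save.raw(xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = K,
                  max_depth = 3, eta = params$eta, lambda = params$lambda,
                  alpha = params$alpha, nthread = 1),
    data = xgboost::xgb.DMatrix(med, label = match(lab, lset) - 1L),
    nrounds = max(20L, params$nrounds %/% 2L), verbose = 0))

  structure(list(feature_set = feature_set(features$pairs),
                 feature_ids = features$feature_ids,
                 params = params, label_set = lset,
                 stacks = stacks, final = final, seeds = seeds),
            class = "pair_ensemble")
}

#' @export
print.pair_ensemble <- function(x, ...) {
  cat("<pair_ensemble>", length(x$label_set), "clusters x",
      x$params$ensemble_size, "learners,", length(x$feature_ids),
      "pair features\n")
  invisible(x)
}

# median per-cluster scores for a feature matrix under a trained model
ensemble_scores <- function(model, values) {
  K <- length(model$label_set)
  med <- matrix(NA_real_, nrow = nrow(values), ncol = K,
                dimnames = list(rownames(values),
                                paste0("score_", model$label_set)))
  dm <- xgboost::xgb.DMatrix(values)
  for (k in seq_len(K)) {
    stack <- model$stacks[[k]]
    preds <- matrix(NA_real_, nrow = nrow(values), ncol = length(stack))
    for (e in seq_along(stack)) {
      bst <- xgboost::xgb.load.raw(stack[[e]])
      preds[, e] <- stats::predict(bst, dm)
    }
    med[, k] <- apply(preds, 1, stats::median)
  }
  med
}

#' Predict cluster labels with a trained pair ensemble
#'
#' Per-cluster score = median over that cluster's stack; best call = the
#' meta-predictor's class, with ties broken by the highest median cluster
#' score and then by label order. Deterministic given the model and input.
#' All of the model's feature genes must be present in `expr`.
#'
#' @param object a `pair_ensemble`.
#' @param expr expression matrix to predict on.
#' @param ... unused.
#' @return object of class `pair_prediction`: list with `sample_ids`,
#'   `scores` (samples x clusters median-score matrix), `prob` (meta-predictor
#'   class probabilities), `best_call` (named character), `label_set`.
#' @export
predict.pair_ensemble <- function(object, expr, ...) {
  features <- binarize_pairs(expr, object$feature_set, missing = "error")
  vals <- features$values
  med <- ensemble_scores(object, vals)
  final <- xgboost::xgb.load.raw(object$final)
  prob <- stats::predict(final, xgboost::xgb.DMatrix(med))
  prob <- matrix(prob, ncol = length(object$label_set),
                 dimnames = list(rownames(vals), object$label_set))
  best <- character(nrow(prob))
  for (i in seq_len(nrow(prob))) {
    p <- prob[i, ]
    top <- which(p == max(p))
    if (length(top) > 1) {
      m <- med[i, top]
      top <- top[m == max(m)]
    }
    best[i] <- object$label_set[top[1]]
  }
  structure(list(sample_ids = rownames(vals), scores = med, prob = prob,
                 best_call = stats::setNames(best, rownames(vals)),
                 label_set = object$label_set),
            class = "pair_prediction")
}

#' @export
print.pair_prediction <- function(x, ...) {
  cat("<pair_prediction>", length(x$sample_ids), "samples;"
      , "calls:", paste(names(table(x$best_call)), table(x$best_call),
                        sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Turn a prediction into a data frame (one score column per cluster)
#' @param x a `pair_prediction`.
#' @param ... unused.
#' @return data.frame with sample_id, per-cluster scores, best_call.
#' @export
as.data.frame.pair_prediction <- function(x, ...) {
  data.frame(sample_id = x$sample_ids, x$scores,
             best_call = unname(x$best_call),
             check.names = FALSE, row.names = NULL)
}

#' Per-cluster feature importance (median split gain across the stack)
#'
#' For each cluster's stack, every learner's total split gain per feature is
#' extracted from the tree dumps and the median across learners is reported
#' (features a learner never split on count as 0 gain). Gains are in the
#' boosting library's native gain units.
#'
#' @param model trained `pair_ensemble`.
#' @return named list (per cluster) of data.frames `feature_id`,
#'   `median_gain`, sorted by gain descending.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "pair_ensemble"))
  if (!length(model$stacks) || !length(model$stacks[[1]]))
    stop("model has an empty learner stack")
  ids <- model$feature_ids
  out <- list()
  for (cl in model$label_set) {
    stack <- model$stacks[[cl]]
    gains <- matrix(0, nrow = length(ids), ncol = length(stack),
                    dimnames = list(ids, NULL))
    for (e in seq_along(stack)) {
      bst <- xgboost::xgb.load.raw(stack[[e]])
      dt <- xgboost::xgb.model.dt.tree(model = bst)
      dt <- dt[dt$Feature != "Leaf", , drop = FALSE]
      if (nrow(dt)) {
        tg <- tapply(dt$Gain, dt$Feature, sum)
        gains[names(tg), e] <- tg
      }
    }
    m <- apply(gains, 1, stats::median)
    df <- data.frame(feature_id = ids, median_gain = unname(m),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$median_gain, df$feature_id), , drop = FALSE]
    rownames(df) <- NULL
    out[[cl]] <- df
  }
  out
}
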