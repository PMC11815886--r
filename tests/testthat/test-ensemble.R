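test_that("binarization builds one 0/1 column per pair, ties give 0", {
  x <- rbind(A = c(1, 5, 3), B = c(2, 4, 3), C = c(0, 9, 1),
             D = c(2, 2, 2))
  colnames(x) <- paste0("s", 1:3)
  fs <- feature_set(data.frame(cluster = c("c1", "c1", "c2"),
                               gene_a = c("A", "C", "A"),
                               gene_b = c("B", "D", "D")))
  f <- binarize_pairs(x, fs)
  expect_equal(dim(f$values), c(3, 3))
  expect_equal(unname(f$values[, "c1:A<B"]), c(1L, 0L, 0L)) # s3 is a tie
  expect_equal(unname(f$values[, "c2:A<D"]), c(1L, 0L, 0L))
  expect_identical(f$feature_ids, c("c1:A<B", "c1:C<D", "c2:A<D"))
})

test_that("missing feature genes follow the declared policy", {
  x <- rbind(A = 1:4, B = 4:1, C = c(1, 3, 2, 4))
  colnames(x) <- paste0("s", 1:4)
  fs <- feature_set(data.frame(cluster = "c1",
                               gene_a = c("A", "C", "E", "F"),
                               gene_b = c("B", "D", "G", "H")))
  expect_error(binarize_pairs(x, fs, missing = "error"), "missing")
  # 3 of 4 pairs unresolvable: exceeds the 25% cap
  expect_error(binarize_pairs(x, fs, missing = "drop"), "25%")
  # a tolerable fraction is dropped with a warning (1 of 4 = 25%)
  x2 <- rbind(x, D = c(2, 2, 2, 2), E = 1:4, F = 4:1, G = c(1, 2, 1, 2))
  fs3 <- feature_set(data.frame(cluster = "c1",
                                gene_a = c("A", "C", "E", "Zmiss"),
                                gene_b = c("B", "D", "F", "G")))
  expect_warning(f3 <- binarize_pairs(x2, fs3, missing = "drop"),
                 "dropping")
  expect_equal(ncol(f3$values), 3)
})

test_that("training is deterministic and separable cohorts are learned exactly", {
  co <- small_cohort(seed = 1)
  fs <- select_from_cohort(co, k_per_cluster = 3)
  feats <- binarize_pairs(co$expression, fs)
  m1 <- train_ensemble(feats, co$labels, fast_params(seed = 7))
  p1 <- predict(m1, co$expression)
  rep1 <- classification_report(co$labels, p1)
  expect_equal(rep1$accuracy, 1)  # planted |PD| ~ 1: separable

  m2 <- train_ensemble(feats, co$labels, fast_params(seed = 7))
  p2 <- predict(m2, co$expression)
  expect_identical(p1$best_call, p2$best_call)
  expect_equal(p1$scores, p2$scores)

  # single-member ensemble with full subsample: score equals the learner's
  pm <- model_params(ensemble_size = 1, subsample_fraction = 1,
                     nrounds = 20, seed = 3)
  m3 <- train_ensemble(feats, co$labels, pm)
  one <- stats::predict(xgboost::xgb.load.raw(m3$stacks[["c1"]][[1]]),
                        xgboost::xgb.DMatrix(feats$values))
  p3 <- predict(m3, co$expression)
  expect_equal(unname(p3$scores[, "score_c1"]), unname(one))
})

test_that("predictions are invariant under per-sample monotone transforms", {
  co <- small_cohort(seed = 2)
  fs <- select_from_cohort(co, k_per_cluster = 3)
  m <- train_ensemble(binarize_pairs(co$expression, fs), co$labels,
                      fast_params(seed = 2))
  p0 <- predict(m, co$expression)
  for (tseed in 1:3) {
    pt <- predict(m, random_monotone(co$expression, tseed))
    expect_identical(pt$best_call, p0$best_call)
    expect_equal(pt$scores, p0$scores)
  }
  # single-sample prediction works
  p1 <- predict(m, co$expression[, 1, drop = FALSE])
  expect_equal(length(p1$best_call), 1L)
  expect_equal(unname(p1$best_call), unname(p0$best_call[1]))
})

test_that("tiny clusters train with at least one positive per learner", {
  set.seed(4)
  x <- matrix(exp(rnorm(20 * 22)), 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:22)))
  x["g1", 1:2] <- 100; x["g2", 1:2] <- 1       # cluster tiny: g2 < g1
  x["g1", 3:22] <- 1; x["g2", 3:22] <- 100
  lab <- cluster_labels(setNames(c("tiny", "tiny", rep("big", 20)),
                                 colnames(x)))
  fs <- feature_set(data.frame(cluster = c("tiny", "big"),
                               gene_a = c("g2", "g3"),
                               gene_b = c("g1", "g4")))
  m <- train_ensemble(binarize_pairs(x, fs), lab, fast_params(seed = 1))
  expect_s3_class(m, "pair_ensemble")
  # a 1-sample cluster is refused by name
  lab2 <- cluster_labels(setNames(c("tiny", rep("big", 21)), colnames(x)))
  expect_error(train_ensemble(binarize_pairs(x, fs), lab2,
                              fast_params(seed = 1)), "tiny")
})

test_that("classification reports match hand-computed confusion tables", {
  tl <- setNames(rep(c("a", "b"), each = 5), paste0("s", 1:10))
  rep1 <- classification_report(tl, tl)
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$per_cluster$f1, c(1, 1))

  # everything predicted "a" over two balanced classes
  pl <- setNames(rep("a", 10), names(tl))
  rep2 <- classification_report(tl, pl)
  expect_equal(rep2$accuracy, 0.5)
  expect_equal(rep2$per_cluster$f1[rep2$per_cluster$cluster == "a"], 2 / 3)
  expect_equal(rep2$per_cluster$f1[rep2$per_cluster$cluster == "b"], 0)
  expect_equal(rep2$per_cluster$specificity[rep2$per_cluster$cluster == "a"], 0)

  # row sums of the confusion matrix are the true class counts
  expect_equal(unname(rowSums(rep2$confusion)), c(5, 5))

  expect_error(classification_report(tl, setNames(rep("a", 2),
                                                  c("x1", "x2"))),
               "no overlapping")
  expect_error(classification_report(tl, pl[1:9]), "same samples")
})

test_that("cross-validation refuses more folds than the smallest cluster", {
  co <- small_cohort(seed = 3)
  expect_error(cross_validate(co$expression, co$labels, fast_params(),
                              n_folds = 11, seed = 1,
                              feature_selection = list()),
               "smallest cluster")
  expect_error(cross_validate(co$expression, co$labels, fast_params(),
                              n_folds = 5, seed = 1),
               "feature_set or")
})

test_that("a planted perfect pair dominates the information-gain ranking", {
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 60
    x <- matrix(exp(rnorm(22 * n)), 22,
                dimnames = list(paste0("g", 1:22), paste0("s", 1:n)))
    lab <- cluster_labels(setNames(rep(c("in", "out"), each = n / 2),
                                   colnames(x)))
    # plant a perfect reversal on g1/g2; g3..g22 feed 9 noise pairs
    x["g1", 1:(n / 2)] <- 1;  x["g2", 1:(n / 2)] <- 10
    x["g1", (n / 2 + 1):n] <- 10; x["g2", (n / 2 + 1):n] <- 1
    fs <- feature_set(data.frame(
      cluster = "in",
      gene_a = paste0("g", seq(1, 19, 2)),
      gene_b = paste0("g", seq(2, 20, 2)),
      stringsAsFactors = FALSE))
    m <- train_ensemble(binarize_pairs(x, fs), lab, fast_params(seed = s))
    imp <- feature_importance(m)
    imp[["in"]]$feature_id[1] == "in:g1<g2"
  }, logical(1))
  expect_true(all(hits))
})

test_that("feature importance is deterministic and needs a trained stack", {
  co <- small_cohort(seed = 6)
  fs <- select_from_cohort(co, k_per_cluster = 3)
  m <- train_ensemble(binarize_pairs(co$expression, fs), co$labels,
                      fast_params(seed = 5))
  i1 <- feature_importance(m)
  i2 <- feature_importance(m)
  expect_identical(i1, i2)
  broken <- m; broken$stacks <- list()
  expect_error(feature_importance(broken), "empty")
})

test_that("grid search evaluates every point and breaks ties toward shallow trees", {
  co <- small_cohort(seed = 2)
  fs <- select_from_cohort(co, k_per_cluster = 3)
  g1 <- grid_search(co$expression, co$labels, fs,
                    grid = list(max_depth = 4), n_folds = 5, seed = 1)
  expect_equal(nrow(g1$table), 1)
  expect_equal(g1$best_params$max_depth, 4L)

  g2 <- grid_search(co$expression, co$labels, fs,
                    grid = list(max_depth = c(2, 6), eta = c(0.3, 0.1)),
                    n_folds = 5, seed = 1)
  expect_equal(nrow(g2$table), 4)       # one row per combination
  expect_true(all(g2$table$macro_f1 > 0.95))  # separable everywhere
  expect_equal(g2$best_params$max_depth, 2L)  # tie-break: smaller depth

  expect_error(grid_search(co$expression, co$labels, fs,
                           grid = list(bogus = 1)), "invalid parameter")
  expect_error(model_params(ensemble_size = 4), "odd")
  expect_error(model_params(subsample_fraction = 0), "subsample")
})
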