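# The worked example used throughout: in-cluster sample values for
# (gene_a, gene_b) are (1,2), (0.5,3), (2,2.5); out-of-cluster values are
# (5,1), (4,2), (3,3.5). Counting gives p_in = 1, p_out = 1/3, PD = 2/3,
# Q = mean(1-2, 0.5-3, 2-2.5) = -4/3, R = mean(5-1, 4-2, 3-3.5) = 11/6.
worked_example <- function() {
  x <- rbind(A = c(1, 0.5, 2, 5, 4, 3),
             B = c(2, 3, 2.5, 1, 2, 3.5),
             C = exp(seq(0.1, 0.6, by = 0.1)))  # filler so nrow >= 2 genes
  colnames(x) <- paste0("s", 1:6)
  lab <- cluster_labels(setNames(rep(c("in", "out"), each = 3),
                                 colnames(x)))
  list(expr = x, labels = lab)
}

test_that("proportion difference matches hand-counted values", {
  w <- worked_example()
  st <- proportion_difference(w$expr, w$labels, "in", c("A", "B"))
  expect_equal(st$p_in, 1)
  expect_equal(st$p_out, 1 / 3)
  expect_equal(st$pd, 2 / 3)
  expect_equal(st$q, -4 / 3)
  expect_equal(st$r, 11 / 6)
  expect_equal(pair_score(st), 44 / 27)
})

test_that("ties count as not-less and degenerate cases give PD 0", {
  x <- rbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4), C = c(9, 9, 9, 9))
  colnames(x) <- paste0("s", 1:4)
  lab <- cluster_labels(setNames(c("in", "in", "out", "out"), colnames(x)))
  st <- proportion_difference(x, lab, "in", c("A", "B"))
  expect_equal(st$p_in, 0)  # ties are not "less than"
  expect_equal(st$p_out, 0)
  expect_equal(st$pd, 0)
  expect_equal(st$q, 0)
  expect_equal(st$r, 0)
  expect_equal(pair_score(st), 0)

  # A < B everywhere: both proportions 1, PD 0
  st2 <- proportion_difference(x, lab, "in", c("A", "C"))
  expect_equal(st2$p_in, 1)
  expect_equal(st2$p_out, 1)
  expect_equal(st2$pd, 0)
})

test_that("pair statistics error on unknown genes or empty groups", {
  w <- worked_example()
  expect_error(proportion_difference(w$expr, w$labels, "in", c("A", "Z")),
               "unknown gene")
  expect_error(proportion_difference(w$expr, w$labels, "zz", c("A", "B")),
               "in and|>= 1 sample")
})

test_that("scores follow the sign rules of the score algebra", {
  set.seed(42)
  for (i in 1:2000) {
    st <- structure(list(pd = runif(1, -1, 1), q = rnorm(1), r = rnorm(1)),
                    class = "pair_stats")
    sc <- pair_score(st)
    expect_equal(sc, abs(st$pd) * (-1 * st$q * st$r))
    expect_identical(sc > 0, st$q * st$r < 0 && st$pd != 0)
    expect_lte(abs(sc), abs(st$q * st$r))
  }
})

test_that("updated score zeroes discordant cross-dataset directions", {
  st <- structure(list(pd = 0.8, q = -1, r = 2), class = "pair_stats")
  expect_equal(updated_pair_score(st, 0.7), 0.8 * 0.7 * 2)
  expect_equal(updated_pair_score(st, 0), 0)
  expect_equal(updated_pair_score(st, -0.7), 0) # discordant sign
  expect_error(updated_pair_score(st, 1.2), "\\[-1, 1\\]")
})

test_that("rank_pairs agrees exactly with the double-loop oracle", {
  for (seed in 1:4) {
    rc <- random_cohort_matrix(seed = seed)
    rk <- suppressWarnings(rank_pairs(rc$expr, rc$labels, pd_min = 0))
    for (cl in names(rk)) {
      df <- rk[[cl]]
      idx <- sample(nrow(df), min(25, nrow(df)))
      for (i in idx) {
        o <- oracle_pair_stats(rc$expr, rc$labels, cl,
                               df$gene_a[i], df$gene_b[i])
        expect_lt(max(abs(df$p_in[i] - o$p_in), abs(df$p_out[i] - o$p_out),
                      abs(df$pd[i] - o$pd), abs(df$q[i] - o$q),
                      abs(df$r[i] - o$r),
                      abs(df$score[i] - abs(o$pd) * (-o$q * o$r))),
                  1e-12)
      }
      # every unordered pair appears exactly once, in some orientation
      expect_equal(nrow(df), choose(nrow(rc$expr), 2))
      expect_false(any(duplicated(pair_id(df$cluster, df$gene_a,
                                          df$gene_b))))
      # canonical orientation: PD >= 0 at pd_min 0
      expect_true(all(df$pd >= 0))
      # sorted by score, ties by |PD| then names
      expect_true(all(diff(df$score) <= 1e-12))
    }
  }
})

test_that("PD and proportions are invariant under monotone transforms; Q and R are not", {
  rc <- random_cohort_matrix(seed = 9)
  rk <- suppressWarnings(rank_pairs(rc$expr, rc$labels, pd_min = 0))
  for (tseed in 1:3) {
    rk2 <- suppressWarnings(rank_pairs(random_monotone(rc$expr, tseed),
                                       rc$labels, pd_min = 0))
    for (cl in names(rk)) {
      a <- rk[[cl]][order(rk[[cl]]$gene_a, rk[[cl]]$gene_b), ]
      b <- rk2[[cl]][order(rk2[[cl]]$gene_a, rk2[[cl]]$gene_b), ]
      expect_equal(a$pd, b$pd)
      expect_equal(a$p_in, b$p_in)
      expect_false(isTRUE(all.equal(a$q, b$q)))
    }
  }
})

test_that("swapping orientation negates PD when there are no ties", {
  rc <- random_cohort_matrix(seed = 5)
  cl <- rc$labels$label_set[1]
  st <- proportion_difference(rc$expr, rc$labels, cl, c("g01", "g02"))
  sw <- proportion_difference(rc$expr, rc$labels, cl, c("g02", "g01"))
  expect_equal(sw$pd, -st$pd)
  expect_equal(sw$p_in, 1 - st$p_in)
  expect_equal(sw$q, -st$q)
})

test_that("pd_min above 1 empties every cluster with a warning", {
  rc <- random_cohort_matrix(seed = 2)
  w <- capture_warnings(rk <- rank_pairs(rc$expr, rc$labels, pd_min = 1.01))
  expect_true(all(grepl("no pair", w)))
  expect_gte(length(w), 1)
  expect_true(all(vapply(rk, nrow, integer(1)) == 0))
})

test_that("mirrored planted pairs rank highly only in their own cluster", {
  co <- generate_cohort(n_samples = 60, cluster_sizes = c(c1 = 30, c2 = 30),
                        n_genes = 40, pairs_per_cluster = 2,
                        effect_size = 4, seed = 7)
  lx <- log2(co$expression + 1)
  rk <- rank_pairs(lx, co$labels, pd_min = 0.3)
  tp <- co$truth$planted_pairs
  for (i in seq_len(nrow(tp))) {
    own <- rk[[tp$cluster[i]]]
    own_rank <- which(pair_id(own$cluster, own$gene_a, own$gene_b) ==
                        pair_id(tp$cluster[i], tp$gene_a[i], tp$gene_b[i]))
    expect_lte(own_rank, 4)
  }
})

test_that("greedy selection enforces the correlation cap", {
  # ranking whose top two pairs share gene_a: only the first survives
  set.seed(11)
  x <- rbind(A = exp(rnorm(20)), B = exp(rnorm(20)), C = exp(rnorm(20)),
             D = exp(rnorm(20)))
  colnames(x) <- paste0("s", 1:20)
  rk <- list(c1 = data.frame(cluster = "c1",
                             gene_a = c("A", "A", "C"),
                             gene_b = c("B", "C", "D"),
                             p_in = 1, p_out = 0, pd = 1, q = -1, r = 1,
                             score = c(3, 2, 1)))
  fs <- suppressWarnings(select_features(rk, x, k_per_cluster = 2))
  expect_equal(nrow(fs$pairs), 2)
  expect_equal(fs$pairs$gene_a, c("A", "C"))

  # an exact copy gene under a different name is caught by the cap
  x2 <- rbind(x, Acopy = x["A", ] * 2)  # perfectly correlated with A
  rk2 <- list(c1 = data.frame(cluster = "c1",
                              gene_a = c("A", "Acopy"),
                              gene_b = c("B", "D"),
                              p_in = 1, p_out = 0, pd = 1, q = -1, r = 1,
                              score = c(3, 2)))
  fs2 <- suppressWarnings(select_features(rk2, x2, k_per_cluster = 2))
  expect_equal(nrow(fs2$pairs), 1)
  expect_equal(fs2$pairs$gene_a, "A")
})

test_that("selected feature sets never violate the correlation cap post hoc", {
  co <- small_cohort(seed = 3)
  lx <- log2(co$expression + 1)
  fs <- select_from_cohort(co, k_per_cluster = 3)
  for (cl in unique(fs$pairs$cluster)) {
    sub <- fs$pairs[fs$pairs$cluster == cl, ]
    genes <- as.vector(rbind(sub$gene_a, sub$gene_b)) # (a1,b1,a2,b2,...)
    cc <- abs(stats::cor(t(lx[genes, names(co$labels$assignments)])))
    diag(cc) <- 0
    # cap applies between genes of different pairs
    for (i in seq(1, length(genes) - 1, by = 2)) {
      others <- setdiff(seq_along(genes), c(i, i + 1))
      if (length(others))
        expect_lte(max(cc[c(i, i + 1), others]), 0.85)
    }
  }
})

test_that("cross-platform refinement drops only noise-replaced genes", {
  co <- small_cohort(seed = 4)
  fs <- select_from_cohort(co, k_per_cluster = 3)
  # a monotone transform of the primary keeps rank correlation 1
  sec <- random_monotone(co$expression, seed = 1)
  expect_equal(nrow(cross_platform_refine(fs, co$expression, sec, 0.5)$pairs),
               nrow(fs$pairs))
  # replace one selected gene by independent noise: its pairs get dropped
  set.seed(2)
  bad_gene <- fs$pairs$gene_a[1]
  sec[bad_gene, ] <- exp(rnorm(ncol(sec)))
  expect_message(ref <- cross_platform_refine(fs, co$expression, sec, 0.5),
                 "dropped")
  expect_false(bad_gene %in% c(ref$pairs$gene_a, ref$pairs$gene_b))
  expect_equal(nrow(ref$pairs), nrow(fs$pairs) - 1)
  # an empty feature set passes through empty
  empty <- feature_set(fs$pairs[0, ])
  expect_equal(nrow(cross_platform_refine(empty, co$expression, sec)$pairs), 0)
  # fewer than 3 matched samples is an error
  expect_error(cross_platform_refine(fs, co$expression,
                                     sec[, 1:2, drop = FALSE]), ">= 3")
})
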