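mat_fm <- function(x, y_pos) {
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  feature_matrix(x, ifelse(y_pos, "positive", "negative"))
}

test_that("f_score matches the hand-computed example and edge cases", {
  # pos {2,4}, neg {0,2}: numerator (3-2)^2 + (1-2)^2 = 2, denominator 2+2
  fm <- mat_fm(cbind(c(2, 4, 0, 2)), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(f_score(fm)$score, 0.5)

  # constant feature -> F = 0
  fm2 <- mat_fm(cbind(rep(1, 6)), rep(c(TRUE, FALSE), 3))
  expect_equal(f_score(fm2)$score, 0)

  # zero within-class variance, nonzero numerator -> epsilon rule
  fm3 <- mat_fm(cbind(c(1, 1, 0, 0)), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(f_score(fm3)$score, 0.5 / 1e-12)
  expect_true(is.finite(f_score(fm3)$score))

  one_pos <- mat_fm(cbind(1:3), c(TRUE, FALSE, FALSE))
  expect_error(f_score(one_pos), "at least 2")
})

test_that("f_score agrees with the textbook oracle and is affine-invariant", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(6:20, 1); p <- sample(2:8, 1)
    x <- matrix(rnorm(n * p), n, p)
    y <- rep_len(c(TRUE, FALSE), n)
    fm <- mat_fm(x, y)
    expect_equal(f_score(fm)$score, fscore_oracle(x, y), tolerance = 1e-10)
    # affine transform x -> a x + b leaves F unchanged
    a <- runif(1, 0.5, 3) * sample(c(-1, 1), 1); b <- rnorm(1)
    expect_equal(f_score(mat_fm(a * x + b, y))$score, f_score(fm)$score,
                 tolerance = 1e-8)
  }
})

test_that("ranking is stable-descending and tfidf ranking uses model scores", {
  fm <- mat_fm(cbind(c(2, 4, 0, 2), c(1, 1, 1, 1)),
               c(TRUE, TRUE, FALSE, FALSE))
  sc <- f_score(fm)
  expect_equal(sc$rank, c(1L, 2L))
  expect_true(all(sort(sc$rank) == seq_along(sc$score)))  # permutation

  m <- fit_tfidf(toy_set("ACAC", "GTGT"), kmer_vocabulary(1, 2))
  tf_fm <- transform_tfidf(m, toy_set("ACGT", "TTAA"))
  r <- rank_features(tf_fm, "tfidf_score", tfidf_model = m)
  expect_equal(r$score, unname(m$tfidf))
  expect_equal(r$rank, order(-m$tfidf))
  expect_error(rank_features(fm, "tfidf_score", tfidf_model = m), "provenance|TF-IDF")
  expect_error(rank_features(tf_fm, "tfidf_score"), "requires")
})

test_that("a planted discriminative feature ranks first among noise", {
  set.seed(62)
  n <- 40
  y <- rep_len(c(TRUE, FALSE), n)
  x <- matrix(rnorm(n * 21), n, 21)
  x[, 7] <- x[, 7] + ifelse(y, 5, 0)   # large class mean gap
  sc <- f_score(mat_fm(x, y))
  expect_equal(sc$rank[1], 7L)
})

test_that("IFS walks the ranking, honors step, and picks the smallest argmax", {
  set.seed(63)
  n <- 40
  y <- rep_len(c(TRUE, FALSE), n)
  x <- cbind(ifelse(y, 1, -1) + rnorm(n, sd = 0.05),
             matrix(rnorm(n * 9), n, 9))  # feature 1 separates perfectly
  fm <- mat_fm(x, y)
  sc <- f_score(fm)
  expect_equal(sc$rank[1], 1L)
  sel <- incremental_feature_selection(fm, sc)
  expect_equal(sel$best_count, 1L)
  expect_gte(sel$curve$accuracy[1], 0.99)
  expect_equal(sel$selected, "f1")
  # monotone nesting of selected sets along the curve
  for (j in seq_len(nrow(sel$curve) - 1))
    expect_true(all(sc$names[sc$rank[seq_len(j)]] %in%
                    sc$names[sc$rank[seq_len(j + 1)]]))

  # step grid {1, 6, 11, 12} on 12 features
  fm12 <- mat_fm(matrix(rnorm(20 * 12), 20, 12), rep_len(c(TRUE, FALSE), 20))
  sel12 <- incremental_feature_selection(fm12, f_score(fm12),
                                         evaluator = function(x, y) 0.5,
                                         step = 5)
  expect_equal(sel12$curve$feature_count, c(1L, 6L, 11L, 12L))
  # tie on the max -> smallest count
  expect_equal(sel12$best_count, 1L)

  # single-feature matrix
  fm1 <- mat_fm(cbind(rnorm(20)), rep_len(c(TRUE, FALSE), 20))
  sel1 <- incremental_feature_selection(fm1, f_score(fm1),
                                        evaluator = function(x, y) 0.7)
  expect_equal(nrow(sel1$curve), 1L)
  expect_equal(sel1$best_count, 1L)

  expect_error(incremental_feature_selection(fm1, f_score(fm1),
                                             evaluator = function(x, y) NaN),
               "non-finite")
})

test_that("the IFS curve ignores unselected columns' values", {
  set.seed(64)
  n <- 30
  y <- rep_len(c(TRUE, FALSE), n)
  x <- matrix(rnorm(n * 6), n, 6)
  fm_a <- mat_fm(x, y)
  sc <- f_score(fm_a)
  ev <- cv_accuracy_evaluator(family = "knn", folds = 3, seed = 9)
  sel_a <- incremental_feature_selection(fm_a, sc, ev, max_count = 3)
  # corrupt the columns ranked below 3: curve up to 3 must not change
  x_b <- x
  x_b[, sc$rank[4:6]] <- 1e6 * matrix(rnorm(n * 3), n, 3)
  fm_b <- mat_fm(x_b, y)
  sel_b <- incremental_feature_selection(fm_b, sc, ev, max_count = 3)
  expect_equal(sel_b$curve, sel_a$curve)
})

test_that("selection results serialize to curve + name list", {
  fm1 <- mat_fm(cbind(a = rnorm(20), b = rnorm(20)),
                rep_len(c(TRUE, FALSE), 20))
  sel <- incremental_feature_selection(fm1, f_score(fm1),
                                       evaluator = function(x, y) ncol(x) / 10)
  cp <- tempfile(fileext = ".tsv"); sp <- tempfile(fileext = ".txt")
  write_selection_result(sel, cp, sp)
  curve <- read.table(cp, header = TRUE, sep = "\t")
  expect_equal(curve$feature_count, sel$curve$feature_count)
  expect_equal(readLines(sp), sel$selected)
})
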