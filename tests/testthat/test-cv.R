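random_fm <- function(n = 60, p = 5, seed = 91) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  feature_matrix(x, rep_len(c("positive", "negative"), n))
}

test_that("fold assignments are stratified partitions, seeded", {
  labels <- factor(rep(c("positive", "negative"), c(20, 30)))
  f <- oriclass:::make_folds(labels, 5, seed = 4)
  expect_length(f, 50)
  expect_true(all(f %in% 1:5))
  # every sample in exactly one fold; classes spread evenly
  for (k in 1:5) {
    expect_equal(sum(f == k & labels == "positive"), 4)
    expect_equal(sum(f == k & labels == "negative"), 6)
  }
  expect_identical(f, oriclass:::make_folds(labels, 5, seed = 4))
  expect_false(identical(f, oriclass:::make_folds(labels, 5, seed = 5)))
  expect_error(oriclass:::make_folds(labels, 1, seed = 1), "folds")
  expect_error(oriclass:::make_folds(factor(rep(c("positive", "negative"),
                                                c(3, 30))), 5, 1),
               "at least")
})

test_that("repeated_cv is reproducible and reports coherent metrics", {
  fm <- random_fm()
  r1 <- repeated_cv("naive_bayes", list(), fm, folds = 5, repeats = 3, seed = 2)
  r2 <- repeated_cv("naive_bayes", list(), fm, folds = 5, repeats = 3, seed = 2)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_equal(nrow(r1$per_repeat), 3L)
  with(r1$per_repeat, {
    expect_true(all(fn <= n_pos & fp <= n_neg))
    expect_true(all(sn >= 0 & sn <= 1 & sp >= 0 & sp <= 1))
    expect_true(all(mcc >= -1 & mcc <= 1 & auc >= 0 & auc <= 1))
  })
  expect_named(r1$mean, c("Sn", "Sp", "Acc", "MCC", "AUC"))
})

test_that("label-independent features score at chance", {
  fm <- random_fm(n = 80, seed = 92)
  r <- repeated_cv("knn", list(k = 5L), fm, folds = 5, repeats = 10, seed = 6)
  se <- sqrt(0.25 / nrow(fm$x))      # binomial SE of accuracy at chance
  expect_lt(abs(r$mean[["Acc"]] - 0.5), 3 * se + 3 * sd(r$per_repeat$acc))
  expect_lt(r$mean[["Acc"]], 0.65)
})

test_that("strong separation yields near-perfect CV and permutation destroys it", {
  set.seed(93)
  n <- 60
  y <- rep_len(c("positive", "negative"), n)
  x <- cbind(a = rnorm(n) + ifelse(y == "positive", 6, 0), b = rnorm(n))
  fm <- feature_matrix(x, y)
  r <- repeated_cv("svm", list(), fm, folds = 5, repeats = 3, seed = 8)
  expect_gte(r$mean[["Acc"]], 0.95)
  expect_gte(r$mean[["AUC"]], 0.98)

  perm <- feature_matrix(x, sample(y))
  rp <- repeated_cv("svm", list(), perm, folds = 5, repeats = 5, seed = 8)
  expect_lt(abs(rp$mean[["Acc"]] - 0.5), 0.2)
})

test_that("grid search is exhaustive, deterministic, first-wins on ties", {
  fm <- random_fm(n = 40, seed = 94)
  one <- classifier_spec("knn", grid = list(k = 3L))
  t1 <- tune_hyperparameters(one, fm, folds = 3, seed = 1)
  expect_equal(t1$best_params, list(k = 3L))

  spec <- classifier_spec("decision_tree",
                          grid = list(min_split = c(2L, 10L), max_depth = c(2L, 4L)))
  tt <- tune_hyperparameters(spec, fm, folds = 3, seed = 1)
  expect_equal(nrow(tt$results), 4L)
  expect_equal(tt$best_accuracy, max(tt$results$accuracy))
  tt2 <- tune_hyperparameters(spec, fm, folds = 3, seed = 1)
  expect_identical(tt$results, tt2$results)

  # separable data: large-cost SVM grid points all reach accuracy 1,
  # winner is the first such grid point in declared order
  set.seed(95)
  ysep <- rep_len(c("positive", "negative"), 30)
  xsep <- cbind(a = rnorm(30) + ifelse(ysep == "positive", 8, 0), b = rnorm(30))
  fsep <- feature_matrix(xsep, ysep)
  gspec <- classifier_spec("svm", grid = list(cost = c(1, 10, 100), gamma = 0.5))
  ts <- tune_hyperparameters(gspec, fsep, folds = 3, seed = 2)
  winners <- ts$results$accuracy == max(ts$results$accuracy)
  expect_equal(unname(unlist(ts$best_params["cost"])),
               ts$results$cost[which(winners)[1]])

  expect_error(tune_hyperparameters(one,
                 feature_matrix(matrix(numeric(0), 0, 1,
                                       dimnames = list(NULL, "a")),
                                character(0)), 3, 1),
               "empty|at least")
})

test_that("evaluation reports export to TSV and summary text", {
  fm <- random_fm(n = 40, seed = 96)
  r <- repeated_cv("naive_bayes", list(), fm, folds = 4, repeats = 2, seed = 3)
  tp <- tempfile(fileext = ".tsv"); sp <- tempfile(fileext = ".txt")
  write_evaluation_report(r, tp, sp)
  tab <- read.table(tp, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 2L)
  txt <- readLines(sp)
  expect_match(txt[2], "Acc.*Sn.*Sp.*MCC.*AUC")
  expect_match(txt[3], sprintf("^%.2f", 100 * r$mean[["Acc"]]))
})
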