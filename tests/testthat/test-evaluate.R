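# Cross-validation plans, confusion-matrix statistics and the evaluation
# protocol.

test_that("stratified folds reproduce the published cohort layouts", {
  # 95 subjects, 51 patients / 44 controls, 5-fold: folds of 19 with 10-11
  # patients each
  lab <- rep(c("patient", "control"), c(51, 44))
  pl <- make_cv_plan(lab, k = 5, runs = 3, seed = 7)
  for (r in 1:3) {
    f <- pl$folds[[r]]
    expect_equal(unname(table(f)), rep(19L, 5), ignore_attr = TRUE)
    pat <- table(f[lab == "patient"])
    expect_true(all(pat %in% c(10L, 11L)))
  }
  # 172 subjects, 86/86, 10-fold: balanced classes within 1
  lab2 <- rep(c("patient", "control"), each = 86)
  pl2 <- make_cv_plan(lab2, k = 10, runs = 2, seed = 8)
  for (r in 1:2) {
    f <- pl2$folds[[r]]
    expect_true(all(table(f) %in% c(17L, 18L)))
    expect_true(all(abs(table(f[lab2 == "patient"]) -
                        table(f[lab2 == "control"])) <= 1))
  }
  # 10 balanced subjects, 5-fold: exactly one of each class per fold
  lab3 <- rep(c("patient", "control"), 5)
  f3 <- make_cv_plan(lab3, k = 5, runs = 1, seed = 9)$folds[[1]]
  expect_true(all(table(f3, lab3) == 1L))
})

test_that("fold plans cover all subjects, are disjoint, and vary by run", {
  lab <- rep(c("patient", "control"), c(12, 15))
  pl <- make_cv_plan(lab, k = 3, runs = 4, seed = 10)
  for (f in pl$folds) {
    expect_length(f, 27L)
    expect_setequal(unique(f), 1:3)
  }
  expect_false(identical(pl$folds[[1]], pl$folds[[2]]))
  expect_error(make_cv_plan(lab, k = 13), "invalid")
})

test_that("the seven statistics follow the printed formulas", {
  m <- classification_metrics(tp = 50, fn = 5, fp = 5, tn = 40)
  expect_equal(m[["accuracy"]], 0.90)
  expect_equal(m[["sensitivity"]], 50 / 55)
  expect_equal(m[["specificity"]], 40 / 45)
  expect_equal(m[["precision"]], 50 / 55)
  expect_identical(m[["recall"]], m[["sensitivity"]])
  expect_equal(m[["f_measure"]],
               2 * m[["precision"]] * m[["recall"]] /
                 (m[["precision"]] + m[["recall"]]))
  expect_equal(m[["gmean"]], sqrt(m[["sensitivity"]] * m[["specificity"]]))
  # perfect classifier
  p <- classification_metrics(tp = 10, fn = 0, fp = 0, tn = 12)
  expect_true(all(p == 1))
})

test_that("degenerate confusion counts give NA markers, not errors", {
  m <- classification_metrics(tp = 0, fn = 0, fp = 2, tn = 8)
  expect_true(is.na(m[["sensitivity"]]))
  expect_true(is.na(m[["recall"]]))
  expect_equal(m[["accuracy"]], 0.8)
  expect_true(is.na(m[["gmean"]]))
  expect_error(classification_metrics(0, 0, 0, 0), "empty")
})

test_that("cross-validation is deterministic given the seed", {
  X <- cohort_features(tiny_cohort(n_per_class = 6, image_size = 32,
                                   n_slices = 2))
  cv1 <- cv_evaluate(X, k = 3, runs = 2, seed = 4, n_components = 5)
  cv2 <- cv_evaluate(X, k = 3, runs = 2, seed = 4, n_components = 5)
  expect_identical(cv1$summary, cv2$summary)
  expect_identical(cv1$fold_accuracy, cv2$fold_accuracy)
  expect_identical(cv1$predictions, cv2$predictions)
  cv3 <- cv_evaluate(X, k = 3, runs = 2, seed = 5, n_components = 5)
  expect_false(identical(cv1$plan$folds, cv3$plan$folds))
})

test_that("fold-averaged accuracy equals pooled accuracy on equal folds", {
  X <- cohort_features(tiny_cohort(n_per_class = 6, image_size = 32,
                                   n_slices = 2, effect_size = 0.3))
  cv <- cv_evaluate(X, k = 3, runs = 3, seed = 2, n_components = 5)
  # 12 subjects, k = 3 -> folds of exactly 4; averaging fold accuracies
  # then runs must equal the pooled per-run accuracy
  expect_equal(unname(rowMeans(cv$fold_accuracy)),
               unname(cv$run_metrics[, "accuracy"]), tolerance = 1e-12)
  expect_identical(cv$run_metrics[, "recall"], cv$run_metrics[, "sensitivity"])
  expect_true(all(cv$summary[, "mean"] >= 0 & cv$summary[, "mean"] <= 1))
})

test_that("no test-fold subject influences its own fold's model (leak test)", {
  coh <- tiny_cohort(n_per_class = 6, image_size = 32, n_slices = 2)
  X <- cohort_features(coh)
  y <- attr(X, "labels")
  pl <- make_cv_plan(ifelse(y > 0, "patient", "control"), k = 3, runs = 1,
                     seed = 11)
  fold <- pl$folds[[1]]
  te <- fold == 1
  fit1 <- wave_classifier(X[!te, , drop = FALSE], y[!te], n_components = 5)
  # poison the held-out labels: the trained model must be identical
  y2 <- y; y2[te] <- -y2[te]
  fit2 <- wave_classifier(X[!te, , drop = FALSE], y2[!te], n_components = 5)
  expect_identical(predict(fit1, X[te, , drop = FALSE]),
                   predict(fit2, X[te, , drop = FALSE]))
  expect_equal(c(fit1$tsvm$w1, fit1$tsvm$b1), c(fit2$tsvm$w1, fit2$tsvm$b1))
})

test_that("pipeline variants are reachable by flags and labelled correctly", {
  coh <- tiny_cohort(n_per_class = 5, image_size = 32, n_slices = 1)
  for (tr in c("dtcwt", "dwt")) {
    X <- cohort_features(coh, transform = tr)
    for (lda in c(TRUE, FALSE)) {
      cv <- cv_evaluate(X, k = 2, runs = 1, seed = 1, n_components = 4,
                        use_lda = lda)
      expect_equal(cv$variant,
                   paste0(toupper(tr), "+PCA", if (lda) "+LDA", "+TSVM"))
    }
  }
})

test_that("results are written as run x fold TSV and JSON summary", {
  X <- cohort_features(tiny_cohort(n_per_class = 5, image_size = 32,
                                   n_slices = 1))
  cv <- cv_evaluate(X, k = 2, runs = 2, seed = 3, n_components = 4)
  dir <- tempfile()
  paths <- write_cv_results(cv, dir)
  expect_true(all(file.exists(paths)))
  tab <- utils::read.table(paths[1], sep = "\t", header = TRUE, row.names = 1)
  expect_equal(dim(tab), c(3L, 3L))   # 2 runs + fold means, 2 folds + run mean
  js <- jsonlite::read_json(paths[2])
  expect_equal(js$variant, cv$variant)
  expect_equal(js$metrics_percent$accuracy$mean,
               100 * cv$summary["accuracy", "mean"], tolerance = 1e-10)
})
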