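test_that("fold plans are stratified partitions, reproducible from the seed", {
  labels <- setNames(rep(c(0L, 1L), each = 35), paste0("s", 1:70))
  plan <- make_fold_plan(labels, seed = 7)
  tests <- lapply(plan$outer, `[[`, "test")
  # partition: union = all subjects, pairwise disjoint
  expect_setequal(unlist(tests), names(labels))
  expect_identical(anyDuplicated(unlist(tests)), 0L)
  # exact stratification: each outer test fold has 7 + 7
  for (te in tests) {
    expect_identical(sum(labels[te] == 1L), 7L)
    expect_identical(sum(labels[te] == 0L), 7L)
  }
  # inner folds partition the outer TRAIN
  f1 <- plan$outer[[1]]
  expect_setequal(unlist(lapply(f1$inner, `[[`, "test")), f1$train)
  # reproducibility
  expect_identical(make_fold_plan(labels, seed = 7), plan)
  expect_false(identical(make_fold_plan(labels, seed = 8), plan))
  # class-ratio tolerance of +/- 1 with uneven counts
  lab2 <- setNames(c(rep(0L, 16), rep(1L, 13)), paste0("t", 1:29))
  plan2 <- make_fold_plan(lab2, seed = 1)
  for (te in lapply(plan2$outer, `[[`, "test")) {
    expect_lte(abs(sum(lab2[te] == 1L) - 13 / 5), 1)
  }
  expect_error(make_fold_plan(setNames(c(1L, 1L, 0L, 0L), letters[1:4]), 1),
               "reduce n_outer")
})

test_that("metrics satisfy their confusion-matrix identities on fuzzed inputs", {
  set.seed(51)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels <- c(0L, 1L, labels[-(1:2)])
    predicted <- rbinom(n, 1, 0.5)
    scores <- runif(n)
    m <- compute_metrics(labels, predicted, scores)
    tp <- m[["tp"]]; fp <- m[["fp"]]; tn <- m[["tn"]]; fn <- m[["fn"]]
    expect_equal(m[["accuracy"]], 100 * (tp + tn) / n)
    expect_equal(m[["sensitivity"]], 100 * tp / (tp + fn))
    expect_equal(m[["specificity"]], 100 * tn / (tn + fp))
    if (tp + fp > 0) {
      expect_equal(m[["ppv"]], 100 * tp / (tp + fp))
      expect_equal(m[["fdr"]], 100 - m[["ppv"]]) # FDR = 1 - PPV always
    }
    if (tn + fn > 0) expect_equal(m[["npv"]], 100 * tn / (tn + fn))
    expect_equal(m[["f1"]],
                 100 * 2 * tp / (2 * tp + fp + fn), tolerance = 1e-10)
  }
})

test_that("metrics match a hand-computed toy confusion matrix and AUC extremes", {
  # 6 subjects: TP=2, FN=1, TN=2, FP=1
  labels <- c(1, 1, 1, 0, 0, 0)
  predicted <- c(1, 1, 0, 0, 0, 1)
  scores <- c(0.9, 0.8, 0.4, 0.2, 0.1, 0.6)
  m <- compute_metrics(labels, predicted, scores)
  expect_equal(m[["accuracy"]], 100 * 4 / 6)
  expect_equal(m[["sensitivity"]], 100 * 2 / 3)
  expect_equal(m[["specificity"]], 100 * 2 / 3)
  expect_equal(m[["ppv"]], 100 * 2 / 3)
  expect_equal(m[["npv"]], 100 * 2 / 3)
  expect_equal(m[["fdr"]], 100 * 1 / 3)
  expect_equal(m[["f1"]], 100 * 2 / 3)
  expect_equal(m[["auc"]], 100 * 8 / 9) # one discordant pair of nine
  # all correct
  mall <- compute_metrics(labels, labels, labels)
  expect_equal(mall[["accuracy"]], 100)
  expect_equal(mall[["fdr"]], 0)
  # perfectly anti-ordered scores give AUC 0
  expect_equal(rank_auc(labels, -scores + 1), 1 - rank_auc(labels, scores))
  expect_equal(100 * rank_auc(c(1, 0), c(0, 1)), 0)
  # AUC is invariant under strictly monotone transforms of the scores
  expect_equal(rank_auc(labels, scores), rank_auc(labels, exp(3 * scores)))
})

test_that("bootstrap CIs are deterministic, degenerate when perfect, and count exclusions", {
  labels <- c(1, 1, 1, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  ci <- bootstrap_ci(labels, labels, scores, n_boot = 2000, seed = 5)
  expect_equal(ci$auc_ci, c(1, 1))
  expect_equal(ci$accuracy_ci, c(1, 1))
  expect_identical(ci, bootstrap_ci(labels, labels, scores, n_boot = 2000, seed = 5))
  # tiny minority class: one-class resamples occur and are excluded
  lab2 <- c(1, rep(0, 9))
  ci2 <- bootstrap_ci(lab2, lab2, c(0.9, runif(9, 0, 0.5)),
                      n_boot = 2000, seed = 6)
  expect_gt(ci2$n_excluded_one_class, 0)
  expect_lt(ci2$n_excluded_one_class, 2000)
})

test_that("inner grid search selects and nested CV separates a separable cohort", {
  set.seed(52)
  # perfectly separable synthetic features through the plain classifiers
  n <- 40
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- as.integer(X[, 1] > 0)
  X[, 1] <- X[, 1] + sign(X[, 1]) * 3 # wide margin
  for (fam in c("logistic", "rf")) {
    spec <- classifier_spec(fam)
    m <- fmricv:::fit_classifier(spec, fmricv:::grid_combos(spec$grid)[[1]],
                                 X, y, seed = 1)
    s <- fmricv:::predict_score(m, X)
    expect_equal(rank_auc(y, s), 1)
  }
  # grid utilities: every combination enumerated
  g <- fmricv:::grid_combos(list(a = 1:2, b = c("x", "y")))
  expect_length(g, 4L)
  expect_error(classifier_spec("lda"))
})
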