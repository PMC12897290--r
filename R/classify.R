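#' Nested stratified fold plan
#'
#' Outer `n_outer`-fold stratified partition of the subjects plus, per
#' outer fold, an inner `n_inner`-fold stratified partition of its TRAIN
#' subjects. Stratification assigns each class's shuffled members
#' round-robin, so fold class ratios differ by at most one subject.
#'
#' @param labels 0/1 integer vector named by subject id.
#' @param seed integer seed; the plan is a pure function of it.
#' @param n_outer,n_inner outer / inner fold counts.
#' @return an object of class `fold_plan`: `outer` (list of lists with
#'   `train`, `test` id vectors), each with an `inner` list of
#'   train/test splits of the outer TRAIN.
#' @export
make_fold_plan <- function(labels, seed, n_outer = 5L, n_inner = 3L) {
  stopifnot(!is.null(names(labels)), all(labels %in% c(0L, 1L)))
  if (min(table(labels)) < n_outer)
    stopf("need >= %d subjects per class for %d-fold CV; reduce n_outer in the config",
          n_outer, n_outer)
  assign_folds <- function(ids_by_class, k, seed) {
    set.seed(seed)
    fold <- stats::setNames(integer(0), character(0))
    for (ids in ids_by_class) {
      ids <- sample(ids)
      fold[ids] <- rep_len(seq_len(k), length(ids))
    }
    fold
  }
  by_class <- split(names(labels), labels)
  outer_fold <- assign_folds(by_class, n_outer, derive_seed(seed, "outer"))
  outer <- lapply(seq_len(n_outer), function(f) {
    test <- names(outer_fold)[outer_fold == f]
    train <- names(outer_fold)[outer_fold != f]
    inner_fold <- assign_folds(split(train, labels[train]), n_inner,
                               derive_seed(seed, paste0("inner", f)))
    inner <- lapply(seq_len(n_inner), function(g)
      list(train = names(inner_fold)[inner_fold != g],
           test = names(inner_fold)[inner_fold == g]))
    list(train = train, test = test, inner = inner)
  })
  structure(list(outer = outer, seed = seed, n_outer = n_outer,
                 n_inner = n_inner, labels = labels),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> outer %d-fold / inner %d-fold, %d subjects, seed %d\n",
              x$n_outer, x$n_inner, length(x$labels), x$seed))
  invisible(x)
}

#' Classifier family specification
#'
#' @param family one of `"logistic"`, `"svm"`, `"rf"`, `"xgboost"`,
#'   `"naive_bayes"`.
#' @param grid named list of hyperparameter candidate vectors; NULL uses
#'   [default_grid()] for the family.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("logistic", "svm", "rf", "xgboost",
                                       "naive_bayes"),
                            grid = NULL) {
  family <- match.arg(family)
  grid <- grid %||% default_grid(family)
  stopifnot(length(grid) >= 1L, all(lengths(grid) >= 1L))
  structure(list(family = family, grid = grid), class = "classifier_spec")
}

#' Default hyperparameter grids per classifier family
#' @param family family name.
#' @return named list of candidate vectors.
#' @export
default_grid <- function(family) {
  switch(family,
         logistic = list(lambda = c(0.01, 0.1, 1)),
         svm = list(cost = c(0.1, 1, 10)),
         rf = list(mtry_frac = c(0.1, 0.333), ntree = 200),
         xgboost = list(max_depth = c(2, 3), eta = c(0.1, 0.3), nrounds = 40),
         naive_bayes = list(laplace = 0),
         stopf("unknown classifier family '%s'", family))
}

grid_combos <- function(grid) {
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(i) as.list(combos[i, , drop = FALSE]))
}

# Fit one classifier; returns list(family, fit, params). y is 0/1.
# Scores are the continuous class-1 score: predicted probability for
# logistic / rf / xgboost / naive Bayes, decision value for svm.
fit_classifier <- function(spec, params, X, y, seed = 1L) {
  set.seed(seed)
  fit <- switch(spec$family,
    logistic = glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                              lambda = params$lambda, standardize = FALSE),
    svm = e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                     cost = params$cost, scale = FALSE),
    rf = randomForest::randomForest(
      X, factor(y, levels = c(0, 1)),
      ntree = params$ntree %||% 200,
      mtry = max(1L, floor((params$mtry_frac %||% 0.333) * ncol(X)))),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth %||% 3,
                    eta = params$eta %||% 0.3, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = params$nrounds %||% 40, verbose = 0),
    naive_bayes = e1071::naiveBayes(X, factor(y, levels = c(0, 1)),
                                    laplace = params$laplace %||% 0),
    stopf("unknown family"))
  structure(list(family = spec$family, fit = fit, params = params),
            class = "fitted_classifier")
}

# Continuous class-1 score; see fit_classifier for the per-family score.
predict_score <- function(model, X) {
  switch(model$family,
    logistic = drop(stats::predict(model$fit, X, type = "response",
                                   s = model$params$lambda)),
    svm = {
      dv <- attr(stats::predict(model$fit, X, decision.values = TRUE),
                 "decision.values")
      # e1071 orients the decision value toward its first level ("0")
      if (colnames(dv)[1L] == "0/1") -drop(dv) else drop(dv)
    },
    rf = stats::predict(model$fit, X, type = "prob")[, "1"],
    xgboost = stats::predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1)),
    naive_bayes = stats::predict(model$fit, X, type = "raw")[, "1"],
    stopf("unknown family"))
}

# decision threshold: 0.5 on probabilities, 0 on svm decision values
predict_label <- function(model, X) {
  s <- predict_score(model, X)
  thr <- if (model$family == "svm") 0 else 0.5
  as.integer(s > thr)
}

#' Rank-based AUC of scores against 0/1 labels
#' @param labels 0/1 vector.
#' @param scores numeric scores (higher = class 1).
#' @return AUC in [0, 1] (NA if one class absent).
#' @export
rank_auc <- function(labels, scores) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from pooled predictions
#'
#' All eight metrics from the pooled confusion matrix (decision
#' threshold already applied) plus rank-based AUC, as percentages.
#'
#' @param labels true 0/1 labels.
#' @param predicted predicted 0/1 labels.
#' @param scores continuous class-1 scores.
#' @return named numeric vector: accuracy, sensitivity, specificity,
#'   auc, f1, ppv, npv, fdr (percent), plus tp/fp/tn/fn counts.
#' @export
compute_metrics <- function(labels, predicted, scores) {
  stopifnot(length(labels) == length(predicted),
            length(labels) == length(scores))
  if (length(unique(labels)) < 2L)
    stopf("need at least one subject per class")
  tp <- sum(labels == 1L & predicted == 1L)
  tn <- sum(labels == 0L & predicted == 0L)
  fp <- sum(labels == 0L & predicted == 1L)
  fn <- sum(labels == 1L & predicted == 0L)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- if (!is.na(ppv) && ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else NA_real_
  c(accuracy = 100 * (tp + tn) / length(labels),
    sensitivity = 100 * sens, specificity = 100 * spec,
    auc = 100 * rank_auc(labels, scores), f1 = 100 * f1,
    ppv = 100 * ppv, npv = 100 * npv, fdr = 100 * (1 - ppv),
    tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Percentile bootstrap confidence intervals for AUC and accuracy
#'
#' Nonparametric subject-level resampling of the pooled out-of-fold
#' predictions; resamples containing only one class are excluded from
#' the AUC distribution and counted.
#'
#' @param labels,predicted,scores pooled out-of-fold vectors.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list: `auc_ci`, `accuracy_ci` (length-2), `n_boot`,
#'   `n_excluded_one_class`.
#' @export
bootstrap_ci <- function(labels, predicted, scores, n_boot = 10000L,
                         seed = 1L, conf = 0.95) {
  n <- length(labels)
  stopifnot(n >= 1L)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  acc <- rowMeans(matrix(labels[idx] == predicted[idx], n_boot, n))
  auc <- vapply(seq_len(n_boot), function(b)
    rank_auc(labels[idx[b, ]], scores[idx[b, ]]), 0)
  excl <- sum(is.na(auc))
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  list(auc_ci = unname(stats::quantile(auc, probs, na.rm = TRUE, type = 7)),
       accuracy_ci = unname(stats::quantile(acc, probs, type = 7)),
       n_boot = n_boot, n_excluded_one_class = excl)
}

# inner grid search: pooled inner out-of-fold AUC per candidate; ties
# broken by grid order
select_hyperparams <- function(spec, fm, labels, inner, seed) {
  combos <- grid_combos(spec$grid)
  if (length(combos) == 1L) return(combos[[1L]])
  aucs <- vapply(seq_along(combos), function(ci) {
    sc <- c(); lb <- c()
    for (g in seq_along(inner)) {
      tr <- inner[[g]]$train; te <- inner[[g]]$test
      if (length(unique(labels[tr])) < 2L || !length(te)) next
      m <- fit_classifier(spec, combos[[ci]], fm$x[tr, , drop = FALSE],
                          labels[tr], seed = derive_seed(seed, paste0("in", g, "c", ci)))
      sc <- c(sc, predict_score(m, fm$x[te, , drop = FALSE]))
      lb <- c(lb, labels[te])
    }
    if (length(unique(lb)) < 2L) return(NA_real_)
    rank_auc(lb, sc)
  }, 0)
  if (all(is.na(aucs))) return(combos[[1L]])
  combos[[which.max(aucs)]]
}
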