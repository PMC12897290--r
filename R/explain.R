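#' Per-column Shapley attribution magnitudes on held-out data
#'
#' Chooses the explainer by model family: exact tree-path SHAP for
#' gradient-boosted trees (xgboost's `predcontrib`), the closed-form
#' linear attribution `coef * (x - baseline)` for the linear logistic
#' model, and a permutation-sampling Shapley estimator against a single
#' baseline (the TRAIN feature mean) for the other families. The
#' sampling estimator telescopes exactly, so per-subject attributions
#' sum to `f(x) - f(baseline)` for every sampled permutation.
#'
#' @param model a `fitted_classifier`.
#' @param x_test test feature rows (matrix).
#' @param x_train TRAIN feature rows (baseline reference).
#' @param n_perm permutations per subject for the sampling estimator.
#' @param seed integer seed for permutation sampling.
#' @return numeric vector: mean over test subjects of |SHAP| per column.
#' @export
shap_on_test <- function(model, x_test, x_train, n_perm = 8L, seed = 1L) {
  phi <- shap_values(model, x_test, x_train, n_perm = n_perm, seed = seed)
  colMeans(abs(phi))
}

# per-subject signed attribution matrix (test subjects x columns)
shap_values <- function(model, x_test, x_train, n_perm = 8L, seed = 1L) {
  if (model$family == "xgboost") {
    contrib <- stats::predict(model$fit,
                              xgboost::xgb.DMatrix(x_test, nthread = 1),
                              predcontrib = TRUE)
    return(contrib[, -ncol(contrib), drop = FALSE]) # last column is the bias
  }
  if (model$family == "logistic") {
    beta <- as.matrix(stats::coef(model$fit, s = model$params$lambda))[-1L, 1L]
    base <- colMeans(x_train)
    return(sweep(sweep(x_test, 2L, base), 2L, beta, `*`))
  }
  sampling_shap(function(X) predict_score(model, X), x_test,
                baseline = colMeans(x_train), n_perm = n_perm, seed = seed)
}

# Monte-Carlo permutation Shapley against a single baseline row.
# For a permutation pi, phi_j += f(z after adding j) - f(z before);
# contributions telescope to f(x) - f(baseline) exactly.
sampling_shap <- function(f, x_test, baseline, n_perm = 8L, seed = 1L) {
  p <- ncol(x_test)
  nt <- nrow(x_test)
  set.seed(seed)
  perms <- lapply(seq_len(n_perm), function(i) sample.int(p))
  phi <- matrix(0, nt, p, dimnames = dimnames(x_test))
  for (s in seq_len(nt)) {
    x <- x_test[s, ]
    for (perm in perms) {
      # build the p+1 intermediate rows in one batch
      Z <- matrix(baseline, p + 1L, p, byrow = TRUE)
      for (j in seq_len(p)) Z[(j + 1L):(p + 1L), perm[j]] <- x[perm[j]]
      colnames(Z) <- colnames(x_test)
      fz <- f(Z)
      phi[s, perm] <- phi[s, perm] + diff(fz) / n_perm
    }
  }
  phi
}

#' Aggregate per-column attributions to ROI importance
#'
#' Per fold, column attribution magnitudes are summed within each ROI
#' (over its time-point columns) and normalized to within-fold shares;
#' shares are then averaged across the folds in which the ROI was
#' selected. Normalizing before averaging keeps high-magnitude folds
#' from dominating.
#'
#' @param fold_attr list per fold: list(`attr` = per-column mean |SHAP|,
#'   `index_map` = the fold's feature index map).
#' @param top_n optional; keep only the top-N ROIs in the table views.
#' @return an object of class `importance_table`: data.frame with `roi`,
#'   `share` (percent, renormalized to sum 100 over reported ROIs),
#'   `mean_abs_shap`, `folds_present`, sorted descending by share.
#' @export
aggregate_to_rois <- function(fold_attr, top_n = NULL) {
  stopifnot(length(fold_attr) >= 1L)
  per_fold <- lapply(fold_attr, function(fa) {
    mass <- tapply(fa$attr, fa$index_map$roi, sum)
    tot <- sum(mass)
    share <- if (tot > 0) mass / tot else mass * 0
    list(share = share, mass = mass)
  })
  rois <- unique(unlist(lapply(per_fold, function(pf) names(pf$share))))
  rows <- lapply(rois, function(r) {
    shares <- unlist(lapply(per_fold, function(pf) pf$share[r]))
    masses <- unlist(lapply(per_fold, function(pf) pf$mass[r]))
    shares <- shares[!is.na(shares)]
    data.frame(roi = r, share = 100 * mean(shares),
               mean_abs_shap = mean(masses, na.rm = TRUE),
               folds_present = length(shares))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$share), , drop = FALSE]
  # cross-fold averaging of within-fold shares need not sum to 100 when
  # ROI sets vary across folds; renormalize over all ROIs present
  tab$share <- 100 * tab$share / sum(tab$share)
  if (!is.null(top_n)) tab <- utils::head(tab, top_n)
  rownames(tab) <- NULL
  structure(tab, class = c("importance_table", "data.frame"))
}

#' @export
print.importance_table <- function(x, ...) {
  cat("<importance_table> ROI importance (share of |SHAP| mass, %)\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
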