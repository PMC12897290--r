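#' Preprocess a cohort and compute first-level contrast maps
#'
#' Runs per-subject preprocessing (FD/QC/scrubbing, nuisance regression,
#' band-pass, smoothing) and first-level GLM z-maps for the requested
#' contrasts. Subjects failing the gross-motion QC rule are dropped with
#' a message.
#'
#' @param cohort an `fmri_cohort` from [simulate_cohort()].
#' @param contrasts character names from [contrast_specs()].
#' @param fd_threshold_mm,band_hz,fwhm_mm preprocessing parameters.
#' @return an object of class `cohort_prep`: `ids`, `groups`, `bold`
#'   (preprocessed series per subject), `zmaps[[contrast]][[id]]`,
#'   `roi_ts_source` (alias of `bold`), `reports`, `atlas`, `config`.
#' @export
prepare_cohort <- function(cohort, contrasts = names(contrast_specs()),
                           fd_threshold_mm = 0.2, band_hz = c(0.01, 0.10),
                           fwhm_mm = 4) {
  specs <- contrast_specs()
  bad <- setdiff(contrasts, names(specs))
  if (length(bad)) stopf("unknown contrast(s): %s", paste(bad, collapse = ", "))
  atlas <- cohort$atlas
  bold <- list(); reports <- list()
  zmaps <- stats::setNames(vector("list", length(contrasts)), contrasts)
  for (s in cohort$subjects) {
    pp <- preprocess_subject(s, atlas, fd_threshold_mm, band_hz, fwhm_mm)
    if (pp$report$excluded) {
      message(sprintf("excluding %s: %s", s$id, pp$report$reason))
      next
    }
    bold[[s$id]] <- pp$bold
    reports[[s$id]] <- pp$report
    design <- first_level_design(s$events, pp$bold$tr_s, n_volumes(pp$bold),
                                 cohort$config$conditions)
    for (cn in contrasts)
      zmaps[[cn]][[s$id]] <- suppressMessages(
        first_level_zmap(pp$bold, design, specs[[cn]], contrast_name = cn))
  }
  groups <- vapply(cohort$subjects[names(bold)], `[[`, "", "group")
  structure(list(ids = names(bold), groups = groups, bold = bold,
                 zmaps = zmaps, reports = reports, atlas = atlas,
                 config = cohort$config),
            class = "cohort_prep")
}

#' Nested cross-validated classification with fold-internal features
#'
#' For each outer fold: abnormal ROIs are defined from TRAIN subjects'
#' first-level maps only (ROI-defining patients vs controls), ROI-mean
#' time-series features are built and scaled on TRAIN, an inner
#' stratified grid search (maximizing inner out-of-fold AUC) selects
#' hyperparameters, the model is refit on the full TRAIN and evaluated
#' on TEST. Pooled out-of-fold predictions feed the metrics and the
#' bootstrap intervals. Folds with an empty ROI set (K = 0) are skipped
#' and counted.
#'
#' @param prep a [prepare_cohort()] result.
#' @param contrast contrast name.
#' @param labels named 0/1 vector over the subjects to classify
#'   (1 = patient).
#' @param plan a [make_fold_plan()] over those subjects.
#' @param classifiers list of [classifier_spec()]s (or a single spec).
#' @param roi_patient_ids,roi_control_ids subject pools whose TRAIN
#'   members define the fold's abnormal ROIs; default: the labeled
#'   patients / controls themselves (state-specific mode). Pooled
#'   generalization passes a single mood-state subgroup as
#'   `roi_patient_ids`.
#' @param rft voxel/cluster thresholds, a list with `voxel_p`,
#'   `cluster_p`, `min_extent`, `min_overlap`.
#' @param n_boot bootstrap resamples for the 95% intervals.
#' @param compute_shap logical; also compute per-fold held-out SHAP and
#'   the aggregated ROI importance table.
#' @param seed integer seed for classifier fitting, bootstrap and SHAP.
#' @return a named list (one `evaluation_report` per classifier family).
#' @export
run_nested_cv <- function(prep, contrast, labels, plan, classifiers,
                          roi_patient_ids = NULL, roi_control_ids = NULL,
                          rft = list(), n_boot = 10000L,
                          compute_shap = FALSE, seed = 1L) {
  if (inherits(classifiers, "classifier_spec")) classifiers <- list(classifiers)
  names(classifiers) <- vapply(classifiers, `[[`, "", "family")
  rft <- utils::modifyList(list(voxel_p = 0.001, cluster_p = 0.05,
                                min_extent = 10L, min_overlap = 10L), rft)
  if (!contrast %in% names(prep$zmaps)) stopf("contrast '%s' not prepared", contrast)
  maps <- prep$zmaps[[contrast]]
  ids <- names(labels)
  stopifnot(all(ids %in% prep$ids))
  roi_patient_ids <- roi_patient_ids %||% ids[labels == 1L]
  roi_control_ids <- roi_control_ids %||% ids[labels == 0L]
  per_clf <- lapply(classifiers, function(cs)
    list(pred = data.frame(), folds = list(), shap = list()))
  skipped <- 0L
  fold_log <- list()
  for (f in seq_along(plan$outer)) {
    fold <- plan$outer[[f]]
    rois <- define_abnormal_rois(
      maps[intersect(fold$train, roi_patient_ids)],
      maps[intersect(fold$train, roi_control_ids)],
      prep$atlas, voxel_p = rft$voxel_p, cluster_p = rft$cluster_p,
      min_extent = rft$min_extent, min_overlap = rft$min_overlap,
      fold_id = f)
    if (rois$k == 0L) {
      skipped <- skipped + 1L
      fold_log[[f]] <- list(fold = f, k = 0L, skipped = TRUE)
      message(sprintf("fold %d: empty abnormal-ROI set, skipping", f))
      next
    }
    ts_of <- function(id) extract_roi_timeseries(prep$bold[[id]], rois)
    train_ts <- stats::setNames(lapply(fold$train, ts_of), fold$train)
    test_ts <- stats::setNames(lapply(fold$test, ts_of), fold$test)
    fm <- build_feature_matrix(train_ts, test_ts)
    fold_log[[f]] <- list(fold = f, k = rois$k, t_use = fm$t_use,
                          rois = rois$roi_table$name, skipped = FALSE)
    for (cf in names(classifiers)) {
      spec <- classifiers[[cf]]
      params <- select_hyperparams(spec, fm, labels, fold$inner,
                                   seed = derive_seed(seed, paste0(cf, "f", f)))
      model <- tryCatch(
        fit_classifier(spec, params, fm$x[fold$train, , drop = FALSE],
                       labels[fold$train],
                       seed = derive_seed(seed, paste0("fit", cf, "f", f))),
        error = function(e) e)
      if (inherits(model, "error")) {
        warning(sprintf("fold %d %s: fit failed (%s)", f, cf,
                        conditionMessage(model)), call. = FALSE)
        per_clf[[cf]]$folds[[f]] <- list(fold = f, failed = TRUE)
        next
      }
      Xte <- fm$x[fold$test, , drop = FALSE]
      pred <- data.frame(id = fold$test, fold = f,
                         label = unname(labels[fold$test]),
                         score = unname(predict_score(model, Xte)),
                         predicted = unname(predict_label(model, Xte)))
      per_clf[[cf]]$pred <- rbind(per_clf[[cf]]$pred, pred)
      per_clf[[cf]]$folds[[f]] <-
        list(fold = f, failed = FALSE, params = params,
             accuracy = 100 * mean(pred$label == pred$predicted))
      if (compute_shap) {
        attr_vec <- tryCatch(
          shap_on_test(model, Xte, fm$x[fold$train, , drop = FALSE],
                       seed = derive_seed(seed, paste0("shap", cf, "f", f))),
          error = function(e) NULL)
        if (!is.null(attr_vec))
          per_clf[[cf]]$shap[[length(per_clf[[cf]]$shap) + 1L]] <-
            list(attr = attr_vec, index_map = fm$index_map)
      }
    }
  }
  out <- lapply(names(classifiers), function(cf) {
    pred <- per_clf[[cf]]$pred
    if (nrow(pred) == 0L)
      return(structure(list(classifier = cf, contrast = contrast,
                            metrics = NULL, predictions = pred,
                            skipped_folds = skipped, fold_log = fold_log),
                       class = "evaluation_report"))
    metrics <- compute_metrics(pred$label, pred$predicted, pred$score)
    ci <- if (n_boot > 0)
      bootstrap_ci(pred$label, pred$predicted, pred$score,
                   n_boot = n_boot, seed = derive_seed(seed, paste0("boot", cf)))
    imp <- NULL
    if (compute_shap && length(per_clf[[cf]]$shap))
      imp <- aggregate_to_rois(per_clf[[cf]]$shap)
    structure(list(classifier = cf, contrast = contrast, metrics = metrics,
                   predictions = pred, ci = ci, importance = imp,
                   per_fold = per_clf[[cf]]$folds, skipped_folds = skipped,
                   fold_log = fold_log),
              class = "evaluation_report")
  })
  stats::setNames(out, names(classifiers))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s / %s", x$contrast, x$classifier))
  if (is.null(x$metrics)) {
    cat(" - no completed folds\n")
    return(invisible(x))
  }
  m <- x$metrics
  cat(sprintf(": accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.2f%%, F1 %.2f%%\n",
              m["accuracy"], m["sensitivity"], m["specificity"], m["auc"], m["f1"]))
  if (!is.null(x$ci))
    cat(sprintf("  95%% CI: AUC [%.3f, %.3f], accuracy [%.3f, %.3f] (%d resamples, %d one-class excluded)\n",
                x$ci$auc_ci[1], x$ci$auc_ci[2], x$ci$accuracy_ci[1],
                x$ci$accuracy_ci[2], x$ci$n_boot, x$ci$n_excluded_one_class))
  if (x$skipped_folds)
    cat(sprintf("  %d fold(s) skipped (empty ROI set)\n", x$skipped_folds))
  invisible(x)
}

#' @export
summary.evaluation_report <- function(object, ...) {
  print(object)
  if (!is.null(object$importance)) print(object$importance)
  invisible(object)
}

#' Flatten evaluation reports into a results table
#'
#' One row per (contrast, classifier), mirroring the layout of a
#' per-condition results table: accuracy, sensitivity, specificity, AUC
#' and F1 in percent.
#'
#' @param reports list of `evaluation_report`s (possibly nested by
#'   contrast).
#' @return data.frame.
#' @export
report_table <- function(reports) {
  flat <- list()
  collect <- function(x) {
    if (inherits(x, "evaluation_report")) flat[[length(flat) + 1L]] <<- x
    else if (is.list(x)) lapply(x, collect)
    invisible(NULL)
  }
  collect(reports)
  rows <- lapply(flat, function(r) {
    if (is.null(r$metrics)) return(NULL)
    data.frame(contrast = r$contrast, classifier = r$classifier,
               accuracy = r$metrics[["accuracy"]],
               sensitivity = r$metrics[["sensitivity"]],
               specificity = r$metrics[["specificity"]],
               auc = r$metrics[["auc"]], f1 = r$metrics[["f1"]],
               ppv = r$metrics[["ppv"]], npv = r$metrics[["npv"]],
               fdr = r$metrics[["fdr"]],
               skipped_folds = r$skipped_folds)
  })
  do.call(rbind, rows)
}
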