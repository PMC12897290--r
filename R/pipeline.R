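#' End-to-end run configuration
#'
#' Aggregates every pipeline parameter with the study defaults: voxel
#' p 0.001, cluster p 0.05, minimum extent 10 voxels, FD scrub threshold
#' 0.2 mm, outer 5-fold / inner 3-fold CV, 10,000 bootstrap resamples.
#' Every default is overridable.
#'
#' @param sim a [sim_config()] describing the synthetic cohort.
#' @param group_sizes named integer vector of subjects per group.
#' @param contrasts contrast names to analyse.
#' @param state mood-state subgroup for state-specific classification /
#'   ROI sourcing.
#' @param classifiers character vector of classifier families.
#' @param n_outer,n_inner fold counts.
#' @param n_boot bootstrap resamples.
#' @param rft list of GRF thresholds (`voxel_p`, `cluster_p`,
#'   `min_extent`, `min_overlap`).
#' @param fd_threshold_mm,band_hz,fwhm_mm preprocessing parameters.
#' @param compute_shap compute held-out SHAP importance.
#' @param seed master seed for the whole run.
#' @param output_dir optional directory for result tables + manifest.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       group_sizes = default_group_sizes(),
                       contrasts = names(contrast_specs()),
                       state = "remission",
                       classifiers = c("logistic", "svm", "rf", "xgboost",
                                       "naive_bayes"),
                       n_outer = 5L, n_inner = 3L, n_boot = 10000L,
                       rft = list(voxel_p = 0.001, cluster_p = 0.05,
                                  min_extent = 10L, min_overlap = 10L),
                       fd_threshold_mm = 0.2, band_hz = c(0.01, 0.10),
                       fwhm_mm = 4, compute_shap = FALSE, seed = 1L,
                       output_dir = NULL) {
  bad <- setdiff(contrasts, names(contrast_specs()))
  if (length(bad)) stopf("unknown contrast(s): %s", paste(bad, collapse = ", "))
  if (!state %in% bd_groups())
    stopf("unknown mood state '%s'", state)
  bad_clf <- setdiff(classifiers, c("logistic", "svm", "rf", "xgboost",
                                    "naive_bayes"))
  if (length(bad_clf)) stopf("unknown classifier(s): %s", paste(bad_clf, collapse = ", "))
  structure(list(sim = sim, group_sizes = group_sizes,
                 contrasts = contrasts, state = state,
                 classifiers = classifiers, n_outer = n_outer,
                 n_inner = n_inner, n_boot = n_boot, rft = rft,
                 fd_threshold_mm = fd_threshold_mm, band_hz = band_hz,
                 fwhm_mm = fwhm_mm, compute_shap = compute_shap,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

config_hash <- function(config) {
  fnv_hash(paste(utils::capture.output(utils::str(config)), collapse = "\n"))
}

write_manifest <- function(config, dir, extra = list()) {
  manifest <- c(list(config_hash = config_hash(config), seed = config$seed,
                     timestamp_free = TRUE,
                     package_version = as.character(utils::packageVersion("fmricv"))),
                extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

prepare_from_config <- function(config, extra_groups = character()) {
  sim <- config$sim
  sim$seed <- derive_seed(config$seed, "cohort")
  wanted <- unique(c(config$state, "HC", extra_groups))
  sizes <- config$group_sizes[intersect(names(config$group_sizes), wanted)]
  cohort <- simulate_cohort(sim, sizes)
  prep <- prepare_cohort(cohort, config$contrasts, config$fd_threshold_mm,
                         config$band_hz, config$fwhm_mm)
  list(cohort = cohort, prep = prep)
}

run_cv_over_contrasts <- function(config, prep, labels, roi_patient_ids,
                                  roi_control_ids) {
  specs <- lapply(config$classifiers, classifier_spec)
  plan <- make_fold_plan(labels, derive_seed(config$seed, "folds"),
                         config$n_outer, config$n_inner)
  out <- list()
  for (cn in config$contrasts) {
    out[[cn]] <- run_nested_cv(prep, cn, labels, plan, specs,
                               roi_patient_ids = roi_patient_ids,
                               roi_control_ids = roi_control_ids,
                               rft = config$rft, n_boot = config$n_boot,
                               compute_shap = config$compute_shap,
                               seed = derive_seed(config$seed, paste0("cv:", cn)))
  }
  out
}

finalize_run <- function(config, reports, mode, extra = list()) {
  tab <- report_table(reports)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(tab, file.path(config$output_dir,
                                      paste0("results_", mode, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(config, config$output_dir, c(list(mode = mode), extra))
  }
  structure(list(reports = reports, table = tab, config = config,
                 mode = mode), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> mode '%s', %d report row(s)\n", x$mode,
              nrow(x$table %||% data.frame())))
  if (!is.null(x$table)) print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' State-specific classification run
#'
#' Simulates the configured cohort (state subgroup + controls),
#' preprocesses it, and runs the leakage-controlled nested CV for every
#' configured contrast and classifier: mood-state patients versus
#' controls, with fold-internal ROI definition from the same subjects.
#'
#' @param config a [run_config()].
#' @return a `pipeline_result` with per-(contrast, classifier) reports
#'   and a flat results table.
#' @export
run_state_specific <- function(config) {
  pc <- prepare_from_config(config)
  groups <- pc$prep$groups
  ids <- pc$prep$ids[groups %in% c(config$state, "HC")]
  labels <- stats::setNames(as.integer(groups[ids] == config$state), ids)
  reports <- run_cv_over_contrasts(config, pc$prep, labels,
                                   roi_patient_ids = ids[labels == 1L],
                                   roi_control_ids = ids[labels == 0L])
  finalize_run(config, reports, "state_specific",
               list(state = config$state))
}

#' Pooled BD-versus-control generalization run
#'
#' ROIs and features are defined, per fold, from the designated mood
#' state's TRAIN subjects and TRAIN controls only, but the classifier is
#' trained and evaluated on pooled patients (all three mood states)
#' versus controls, under the same leakage constraints.
#'
#' @param config a [run_config()]; `config$state` names the ROI-sourcing
#'   state.
#' @return a `pipeline_result`; the manifest records the sourcing state.
#' @export
run_pooled_generalization <- function(config) {
  pc <- prepare_from_config(config, extra_groups = bd_groups())
  groups <- pc$prep$groups
  present <- intersect(bd_groups(), unique(groups))
  if (length(present) < 3L)
    stopf("pooled generalization needs all three mood-state subgroups (have: %s)",
          paste(present, collapse = ", "))
  ids <- pc$prep$ids
  labels <- stats::setNames(as.integer(groups[ids] != "HC"), ids)
  reports <- run_cv_over_contrasts(
    config, pc$prep, labels,
    roi_patient_ids = ids[groups[ids] == config$state],
    roi_control_ids = ids[groups[ids] == "HC"])
  finalize_run(config, reports, "pooled_generalization",
               list(roi_source_state = config$state))
}
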