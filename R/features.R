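#' Define fold-specific abnormal ROIs from TRAIN subjects only
#'
#' Computes a TRAIN-only second-level group-contrast z-map (patients vs
#' controls), derives the GRF-corrected abnormal voxel mask, intersects
#' it with the atlas, and keeps regions overlapping by at least
#' `min_overlap` voxels. The identities of the TRAIN subjects are hashed
#' into the result for leakage auditing.
#'
#' @param patient_maps,control_maps lists of first-level [stat_map()]s of
#'   TRAIN patients / TRAIN controls.
#' @param atlas an `fmri_atlas`.
#' @param voxel_p,cluster_p,min_extent GRF thresholds
#'   (see [grf_cluster_correct()]).
#' @param min_overlap minimum mask-region overlap in voxels.
#' @param fold_id optional fold label recorded in the result.
#' @return an object of class `abnormal_roi_set`: `roi_table` (label,
#'   name, overlap; ascending label), `voxels` (list of mask-intersected
#'   voxel index vectors per kept region), `k`, `mask`, `source`.
#'   `k = 0` when the mask is empty; callers skip such folds.
#' @export
define_abnormal_rois <- function(patient_maps, control_maps, atlas,
                                 voxel_p = 0.001, cluster_p = 0.05,
                                 min_extent = 10L, min_overlap = 10L,
                                 fold_id = NA) {
  zmap <- second_level_zmap(patient_maps, control_maps)
  sm <- estimate_smoothness(attr(zmap, "residuals"))
  cs <- grf_cluster_correct(zmap, sm, voxel_p = voxel_p,
                            cluster_p = cluster_p, min_extent = min_extent)
  labvec <- as.vector(atlas$labels)
  mask_idx <- which(cs$mask)
  keep <- list()
  rows <- list()
  for (r in seq_along(atlas$names)) {
    inter <- mask_idx[labvec[mask_idx] == r]
    if (length(inter) >= min_overlap) {
      keep[[length(keep) + 1L]] <- inter
      rows[[length(rows) + 1L]] <-
        data.frame(label = r, name = atlas$names[r], overlap = length(inter))
    }
  }
  roi_table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(), name = character(), overlap = integer())
  src <- list(contrast = zmap$contrast, fold_id = fold_id,
              train_hash = fnv_hash(paste(
                c(names(patient_maps) %||% "", names(control_maps) %||% ""),
                collapse = "|")))
  structure(list(roi_table = roi_table, voxels = keep,
                 k = nrow(roi_table), mask = cs$mask,
                 cluster_set = cs, source = src),
            class = "abnormal_roi_set")
}

#' @export
print.abnormal_roi_set <- function(x, ...) {
  cat(sprintf("<abnormal_roi_set> K = %d region(s), contrast '%s'\n",
              x$k, x$source$contrast))
  if (x$k) print(x$roi_table, row.names = FALSE)
  invisible(x)
}

#' Extract ROI-mean time series
#'
#' Column k is the mean over ROI k's mask-intersected voxel set at each
#' time point, in the ROI order of the set (ascending atlas label).
#'
#' @param bold a preprocessed [volume_series()].
#' @param rois an [define_abnormal_rois()] result with `k >= 1`.
#' @return numeric matrix, time points x K.
#' @export
extract_roi_timeseries <- function(bold, rois) {
  if (rois$k == 0L) stopf("abnormal ROI set is empty (K = 0)")
  d <- dim(bold$data)
  Y <- matrix(bold$data, prod(d[1:3]), d[4L])
  out <- vapply(rois$voxels, function(vox) {
    if (!length(vox)) stopf("ROI with zero voxels on this grid")
    colMeans(Y[vox, , drop = FALSE])
  }, numeric(d[4L]))
  colnames(out) <- rois$roi_table$name
  out
}

#' Build the leakage-free vectorized feature matrix
#'
#' Truncates every subject's ROI time-series matrix to the first
#' `t_use = min` over TRAIN subjects' available time points, vectorizes
#' ROI-major (all `t_use` time points of ROI 1, then ROI 2, ...), and
#' z-standardizes each column with center/scale fitted on TRAIN rows
#' only.
#'
#' @param train_ts named list (TRAIN subject id -> Ti x K matrix).
#' @param test_ts named list (TEST subject id -> Ti x K matrix).
#' @return an object of class `feature_matrix`: `x` (subjects x
#'   `t_use * K`), `train_ids`, `test_ids`, `t_use`, `k`,
#'   `scaler_params` (center/scale per column), `index_map` (data.frame
#'   column, roi, timepoint).
#' @export
build_feature_matrix <- function(train_ts, test_ts = list()) {
  stopifnot(length(train_ts) >= 1L)
  k <- ncol(train_ts[[1L]])
  all_ts <- c(train_ts, test_ts)
  if (!all(vapply(all_ts, ncol, 0L) == k)) stopf("inconsistent K across subjects")
  t_use <- min(vapply(train_ts, nrow, 0L))
  short <- vapply(test_ts, nrow, 0L) < t_use
  if (any(short))
    stopf("TEST subject(s) %s have fewer than t_use = %d time points",
          paste(names(test_ts)[short], collapse = ", "), t_use)
  vec <- function(m) as.vector(m[seq_len(t_use), , drop = FALSE]) # ROI-major
  X <- t(vapply(all_ts, vec, numeric(t_use * k)))
  rownames(X) <- names(all_ts)
  train_rows <- seq_along(train_ts)
  center <- colMeans(X[train_rows, , drop = FALSE])
  scale_ <- apply(X[train_rows, , drop = FALSE], 2L, stats::sd)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale_, `/`)
  roi_names <- colnames(train_ts[[1L]]) %||% paste0("roi", seq_len(k))
  index_map <- data.frame(column = seq_len(t_use * k),
                          roi = rep(roi_names, each = t_use),
                          timepoint = rep(seq_len(t_use), k))
  structure(list(x = Xs, train_ids = names(train_ts),
                 test_ids = names(test_ts), t_use = t_use, k = k,
                 scaler_params = list(center = center, scale = scale_),
                 index_map = index_map),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d train + %d test subjects, K = %d ROIs x t_use = %d -> %d columns\n",
              length(x$train_ids), length(x$test_ids), x$k, x$t_use,
              ncol(x$x)))
  invisible(x)
}

#' Invert a feature-column index to its (roi, timepoint) pair
#'
#' @param fm a [build_feature_matrix()] result.
#' @param column integer column id(s).
#' @return data.frame rows of the index map.
#' @export
feature_column_info <- function(fm, column) {
  fm$index_map[match(column, fm$index_map$column), , drop = FALSE]
}
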