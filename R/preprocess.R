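#' Jenkinson framewise displacement
#'
#' Root-mean-square displacement between consecutive rigid-body
#' transforms, integrated over a sphere of radius 80 mm (the method's
#' canonical constant) centered at the volume center. Rotations are taken
#' about the sphere center, so for transform difference
#' \eqn{M = T_t T_{t-1}^{-1} - I} partitioned into linear part A and
#' translation b, \eqn{FD = \sqrt{R^2/5\,tr(A^T A) + b^T b}}.
#'
#' @param motion numeric matrix, volumes x 6: three translations (mm)
#'   then three rotations (radians).
#' @param radius_mm sphere radius (mm).
#' @return nonnegative numeric vector of per-volume FD (mm); FD[1] = 0.
#' @export
framewise_displacement <- function(motion, radius_mm = 80) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L) stopf("need at least 2 volumes for FD")
  if (ncol(motion) != 6L) stopf("motion trace must have 6 columns")
  if (!all(is.finite(motion))) stopf("non-finite motion parameters")
  Ts <- lapply(seq_len(nrow(motion)), function(t) rigid_transform(motion[t, ]))
  fd <- numeric(nrow(motion))
  for (t in 2:nrow(motion)) {
    M <- Ts[[t]] %*% solve(Ts[[t - 1L]]) - diag(4)
    A <- M[1:3, 1:3]
    b <- M[1:3, 4]
    fd[t] <- sqrt(radius_mm^2 / 5 * sum(A * A) + sum(b * b))
  }
  fd
}

# 4x4 rigid transform from 6 parameters (tx,ty,tz in mm; rx,ry,rz rad),
# rotation order Rx %*% Ry %*% Rz, about the volume/sphere center.
rigid_transform <- function(p) {
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  tf <- diag(4)
  tf[1:3, 1:3] <- Rx %*% Ry %*% Rz
  tf[1:3, 4] <- p[1:3]
  tf
}

#' Gross-motion exclusion rule
#'
#' A subject is excluded when any translation magnitude exceeds 3 mm or
#' any rotation magnitude exceeds 3 degrees (strict inequalities).
#'
#' @param motion volumes x 6 matrix (mm, radians).
#' @param max_translation_mm translation limit (mm).
#' @param max_rotation_deg rotation limit (degrees).
#' @return list with `excluded` (logical) and `reason` (string or NA)
#'   naming the offending parameter and volume.
#' @export
qc_exclude <- function(motion, max_translation_mm = 3, max_rotation_deg = 3) {
  motion <- as.matrix(motion)
  trans <- abs(motion[, 1:3, drop = FALSE])
  rot_deg <- abs(motion[, 4:6, drop = FALSE]) * 180 / pi
  if (any(trans > max_translation_mm)) {
    w <- which(trans > max_translation_mm, arr.ind = TRUE)[1L, ]
    return(list(excluded = TRUE,
                reason = sprintf("translation %d (%.2f mm) at volume %d exceeds %g mm",
                                 w[2L], trans[w[1L], w[2L]], w[1L], max_translation_mm)))
  }
  if (any(rot_deg > max_rotation_deg)) {
    w <- which(rot_deg > max_rotation_deg, arr.ind = TRUE)[1L, ]
    return(list(excluded = TRUE,
                reason = sprintf("rotation %d (%.2f deg) at volume %d exceeds %g deg",
                                 w[2L], rot_deg[w[1L], w[2L]], w[1L], max_rotation_deg)))
  }
  list(excluded = FALSE, reason = NA_character_)
}

#' Volumes to scrub by framewise displacement
#'
#' @param fd_series per-volume FD (mm).
#' @param threshold_mm scrub threshold; volumes with FD strictly greater
#'   are flagged.
#' @return integer vector of volume indices (possibly empty).
#' @export
scrub_mask <- function(fd_series, threshold_mm = 0.2) {
  which(fd_series > threshold_mm)
}

#' Build the nuisance design matrix
#'
#' Friston-24 motion set (parameters, their squares, one-volume lags and
#' squared lags, with the lag at the first volume set to 0), white-matter
#' and CSF mean signals, a standardized linear trend, and one one-hot
#' spike column per scrubbed volume.
#'
#' @param motion volumes x 6 matrix.
#' @param wm,csf numeric nuisance compartment mean series.
#' @param scrubbed integer indices of scrubbed volumes.
#' @return numeric matrix with named columns (27 + number scrubbed).
#' @export
build_nuisance <- function(motion, wm, csf, scrubbed = integer()) {
  motion <- as.matrix(motion)
  n <- nrow(motion)
  if (length(wm) != n || length(csf) != n)
    stopf("wm/csf length (%d/%d) must match motion rows (%d)",
          length(wm), length(csf), n)
  lag <- rbind(0, motion[-n, , drop = FALSE])
  fr24 <- cbind(motion, motion^2, lag, lag^2)
  colnames(fr24) <- c(paste0("mp", 1:6), paste0("mp", 1:6, "_sq"),
                      paste0("mp", 1:6, "_lag"), paste0("mp", 1:6, "_lagsq"))
  trend <- seq_len(n) - 1
  trend <- (trend - mean(trend)) / stats::sd(trend)
  X <- cbind(fr24, wm = wm, csf = csf, trend = trend)
  if (length(scrubbed)) {
    spikes <- matrix(0, n, length(scrubbed))
    spikes[cbind(scrubbed, seq_along(scrubbed))] <- 1
    colnames(spikes) <- paste0("spike_", scrubbed)
    X <- cbind(X, spikes)
  }
  X
}

# residualize Y (n x v) against [1 X], dropping dependent columns with a
# warning; returns residuals + column means (so the mean can be restored)
residualize <- function(Y, X) {
  n <- nrow(Y)
  Xf <- cbind(intercept = rep(1, n), X)
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    dropped <- colnames(Xf)[qrX$pivot[(qrX$rank + 1L):ncol(Xf)]]
    warning(sprintf("rank-deficient nuisance design: dropping %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  Y - qr.fitted(qrX, Y)
}

# hard frequency-domain band-pass on the columns of a (time x series) matrix
bandpass_matrix <- function(Y, tr_s, band_hz) {
  n <- nrow(Y)
  freq <- (seq_len(n) - 1L) / (n * tr_s)
  freq <- pmin(freq, 1 / tr_s - freq)   # two-sided bin frequencies
  keep <- freq >= band_hz[1L] - 1e-12 & freq <= band_hz[2L] + 1e-12
  F <- stats::mvfft(Y)
  F[!keep, ] <- 0
  Re(stats::mvfft(F, inverse = TRUE)) / n
}

#' Nuisance regression, band-pass filtering and spatial smoothing
#'
#' Per voxel: residualize the series against the nuisance design (least
#' squares with intercept), band-pass within `band_hz` by hard
#' frequency-domain masking, restore the voxel mean, then smooth each 3D
#' frame with a Gaussian kernel of FWHM `fwhm_mm`.
#'
#' @param bold a [volume_series()].
#' @param design nuisance matrix from [build_nuisance()] (rows = volumes).
#' @param band_hz length-2 passband in Hz.
#' @param fwhm_mm spatial smoothing FWHM in mm.
#' @return a [volume_series()] of the same shape.
#' @export
regress_filter_smooth <- function(bold, design, band_hz = c(0.01, 0.10),
                                  fwhm_mm = 4) {
  d <- dim(bold$data)
  n <- d[4L]
  if (nrow(design) != n)
    stopf("design rows (%d) != volumes (%d)", nrow(design), n)
  Y <- t(matrix(bold$data, prod(d[1:3]), n))  # time x voxel
  mu <- colMeans(Y)
  R <- residualize(Y, design)
  R <- bandpass_matrix(R, bold$tr_s, band_hz)
  R <- sweep(R, 2L, mu, `+`)
  out <- array(t(R), d)
  if (fwhm_mm > 0) {
    sigma <- fwhm_to_sigma(fwhm_mm) / bold$voxel_size_mm
    tr <- smooth_transfer(d[1:3], sigma)
    for (t in seq_len(n))
      out[, , , t] <- gaussian_smooth_3d(out[, , , t], transfer = tr)
  }
  volume_series(out, bold$voxel_size_mm, bold$tr_s)
}

#' Full per-subject preprocessing
#'
#' Computes FD, the gross-motion exclusion flag, the scrub set, the
#' nuisance design (with WM/CSF means taken from the atlas's designated
#' background compartments), and the cleaned, filtered, smoothed BOLD.
#'
#' @param subject a `subject_record`.
#' @param atlas an `fmri_atlas` (provides WM/CSF reference voxels).
#' @param fd_threshold_mm scrub threshold.
#' @param band_hz temporal passband.
#' @param fwhm_mm smoothing kernel FWHM.
#' @return list with `bold` (preprocessed volume_series) and `report`
#'   (class `preproc_report`: fd_series, scrubbed_volumes, excluded,
#'   reason, params_used).
#' @export
preprocess_subject <- function(subject, atlas, fd_threshold_mm = 0.2,
                               band_hz = c(0.01, 0.10), fwhm_mm = 4) {
  fd <- framewise_displacement(subject$motion)
  qc <- qc_exclude(subject$motion)
  scrubbed <- scrub_mask(fd, fd_threshold_mm)
  Y <- t(matrix(subject$bold$data, , n_volumes(subject$bold)))
  wm <- rowMeans(Y[, atlas$wm_voxels, drop = FALSE])
  csf <- rowMeans(Y[, atlas$csf_voxels, drop = FALSE])
  design <- build_nuisance(subject$motion, wm, csf, scrubbed)
  cleaned <- regress_filter_smooth(subject$bold, design, band_hz, fwhm_mm)
  report <- structure(list(id = subject$id, fd_series = fd,
                           scrubbed_volumes = scrubbed,
                           excluded = qc$excluded, reason = qc$reason,
                           params_used = list(fd_threshold_mm = fd_threshold_mm,
                                              band_hz = band_hz,
                                              fwhm_mm = fwhm_mm)),
                      class = "preproc_report")
  list(bold = cleaned, report = report)
}

#' @export
print.preproc_report <- function(x, ...) {
  cat(sprintf("<preproc_report> %s: max FD %.3f mm, %d scrubbed, excluded: %s\n",
              x$id, max(x$fd_series), length(x$scrubbed_volumes),
              ifelse(x$excluded, x$reason, "no")))
  invisible(x)
}
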