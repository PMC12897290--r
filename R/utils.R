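#' @keywords internal
"_PACKAGE"

# 32-bit string hash (FNV-1a style, reduced mod 2^31 so it stays an R integer)
fnv_hash <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

#' Derive a stage-specific RNG seed from a base seed
#'
#' A single user-facing seed governs every stochastic stage (cohort
#' generation, fold assignment, classifier fitting, bootstrap, Shapley
#' sampling). Each stage mixes the base seed with a stage tag so that
#' stages draw from independent streams while the whole run stays a pure
#' function of one integer.
#'
#' @param seed integer base seed.
#' @param tag character stage tag, e.g. `"folds"`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  as.integer((as.double(seed) * 48271 + fnv_hash(tag)) %% 2147483646) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# linear index <-> (i,j,k) for a 3D grid, 1-based
coords_to_index <- function(ijk, dim) {
  (ijk[, 3] - 1L) * dim[1L] * dim[2L] + (ijk[, 2] - 1L) * dim[1L] + ijk[, 1L]
}

index_to_coords <- function(idx, dim) {
  idx0 <- idx - 1L
  i <- idx0 %% dim[1L]
  j <- (idx0 %/% dim[1L]) %% dim[2L]
  k <- idx0 %/% (dim[1L] * dim[2L])
  cbind(i + 1L, j + 1L, k + 1L)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Per-axis circular Gaussian kernel (normalised to sum 1); sigma in voxels.
circular_gauss_kernel <- function(n, sigma) {
  if (sigma <= 0) {
    k <- numeric(n)
    k[1L] <- 1
    return(k)
  }
  d <- seq_len(n) - 1L
  d <- pmin(d, n - d) # circular distance to 0
  k <- exp(-d^2 / (2 * sigma^2))
  k / sum(k)
}

# Transfer function (FFT of the separable 3D kernel) for repeated use.
smooth_transfer <- function(dim, sigma_vox) {
  sigma_vox <- rep(sigma_vox, length.out = 3L)
  k1 <- stats::fft(circular_gauss_kernel(dim[1L], sigma_vox[1L]))
  k2 <- stats::fft(circular_gauss_kernel(dim[2L], sigma_vox[2L]))
  k3 <- stats::fft(circular_gauss_kernel(dim[3L], sigma_vox[3L]))
  outer(outer(k1, k2), k3)
}

#' Smooth a 3D volume with an isotropic Gaussian kernel
#'
#' Separable circular (FFT) convolution. Circular convolution conserves
#' the frame mean exactly (the kernel has unit DC gain); the wrap-around
#' at the faces is acceptable for the synthetic grids used here.
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm kernel full width at half maximum in mm.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param transfer optional precomputed transfer array from
#'   `smooth_transfer()`; overrides `fwhm_mm`.
#' @return smoothed array, same shape.
#' @export
gaussian_smooth_3d <- function(vol, fwhm_mm, voxel_size_mm = 1, transfer = NULL) {
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  if (is.null(transfer)) {
    sigma <- fwhm_to_sigma(fwhm_mm) / voxel_size_mm
    if (sigma <= 0) return(vol)
    transfer <- smooth_transfer(d, sigma)
  }
  out <- Re(stats::fft(stats::fft(vol) * transfer, inverse = TRUE)) / prod(d)
  array(out, d)
}

# Variance attenuation factor of circular Gaussian smoothing applied to
# unit-variance white noise: prod over axes of sum(kernel^2).
smooth_var_factor <- function(dim, sigma_vox) {
  sigma_vox <- rep(sigma_vox, length.out = 3L)
  prod(vapply(1:3, function(a) sum(circular_gauss_kernel(dim[a], sigma_vox[a])^2), 0))
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: response peaking near 6 s and an
#' undershoot peaking near 16 s with 1/6 relative amplitude, the standard
#' canonical shape used by SPM-family tools.
#'
#' @param t nonnegative time points in seconds.
#' @return HRF values, peak-normalised to 1.
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 7, rate = 1) - stats::dgamma(t, shape = 17, rate = 1) / 6
  tt <- seq(0, 32, by = 0.01)
  peak <- max(stats::dgamma(tt, shape = 7, rate = 1) - stats::dgamma(tt, shape = 17, rate = 1) / 6)
  h / peak
}

# HRF-convolved condition regressor sampled at volume times.
# onsets/durations in seconds; sub-TR onsets handled by a 0.1 s micro grid.
convolve_condition <- function(onsets, durations, tr_s, n_volumes, dt = 0.1) {
  t_end <- n_volumes * tr_s
  n_micro <- ceiling(t_end / dt) + 1L
  u <- numeric(n_micro)
  durations <- rep(durations, length.out = length(onsets))
  for (e in seq_along(onsets)) {
    i0 <- floor(onsets[e] / dt) + 1L
    i1 <- min(n_micro, ceiling((onsets[e] + durations[e]) / dt))
    if (i0 <= n_micro) u[i0:max(i0, i1)] <- 1
  }
  h <- canonical_hrf(seq(0, 32, by = dt))
  conv <- stats::convolve(u, rev(h), type = "open")[seq_len(n_micro)] * dt
  vol_t <- (seq_len(n_volumes) - 1L) * tr_s
  conv[pmin(n_micro, floor(vol_t / dt) + 1L)]
}

#' Construct a 4D BOLD volume series
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param tr_s repetition time in seconds.
#' @return an object of class `volume_series`.
#' @export
volume_series <- function(data, voxel_size_mm, tr_s) {
  stopifnot(length(dim(data)) == 4L, voxel_size_mm > 0, tr_s > 0)
  structure(list(data = data, voxel_size_mm = voxel_size_mm, tr_s = tr_s),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %d x %d x %d voxels (%g mm), %d volumes, TR %g s\n",
              d[1], d[2], d[3], x$voxel_size_mm, d[4], x$tr_s))
  invisible(x)
}

#' @export
dim.volume_series <- function(x) dim(x$data)

n_volumes <- function(vs) dim(vs$data)[4L]
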