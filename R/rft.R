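#' Estimate field smoothness from residual maps
#'
#' Kiebel-style estimator: residual maps are standardized per voxel (unit
#' RMS across maps); the variance of spatial first differences along each
#' axis estimates the derivative variance \eqn{\lambda_a}, and
#' \eqn{FWHM_a = \sqrt{4\log 2/\lambda_a}} (voxel units). RESELs =
#' masked voxel count / product of per-axis FWHMs.
#'
#' @param residual_maps list of 3D arrays (same grid).
#' @param mask logical/0-1 3D array; NULL = whole grid.
#' @return an object of class `smoothness_estimate` with `fwhm_voxels`
#'   (length 3), `resels`, `n_voxels_search`.
#' @export
estimate_smoothness <- function(residual_maps, mask = NULL) {
  if (length(residual_maps) < 2L) stopf("need >= 2 residual maps")
  d <- dim(residual_maps[[1L]])
  if (is.null(mask)) mask <- array(TRUE, d)
  mask <- array(as.logical(mask), d)
  E <- vapply(residual_maps, as.vector, numeric(prod(d)))
  rms <- sqrt(rowMeans(E^2))
  if (all(rms[as.vector(mask)] == 0)) stopf("zero-variance residuals")
  U <- E / pmax(rms, .Machine$double.eps)
  lambda <- numeric(3L)
  for (a in 1:3) {
    sl <- slice.index(array(0, d), a)
    keep_lo <- as.vector(mask & (sl < d[a]))          # voxel and its +1 neighbour
    shift <- c(1L, d[1L], d[1L] * d[2L])[a]
    idx <- which(keep_lo)
    nb_in <- as.vector(mask)[idx + shift]
    idx <- idx[nb_in]
    if (!length(idx)) stopf("mask too thin along axis %d", a)
    diffs <- U[idx + shift, , drop = FALSE] - U[idx, , drop = FALSE]
    lambda[a] <- mean(diffs^2)
  }
  fwhm <- sqrt(4 * log(2) / lambda)
  nvox <- sum(mask)
  structure(list(fwhm_voxels = fwhm, resels = nvox / prod(fwhm),
                 n_voxels_search = nvox),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("<smoothness_estimate> FWHM (vox): %s; %d voxels = %.1f RESELs\n",
              paste(sprintf("%.2f", x$fwhm_voxels), collapse = ", "),
              x$n_voxels_search, x$resels))
  invisible(x)
}

# 18-connectivity offsets (faces + edges, no corners)
conn18_offsets <- function() {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off[rowSums(abs(off)) %in% c(1L, 2L), , drop = FALSE]
}

#' Label connected clusters in a binary volume
#'
#' Connected components under 18-connectivity (voxels sharing a face or
#' an edge; corner-only contact does not connect). Labels are assigned in
#' order of each component's minimum linear voxel index, so the labeling
#' is deterministic.
#'
#' @param binary logical/0-1 3D array.
#' @return list of integer vectors of linear voxel indices, one per
#'   cluster, ordered by minimum index.
#' @export
label_clusters <- function(binary) {
  d <- dim(binary)
  stopifnot(length(d) == 3L)
  fg <- which(as.logical(binary))
  if (!length(fg)) return(list())
  in_fg <- logical(prod(d))
  in_fg[fg] <- TRUE
  visited <- logical(prod(d))
  off <- conn18_offsets()
  clusters <- list()
  for (start in fg) {
    if (visited[start]) next
    queue <- start
    visited[start] <- TRUE
    members <- integer()
    while (length(queue)) {
      cur <- queue
      queue <- integer()
      members <- c(members, cur)
      crd <- index_to_coords(cur, d)
      for (o in seq_len(nrow(off))) {
        nb <- cbind(crd[, 1L] + off[o, 1L], crd[, 2L] + off[o, 2L],
                    crd[, 3L] + off[o, 3L])
        ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
              nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
              nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
        if (!any(ok)) next
        ni <- coords_to_index(nb[ok, , drop = FALSE], d)
        ni <- ni[in_fg[ni] & !visited[ni]]
        if (length(ni)) {
          ni <- unique(ni)
          visited[ni] <- TRUE
          queue <- c(queue, ni)
        }
      }
    }
    clusters[[length(clusters) + 1L]] <- sort(members)
  }
  clusters[order(vapply(clusters, min, 0L))]
}

# Expected number of clusters above u in a unit Gaussian field with the
# given RESEL count (3D Euler characteristic density, leading term).
expected_clusters <- function(u, resels) {
  resels * (4 * log(2))^(3 / 2) / (2 * pi)^2 * (u^2 - 1) * exp(-u^2 / 2)
}

# P(cluster extent >= k voxels) under the classic 3D approximation:
# exp(-beta k^(2/3)) with beta = (Gamma(5/2) Em / EN)^(2/3).
cluster_extent_tail <- function(k, u, resels, n_voxels) {
  Em <- expected_clusters(u, resels)
  EN <- n_voxels * stats::pnorm(u, lower.tail = FALSE)
  if (Em <= 0 || EN <= 0) return(rep(0, length(k)))
  beta <- (gamma(5 / 2) * Em / EN)^(2 / 3)
  exp(-beta * k^(2 / 3))
}

#' Two-sided GRF cluster-level correction
#'
#' Forms clusters at \eqn{u = \Phi^{-1}(1 - p_{voxel}/2)} separately on
#' the positive and negative excursions, computes each cluster's
#' corrected p from the standard Gaussian-random-field cluster-extent
#' approximation (expected cluster count from the Euler-characteristic
#' density, expected extent from RESELs, extent tail with the 3D
#' 2/3-power exponent), and retains clusters with corrected
#' p < `cluster_p`/2 per tail and size >= `min_extent`.
#'
#' @param zmap a second-level [stat_map()].
#' @param smoothness a [estimate_smoothness()] result on the same grid.
#' @param voxel_p two-sided cluster-forming voxel p.
#' @param cluster_p two-sided cluster-level alpha.
#' @param min_extent minimum cluster size in voxels.
#' @param mask optional logical 3D search mask.
#' @return an object of class `cluster_set`: `clusters` (data.frame:
#'   label, size, peak_z, sign, p_corrected), `voxels` (list of index
#'   vectors), `mask` (logical 3D abnormal mask, union of retained
#'   clusters), `forming_threshold_z`, `min_extent`.
#' @export
grf_cluster_correct <- function(zmap, smoothness, voxel_p = 0.001,
                                cluster_p = 0.05, min_extent = 10L,
                                mask = NULL) {
  if (!(voxel_p > 0 && voxel_p < 1) || !(cluster_p > 0 && cluster_p <= 1))
    stopf("voxel_p must be in (0,1) and cluster_p in (0,1]")
  z <- zmap$values
  d <- dim(z)
  if (is.null(mask)) mask <- array(TRUE, d)
  u <- stats::qnorm(1 - voxel_p / 2)
  rows <- list()
  vox_list <- list()
  for (sgn in c(1, -1)) {
    excur <- (sgn * z >= u) & mask
    cl <- label_clusters(excur)
    for (vox in cl) {
      k <- length(vox)
      ptail <- cluster_extent_tail(k, u, smoothness$resels,
                                   smoothness$n_voxels_search)
      pcorr <- 1 - exp(-expected_clusters(u, smoothness$resels) * ptail)
      if (k >= min_extent && pcorr < cluster_p / 2) {
        rows[[length(rows) + 1L]] <-
          data.frame(size = k, peak_z = sgn * max(sgn * z[vox]),
                     sign = ifelse(sgn > 0, "+", "-"), p_corrected = pcorr)
        vox_list[[length(vox_list) + 1L]] <- vox
      }
    }
  }
  abn <- array(FALSE, d)
  if (length(vox_list)) {
    ord <- order(vapply(vox_list, min, 0L))
    vox_list <- vox_list[ord]
    rows <- rows[ord]
    clusters <- do.call(rbind, rows)
    clusters <- cbind(label = seq_len(nrow(clusters)), clusters)
    abn[unlist(vox_list)] <- TRUE
  } else {
    clusters <- data.frame(label = integer(), size = integer(),
                           peak_z = numeric(), sign = character(),
                           p_corrected = numeric())
  }
  structure(list(clusters = clusters, voxels = vox_list, mask = abn,
                 forming_threshold_z = u, min_extent = as.integer(min_extent)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s) above |z| = %.2f (min extent %d)\n",
              nrow(x$clusters), x$forming_threshold_z, x$min_extent))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}
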