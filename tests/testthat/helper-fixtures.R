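# Shared fixture builders and independent oracles.

# small, fast simulation config; override fields via ...
tiny_config <- function(..., seed = 1L) {
  defaults <- list(grid_shape = c(14L, 14L, 10L), n_volumes = 60L,
                   n_regions = 6L, n_events_per_condition = 6L,
                   effect_rois = character(), effect_size = 0,
                   noise_sd = 1, motion_spike_prob = 0.01, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# strong-effect two-group config used by the recovery experiments
effect_config <- function(..., seed = 1L) {
  tiny_config(grid_shape = c(16L, 16L, 12L), n_volumes = 80L,
              n_events_per_condition = 8L,
              effect_rois = c("region_01", "region_04"), effect_size = 3,
              ..., seed = seed)
}

# independent flood-fill connected components via igraph (18-connectivity)
oracle_components <- function(binary) {
  d <- dim(binary)
  fg <- which(as.logical(binary))
  if (!length(fg)) return(list())
  crd <- fmricv:::index_to_coords(fg, d)
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  off <- off[rowSums(abs(off)) %in% c(1, 2), ]
  pos <- match(fg, fg)
  edges <- integer(0)
  lut <- integer(prod(d)); lut[fg] <- seq_along(fg)
  for (o in seq_len(nrow(off))) {
    nb <- cbind(crd[, 1] + off$di[o], crd[, 2] + off$dj[o], crd[, 3] + off$dk[o])
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    ni <- rep(0L, length(fg))
    ni[ok] <- lut[fmricv:::coords_to_index(nb[ok, , drop = FALSE], d)]
    keep <- ni > 0
    edges <- c(edges, rbind(seq_along(fg)[keep], ni[keep]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  cl <- split(fg, comp)
  cl <- lapply(cl, sort)
  unname(cl[order(vapply(cl, min, 0L))])
}

# independent Jenkinson FD oracle: explicit matrix products
oracle_fd <- function(motion, radius = 80) {
  mk <- function(p) {
    Rx <- rbind(c(1, 0, 0), c(0, cos(p[4]), -sin(p[4])), c(0, sin(p[4]), cos(p[4])))
    Ry <- rbind(c(cos(p[5]), 0, sin(p[5])), c(0, 1, 0), c(-sin(p[5]), 0, cos(p[5])))
    Rz <- rbind(c(cos(p[6]), -sin(p[6]), 0), c(sin(p[6]), cos(p[6]), 0), c(0, 0, 1))
    m <- diag(4); m[1:3, 1:3] <- Rx %*% Ry %*% Rz; m[1:3, 4] <- p[1:3]
    m
  }
  n <- nrow(motion)
  fd <- numeric(n)
  for (t in 2:n) {
    M <- mk(motion[t, ]) %*% solve(mk(motion[t - 1, ])) - diag(4)
    fd[t] <- sqrt(radius^2 / 5 * sum(M[1:3, 1:3]^2) + sum(M[1:3, 4]^2))
  }
  fd
}

# brute-force step-up Benjamini-Hochberg q-values from the definition:
# q_i = min over j with p_(j) >= p_(i) of m * p_(j) / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# simulated unit-variance smooth Gaussian z-field with known FWHM (voxels)
null_zfield <- function(dim, fwhm_vox, transfer = NULL, fac = NULL) {
  sigma <- fmricv:::fwhm_to_sigma(fwhm_vox)
  if (is.null(transfer)) transfer <- fmricv:::smooth_transfer(dim, sigma)
  if (is.null(fac)) fac <- sqrt(fmricv:::smooth_var_factor(dim, sigma))
  gaussian_smooth_3d(array(stats::rnorm(prod(dim)), dim), transfer = transfer) / fac
}

known_smoothness <- function(dim, fwhm_vox) {
  fwhm <- rep(fwhm_vox, 3)
  structure(list(fwhm_voxels = fwhm, resels = prod(dim) / prod(fwhm),
                 n_voxels_search = prod(dim)),
            class = "smoothness_estimate")
}

# labels/plan for a prepared two-group cohort
group_labels <- function(prep, patient_group = "remission") {
  stats::setNames(as.integer(prep$groups == patient_group), prep$ids)
}
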