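#' Simulation configuration for a synthetic Go/NoGo BOLD cohort
#'
#' Defines the acquisition geometry, task timing, noise model and
#' ground-truth group effect of a synthetic cohort. Defaults mirror the
#' emulated study conditions: 2 s TR, 307 usable volumes on a 3 mm grid,
#' three HRF-convolved face conditions (Go = happy, NoGo = sad, Neutral),
#' spatially smooth AR(1) noise and occasional motion spikes. Group
#' differences (patients minus controls, percent-signal units) are
#' injected only into `effect_rois`, on the Go condition, so the Go-NoGo
#' contrast carries the group effect.
#'
#' @param grid_shape integer vector of 3 voxel counts per axis.
#' @param voxel_size_mm isotropic voxel size (mm).
#' @param tr_s repetition time (s).
#' @param n_volumes number of usable volumes.
#' @param n_regions number of atlas regions tiling the grid interior.
#' @param conditions ordered condition names.
#' @param n_events_per_condition events per condition.
#' @param event_duration_s event (face presentation) duration in seconds.
#' @param effect_rois character names of regions carrying the group effect.
#' @param effect_size patient-minus-control Go amplitude difference, in
#'   percent signal change.
#' @param base_amplitude named per-condition baseline response amplitude
#'   (percent signal), shared by all groups and regions.
#' @param subject_amp_sd between-subject SD of the Go amplitude inside
#'   `effect_rois` (percent signal); gives the clinical link a target.
#' @param noise_sd marginal SD of the voxel noise (percent signal).
#' @param ar_coeff lag-1 autoregressive coefficient of the temporal noise.
#' @param spatial_fwhm_mm FWHM of the spatial smoothing applied to the
#'   noise field (mm); creates realistic smoothness for RESEL estimation.
#' @param motion_spike_prob per-volume probability of a motion spike.
#' @param clinical_links data.frame with columns `region`, `metric`,
#'   `rho`: planted correlation between the subject's standardized Go
#'   amplitude in `region` and the named clinical metric.
#' @param clinical_metrics names of clinical/behavioral scores to emit.
#' @param seed integer; fully determines the cohort.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(24L, 24L, 18L),
                       voxel_size_mm = 3,
                       tr_s = 2,
                       n_volumes = 307L,
                       n_regions = 12L,
                       conditions = c("Go", "NoGo", "Neutral"),
                       n_events_per_condition = 15L,
                       event_duration_s = 1,
                       effect_rois = character(),
                       effect_size = 0,
                       base_amplitude = c(Go = 0.6, NoGo = 0.6, Neutral = 0.4),
                       subject_amp_sd = 0.1,
                       noise_sd = 1,
                       ar_coeff = 0.3,
                       spatial_fwhm_mm = 6,
                       motion_spike_prob = 0.02,
                       clinical_links = NULL,
                       clinical_metrics = c("PSQI", "Stroop1", "TMT_B", "GoOmission"),
                       seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            voxel_size_mm > 0, tr_s > 0, n_volumes >= 2L, n_regions >= 1L,
            length(conditions) >= 1L, n_events_per_condition >= 1L,
            event_duration_s > 0, noise_sd > 0,
            abs(ar_coeff) < 1, spatial_fwhm_mm >= 0,
            motion_spike_prob >= 0, motion_spike_prob <= 1)
  if (n_volumes < 2 * n_events_per_condition * ceiling(event_duration_s / tr_s))
    stopf("n_volumes (%d) too small for %d events/condition of %g s at TR %g s",
          n_volumes, n_events_per_condition, event_duration_s, tr_s)
  if (!is.null(clinical_links)) {
    stopifnot(is.data.frame(clinical_links),
              all(c("region", "metric", "rho") %in% names(clinical_links)),
              all(abs(clinical_links$rho) <= 1))
  }
  cfg <- list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
              tr_s = tr_s, n_volumes = as.integer(n_volumes),
              n_regions = as.integer(n_regions), conditions = conditions,
              n_events_per_condition = as.integer(n_events_per_condition),
              event_duration_s = event_duration_s,
              effect_rois = effect_rois, effect_size = effect_size,
              base_amplitude = base_amplitude,
              subject_amp_sd = subject_amp_sd,
              noise_sd = noise_sd, ar_coeff = ar_coeff,
              spatial_fwhm_mm = spatial_fwhm_mm,
              motion_spike_prob = motion_spike_prob,
              clinical_links = clinical_links,
              clinical_metrics = clinical_metrics,
              seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

#' Default cohort group sizes
#'
#' The emulated cohort: 15 remission, 11 depression, 17 mania patients
#' and 43 matched healthy controls.
#' @return named integer vector.
#' @export
default_group_sizes <- function() {
  c(remission = 15L, depression = 11L, mania = 17L, HC = 43L)
}

bd_groups <- function() c("remission", "depression", "mania")

#' Build a deterministic toy atlas tiling the grid interior
#'
#' Partitions the interior of the grid (excluding a one-voxel background
#' shell) into `n_regions` disjoint, connected rectangular regions: the
#' interior y-range is cut into slabs and each slab into x-blocks, every
#' region spanning the full interior z-range. Two shell planes are
#' designated as white-matter and CSF reference compartments for nuisance
#' extraction. Depends only on the config (not the seed draw order).
#'
#' @param config a [sim_config()].
#' @return an object of class `fmri_atlas` with fields `labels` (3D
#'   integer array, 0 = background), `names`, `voxel_size_mm`,
#'   `wm_voxels`, `csf_voxels` (linear voxel indices in the shell).
#' @export
make_atlas <- function(config) {
  d <- config$grid_shape
  R <- config$n_regions
  nx <- d[1L] - 2L; ny <- d[2L] - 2L; nz <- d[3L] - 2L
  if (nx < 1L || ny < 1L || nz < 1L)
    stopf("grid %s has no interior after removing the background shell",
          paste(d, collapse = "x"))
  b <- max(1L, floor(sqrt(R)))          # y slabs
  per <- rep(R %/% b, b)
  if (R %% b > 0) per[seq_len(R %% b)] <- per[seq_len(R %% b)] + 1L
  if (b > ny || max(per) > nx)
    stopf("grid %s too small to host %d disjoint regions (needs >= %d x-interior and >= %d y-interior voxels)",
          paste(d, collapse = "x"), R, max(per), b)
  labels <- array(0L, d)
  ybreaks <- round(seq(0, ny, length.out = b + 1L))
  lab <- 0L
  for (j in seq_len(b)) {
    yidx <- (ybreaks[j] + 1L):ybreaks[j + 1L] + 1L
    m <- per[j]
    if (m == 0L) next
    xbreaks <- round(seq(0, nx, length.out = m + 1L))
    for (i in seq_len(m)) {
      lab <- lab + 1L
      xidx <- (xbreaks[i] + 1L):xbreaks[i + 1L] + 1L
      labels[xidx, yidx, 2:(d[3L] - 1L)] <- lab
    }
  }
  wm <- which(slice.index(labels, 1) == 1L)
  csf <- which(slice.index(labels, 1) == d[1L])
  structure(list(labels = labels,
                 names = sprintf("region_%02d", seq_len(R)),
                 voxel_size_mm = config$voxel_size_mm,
                 wm_voxels = wm, csf_voxels = csf),
            class = "fmri_atlas")
}

#' @export
print.fmri_atlas <- function(x, ...) {
  cat(sprintf("<fmri_atlas> %s grid, %d regions, %g mm voxels\n",
              paste(dim(x$labels), collapse = "x"), length(x$names),
              x$voxel_size_mm))
  invisible(x)
}

#' Pseudo-randomized event schedule shared by all subjects
#'
#' Generates non-overlapping events for each condition with jittered
#' inter-trial intervals, in a condition order randomised from the config
#' seed only: the trial sequence and timing are identical across
#' subjects, as in the emulated task.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `onset` (s), `duration` (s),
#'   `condition`.
#' @export
make_event_schedule <- function(config) {
  n_cond <- length(config$conditions)
  if (n_cond == 0L) stopf("conditions must be nonempty")
  n_ev <- n_cond * config$n_events_per_condition
  total_s <- config$n_volumes * config$tr_s
  dur <- config$event_duration_s
  lead <- min(4, 0.02 * total_s)        # settle-in before first trial
  tail <- 16                            # let the last response evolve
  avail <- total_s - lead - tail - n_ev * dur
  if (avail <= 0.5 * n_ev)
    stopf("cannot schedule %d events of %g s in a %g s run", n_ev, dur, total_s)
  rng <- local({
    set.seed(derive_seed(config$seed, "events"))
    list(gaps = stats::runif(n_ev, 0.5, 1.5),
         order = sample(rep(config$conditions, config$n_events_per_condition)))
  })
  gaps <- rng$gaps / sum(rng$gaps) * avail  # jittered ITIs, each > 1/6 s
  onsets <- lead + cumsum(gaps) + (seq_len(n_ev) - 1L) * dur
  # 0.1 s grid: onsets need not align to volume boundaries (TR = 2 s)
  onsets <- round(onsets * 10) / 10
  data.frame(onset = onsets, duration = dur, condition = rng$order,
             stringsAsFactors = FALSE)
}

# (region, condition, group) amplitude map in percent-signal units
amplitude_map <- function(config, atlas) {
  groups <- c(bd_groups(), "HC")
  amp <- array(0, dim = c(length(atlas$names), length(config$conditions),
                          length(groups)),
               dimnames = list(atlas$names, config$conditions, groups))
  for (cn in config$conditions)
    amp[, cn, ] <- config$base_amplitude[[cn]] %||% 0.5
  if (length(config$effect_rois)) {
    bad <- setdiff(config$effect_rois, atlas$names)
    if (length(bad)) stopf("effect_rois not in atlas: %s", paste(bad, collapse = ", "))
    amp[config$effect_rois, "Go", bd_groups()] <-
      amp[config$effect_rois, "Go", bd_groups()] + config$effect_size
  }
  amp
}

simulate_motion <- function(config, seed) {
  set.seed(seed)
  n <- config$n_volumes
  drift <- cbind(matrix(stats::rnorm(3 * n, 0, 0.002), n, 3),   # mm
                 matrix(stats::rnorm(3 * n, 0, 2e-5), n, 3))    # rad
  drift <- apply(drift, 2, cumsum)
  spikes <- which(stats::runif(n) < config$motion_spike_prob)
  for (s in spikes) {
    ax <- sample.int(3L, 1L)
    drift[s, ax] <- drift[s, ax] + stats::runif(1, 0.4, 0.9) * sample(c(-1, 1), 1)
  }
  colnames(drift) <- c("tx_mm", "ty_mm", "tz_mm", "rx_rad", "ry_rad", "rz_rad")
  drift
}

# AR(1) temporal noise, spatially smoothed per frame, rescaled to
# marginal sd = noise_sd.
simulate_noise <- function(config, seed) {
  set.seed(seed)
  d <- config$grid_shape
  nvox <- prod(d)
  n <- config$n_volumes
  ar <- config$ar_coeff
  innov <- matrix(stats::rnorm(n * nvox), n, nvox)
  if (ar != 0) {
    innov <- innov * sqrt(1 - ar^2)
    innov <- apply(innov, 2, function(x) stats::filter(x, ar, method = "recursive"))
    innov[1, ] <- innov[1, ] / sqrt(1 - ar^2)  # stationary start
  }
  sigma_vox <- fwhm_to_sigma(config$spatial_fwhm_mm) / config$voxel_size_mm
  if (sigma_vox > 0) {
    tr <- smooth_transfer(d, sigma_vox)
    fac <- sqrt(smooth_var_factor(d, sigma_vox))
    for (t in seq_len(n)) {
      fr <- gaussian_smooth_3d(array(innov[t, ], d), transfer = tr)
      innov[t, ] <- as.vector(fr) / fac
    }
  }
  innov * config$noise_sd
}

#' Simulate one subject's record
#'
#' BOLD = baseline 100 + sum over conditions of amplitude(region,
#' condition, group) x HRF-convolved boxcar + spatially smooth AR(1)
#' noise, all in percent-signal units. The subject's Go amplitude inside
#' the effect regions gets a subject-level jitter (SD
#' `subject_amp_sd`) that also drives the planted clinical links.
#'
#' @param config a [sim_config()].
#' @param atlas a [make_atlas()] atlas.
#' @param group one of `"remission"`, `"depression"`, `"mania"`, `"HC"`.
#' @param id subject identifier string.
#' @return an object of class `subject_record` with fields `id`, `group`,
#'   `bold` (volume_series), `events`, `motion`, `clinical`, `amp_jitter`.
#' @export
simulate_subject <- function(config, atlas, group, id) {
  groups <- c(bd_groups(), "HC")
  if (!group %in% groups)
    stopf("unknown group '%s' (expected one of %s)", group,
          paste(groups, collapse = ", "))
  events <- make_event_schedule(config)
  amp <- amplitude_map(config, atlas)
  sseed <- derive_seed(config$seed, paste0("subject:", id))
  set.seed(sseed)
  jitter <- stats::rnorm(1, 0, config$subject_amp_sd)
  d <- config$grid_shape
  n <- config$n_volumes
  regs <- vapply(config$conditions, function(cn) {
    ev <- events[events$condition == cn, ]
    convolve_condition(ev$onset, ev$duration, config$tr_s, n)
  }, numeric(n))
  signal <- matrix(0, n, prod(d))
  labvec <- as.vector(atlas$labels)
  for (r in seq_along(atlas$names)) {
    vox <- which(labvec == r)
    if (!length(vox)) next
    a <- amp[r, , group]
    if (atlas$names[r] %in% config$effect_rois) a[["Go"]] <- a[["Go"]] + jitter
    signal[, vox] <- signal[, vox] + as.vector(regs %*% a)
  }
  noise <- simulate_noise(config, derive_seed(config$seed, paste0("noise:", id)))
  bold4d <- array(t(100 + signal + noise), c(d, n))
  motion <- simulate_motion(config, derive_seed(config$seed, paste0("motion:", id)))
  clinical <- simulate_clinical(config, jitter, derive_seed(config$seed, paste0("clin:", id)))
  structure(list(id = id, group = group,
                 bold = volume_series(bold4d, config$voxel_size_mm, config$tr_s),
                 events = events, motion = motion, clinical = clinical,
                 amp_jitter = jitter),
            class = "subject_record")
}

# Clinical scores: metrics named in a planted link are rho * z-scored
# amplitude jitter + sqrt(1-rho^2) * noise (population correlation = rho);
# the rest are independent standard normal. Scaled/shifted to plausible
# scale units (correlations are scale-free).
simulate_clinical <- function(config, jitter, seed) {
  set.seed(seed)
  z_a <- jitter / config$subject_amp_sd
  out <- stats::setNames(numeric(length(config$clinical_metrics)),
                         config$clinical_metrics)
  links <- config$clinical_links
  for (m in config$clinical_metrics) {
    rho <- 0
    if (!is.null(links) && m %in% links$metric)
      rho <- links$rho[match(m, links$metric)]
    out[[m]] <- 8 + 2 * (rho * z_a + sqrt(1 - rho^2) * stats::rnorm(1))
  }
  out
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s (%s): %d volumes, %d events, %d clinical scores\n",
              x$id, x$group, n_volumes(x$bold), nrow(x$events), length(x$clinical)))
  invisible(x)
}

#' Simulate a full cohort with ground truth
#'
#' @param config a [sim_config()].
#' @param group_sizes named integer vector of subjects per group;
#'   defaults to [default_group_sizes()].
#' @return list with `subjects` (list of subject_record), `atlas`, and
#'   `ground_truth` (effect regions, amplitude map, clinical links,
#'   per-subject amplitude jitters).
#' @export
simulate_cohort <- function(config, group_sizes = default_group_sizes()) {
  stopifnot(all(group_sizes >= 1L), !is.null(names(group_sizes)))
  atlas <- make_atlas(config)
  subjects <- list()
  for (g in names(group_sizes)) {
    for (i in seq_len(group_sizes[[g]])) {
      id <- sprintf("%s_%02d", g, i)
      subjects[[id]] <- simulate_subject(config, atlas, g, id)
    }
  }
  gt <- list(effect_rois = config$effect_rois,
             amplitude = amplitude_map(config, atlas),
             clinical_links = config$clinical_links,
             amp_jitter = vapply(subjects, `[[`, 0, "amp_jitter"))
  structure(list(subjects = subjects, atlas = atlas, ground_truth = gt,
                 config = config),
            class = "fmri_cohort")
}

#' @export
print.fmri_cohort <- function(x, ...) {
  tab <- table(vapply(x$subjects, `[[`, "", "group"))
  cat("<fmri_cohort>", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Group labels of a cohort
#' @param cohort an `fmri_cohort`.
#' @return character vector of group labels, named by subject id.
#' @export
cohort_groups <- function(cohort) {
  vapply(cohort$subjects, `[[`, "", "group")
}
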