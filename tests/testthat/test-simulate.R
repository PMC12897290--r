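test_that("atlas partitions the interior into disjoint connected regions", {
  cfg <- tiny_config(grid_shape = c(24L, 24L, 24L), n_regions = 12L)
  atl <- make_atlas(cfg)
  interior <- array(FALSE, cfg$grid_shape)
  interior[2:23, 2:23, 2:23] <- TRUE
  expect_identical(sort(unique(as.vector(atl$labels))), 0:12)
  expect_true(all(atl$labels[interior] > 0))   # union = interior
  expect_true(all(atl$labels[!interior] == 0)) # shell retained
  for (r in 1:12) {
    comp <- oracle_components(atl$labels == r)
    expect_length(comp, 1L) # connected
  }
  # degenerate partition: one region occupies the whole interior
  cfg1 <- tiny_config(grid_shape = c(8L, 8L, 8L), n_regions = 1L)
  atl1 <- make_atlas(cfg1)
  expect_identical(unname(table(atl1$labels)[["1"]]), 216L)
  # determinism
  expect_identical(make_atlas(cfg)$labels, atl$labels)
  # sizing error names the limit
  expect_error(make_atlas(tiny_config(grid_shape = c(5L, 5L, 5L),
                                      n_regions = 50L)),
               "too small")
})

test_that("event schedule is valid, subject-independent and config-determined", {
  cfg <- tiny_config(n_events_per_condition = 10L, n_volumes = 120L)
  ev <- make_event_schedule(cfg)
  expect_identical(unname(table(ev$condition)["Go"]), 10L)
  expect_identical(unname(table(ev$condition)["NoGo"]), 10L)
  expect_identical(unname(table(ev$condition)["Neutral"]), 10L)
  expect_true(all(ev$onset >= 0 & ev$onset < cfg$n_volumes * cfg$tr_s))
  # non-overlap
  expect_true(all(diff(ev$onset) >= ev$duration[-nrow(ev)]))
  # identical schedule regardless of subject: schedule is config-only
  expect_identical(make_event_schedule(cfg), ev)
  # sub-TR onsets occur (onsets need not align to volume boundaries)
  expect_true(any(ev$onset %% cfg$tr_s != 0))
  # too many events for the run errors
  expect_error(make_event_schedule(tiny_config(n_volumes = 60L,
                                               n_events_per_condition = 25L)),
               "n_volumes|schedule")
})

test_that("group effects are local to effect_rois and null cohorts are exchangeable", {
  cfg <- effect_config(subject_amp_sd = 0, seed = 3L)
  atl <- make_atlas(cfg)
  # subjects sharing an id share their noise draw, so the BD-HC
  # difference of same-id records isolates the injected signal
  bd <- simulate_subject(cfg, atl, "mania", "s1")
  hc <- simulate_subject(cfg, atl, "HC", "s1")
  delta_bold <- bd$bold$data - hc$bold$data
  labvec <- as.vector(atl$labels)
  for (r in seq_along(atl$names)) {
    vox <- which(labvec == r)
    m <- mean(abs(matrix(delta_bold, prod(cfg$grid_shape))[vox, ]))
    if (atl$names[r] %in% cfg$effect_rois) expect_gt(m, 0) else expect_equal(m, 0)
  }
  # ground-truth amplitude map localises the effect
  amp <- fmricv:::amplitude_map(cfg, atl)
  delta <- amp[, "Go", "mania"] - amp[, "Go", "HC"]
  expect_identical(names(which(delta != 0)), c("region_01", "region_04"))
  expect_true(all(amp[, "NoGo", "mania"] == amp[, "NoGo", "HC"]))
  # null config: identical amplitude maps for all groups
  cfg0 <- tiny_config(effect_size = 0)
  amp0 <- fmricv:::amplitude_map(cfg0, make_atlas(cfg0))
  expect_equal(amp0[, , "remission"], amp0[, , "HC"])
  # unknown group label
  expect_error(simulate_subject(cfg, atl, "euthymia", "x"), "unknown group")
})

test_that("cohort generation is deterministic and honours group sizes", {
  cfg <- tiny_config(grid_shape = c(8L, 8L, 6L), n_volumes = 40L,
                     n_regions = 2L, n_events_per_condition = 4L, seed = 9L)
  co1 <- simulate_cohort(cfg, c(HC = 4L, remission = 4L))
  expect_length(co1$subjects, 8L)
  co2 <- simulate_cohort(cfg, c(HC = 4L, remission = 4L))
  expect_identical(co1$subjects[["HC_01"]]$bold$data,
                   co2$subjects[["HC_01"]]$bold$data)
  expect_identical(vapply(co1$subjects, function(s) s$clinical[["PSQI"]], 0),
                   vapply(co2$subjects, function(s) s$clinical[["PSQI"]], 0))
  # default sizes mirror the emulated cohort: 43 patients + 43 controls
  co3 <- simulate_cohort(cfg)
  grp <- cohort_groups(co3)
  expect_identical(sum(grp != "HC"), 43L)
  expect_identical(sum(grp == "HC"), 43L)
  expect_identical(as.integer(table(grp)[c("remission", "depression", "mania")]),
                   c(15L, 11L, 17L))
})

test_that("motion traces are quiet without spikes and planted links correlate", {
  cfg <- tiny_config(motion_spike_prob = 0, seed = 4L)
  atl <- make_atlas(cfg)
  s <- simulate_subject(cfg, atl, "HC", "h1")
  fd <- framewise_displacement(s$motion)
  expect_length(fd, cfg$n_volumes)
  expect_identical(scrub_mask(fd, 0.2), integer(0))
  # planted clinical link: correlation with the amplitude jitter
  links <- data.frame(region = "region_01", metric = "PSQI", rho = -0.8)
  cfgl <- tiny_config(effect_rois = "region_01", effect_size = 1,
                      subject_amp_sd = 1, clinical_links = links, seed = 8L)
  co <- simulate_cohort(cfgl, c(remission = 40L))
  psqi <- vapply(co$subjects, function(s) s$clinical[["PSQI"]], 0)
  r <- cor(co$ground_truth$amp_jitter, psqi)
  expect_lt(r, -0.5)
})
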