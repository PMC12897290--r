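test_that("framewise displacement matches the closed form and the matrix oracle", {
  # no motion -> FD 0
  still <- matrix(0, 5, 6)
  expect_equal(framewise_displacement(still), rep(0, 5))
  # pure 0.5 mm translation step on one axis
  m <- matrix(0, 4, 6)
  m[3, 2] <- 0.5
  fd <- framewise_displacement(m)
  expect_equal(fd[3], 0.5)
  expect_equal(fd[4], 0.5) # stepping back down moves the same amount
  # random small motions match an independently coded matrix oracle
  set.seed(11)
  rnd <- cbind(matrix(rnorm(20 * 3, 0, 0.1), 20, 3),
               matrix(rnorm(20 * 3, 0, 0.005), 20, 3))
  expect_equal(framewise_displacement(rnd), oracle_fd(rnd), tolerance = 1e-10)
  # FD depends on successive differences: with rotations held fixed, a
  # constant offset to every parameter leaves FD exactly unchanged
  fixed_rot <- rnd
  fixed_rot[, 4:6] <- rep(c(0.01, -0.02, 0.015), each = 20)
  off <- sweep(fixed_rot, 2, c(1, -2, 0.5, 0.03, -0.01, 0.02), `+`)
  expect_equal(framewise_displacement(off), framewise_displacement(fixed_rot),
               tolerance = 1e-10)
  # with varying rotations the invariance is first-order in the offset
  off_r <- sweep(rnd, 2, c(0, 0, 0, 1e-3, -1e-3, 1e-3), `+`)
  expect_equal(framewise_displacement(off_r), framewise_displacement(rnd),
               tolerance = 1e-2)
  expect_error(framewise_displacement(matrix(c(NA, rep(0, 11)), 2, 6)),
               "non-finite")
})

test_that("gross-motion exclusion applies strict 3 mm / 3 degree rules", {
  m <- matrix(0, 10, 6)
  expect_false(qc_exclude(m)$excluded)
  m2 <- m; m2[5, 1] <- 3.1
  q <- qc_exclude(m2)
  expect_true(q$excluded)
  expect_match(q$reason, "translation 1 .*volume 5")
  # exactly 3 degrees is not excluded (strict inequality)
  m3 <- m; m3[2, 5] <- 3 * pi / 180
  expect_false(qc_exclude(m3)$excluded)
  m4 <- m; m4[2, 5] <- 3.05 * pi / 180
  expect_true(qc_exclude(m4)$excluded)
})

test_that("scrub mask flags FD strictly above threshold", {
  expect_identical(scrub_mask(rep(0, 10)), integer(0))
  expect_identical(scrub_mask(c(0, 0.25, 0.1)), 2L)
  expect_identical(scrub_mask(c(0, 0.2, 0.1)), integer(0)) # strict
  expect_identical(scrub_mask(runif(50), Inf), integer(0))
})

test_that("nuisance design has Friston-24 structure, trend, and one-hot spikes", {
  set.seed(2)
  n <- 30
  mo <- matrix(rnorm(n * 6, 0, 0.05), n, 6)
  X <- build_nuisance(mo, rnorm(n), rnorm(n))
  expect_identical(ncol(X), 27L)
  # lagged columns are the parameters shifted with p(-1) = 0
  expect_equal(unname(X[, "mp1_lag"]), c(0, mo[-n, 1]))
  expect_equal(unname(X[, "mp3_lagsq"]), c(0, mo[-n, 3])^2)
  X3 <- build_nuisance(mo, rnorm(n), rnorm(n), scrubbed = c(4L, 9L, 20L))
  expect_identical(ncol(X3), 30L)
  spikes <- X3[, grepl("^spike", colnames(X3)), drop = FALSE]
  expect_equal(unname(colSums(spikes)), rep(1, 3))
  expect_equal(which(X3[, "spike_9"] == 1), 9L)
  # zero motion trace: all 24 motion columns zero, no error
  X0 <- build_nuisance(matrix(0, n, 6), rnorm(n), rnorm(n))
  expect_true(all(X0[, 1:24] == 0))
  expect_error(build_nuisance(mo, rnorm(5), rnorm(n)), "length")
})

test_that("nuisance regression is idempotent and the band-pass has the stated response", {
  set.seed(3)
  n <- 100; tr <- 2
  Y <- matrix(100 + rnorm(n * 32), n, 32)
  design <- build_nuisance(matrix(rnorm(n * 6, 0, 0.02), n, 6), rnorm(n), rnorm(n))
  once <- fmricv:::residualize(Y, design)
  twice <- fmricv:::residualize(once, design)
  expect_equal(twice, once, tolerance = 1e-10)
  # residualization removes the design: projection leaves it orthogonal
  expect_lt(max(abs(crossprod(design, once))), 1e-6)

  # frequency response: integer-cycle sinusoids, no nuisance structure
  freq_gain <- function(f_hz) {
    cycles <- f_hz * n * tr
    x <- sin(2 * pi * cycles * (0:(n - 1)) / n)
    vs <- volume_series(array(rep(x, each = 8), c(2, 2, 2, n)), 3, tr)
    filt <- regress_filter_smooth(vs, matrix(0, n, 0), fwhm_mm = 0)
    sd(filt$data[1, 1, 1, ]) / sd(x)
  }
  expect_lt(freq_gain(0.005), 0.1)  # stop band
  expect_gt(freq_gain(0.05), 0.9)   # pass band
  expect_lt(freq_gain(0.2), 0.1)    # high-frequency stop band
})

test_that("rank-deficient designs are handled with a warning, not silently", {
  set.seed(4)
  n <- 40
  bold <- volume_series(array(rnorm(8 * n), c(2, 2, 2, n)), 3, 2)
  base <- rnorm(n)
  dup <- cbind(a = base, b = base) # perfectly collinear
  expect_warning(regress_filter_smooth(bold, dup, fwhm_mm = 0),
                 "rank-deficient")
})

test_that("spatial smoothing conserves each frame's mean", {
  set.seed(5)
  vol <- array(rnorm(16 * 16 * 10), c(16, 16, 10))
  sm <- gaussian_smooth_3d(vol, fwhm_mm = 6, voxel_size_mm = 3)
  expect_equal(mean(sm), mean(vol), tolerance = 1e-12)
  expect_gt(sd(vol), sd(sm)) # smoothing shrinks variance
})

test_that("full per-subject preprocessing produces a coherent QC report", {
  cfg <- tiny_config(motion_spike_prob = 0.05, seed = 12L)
  atl <- make_atlas(cfg)
  s <- simulate_subject(cfg, atl, "HC", "h1")
  pp <- preprocess_subject(s, atl)
  expect_s3_class(pp$report, "preproc_report")
  expect_length(pp$report$fd_series, cfg$n_volumes)
  expect_identical(pp$report$scrubbed_volumes,
                   scrub_mask(pp$report$fd_series, 0.2))
  expect_identical(dim(pp$bold$data), dim(s$bold$data))
  qc_tab <- write_qc_table(list(pp$report), file.path(tempdir(), "qc.tsv"))
  expect_identical(nrow(qc_tab), 1L)
})
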