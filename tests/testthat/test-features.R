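make_prep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- effect_config(seed = 41L)
      coh <- simulate_cohort(cfg, c(remission = 8L, HC = 8L))
      cache <<- list(cfg = cfg,
                     coh = coh,
                     prep = prepare_cohort(coh, "go_minus_nogo"))
    }
    cache
  }
})

test_that("abnormal ROIs come from TRAIN maps with the overlap rule applied", {
  fx <- make_prep()
  prep <- fx$prep
  g <- prep$groups
  pm <- prep$zmaps$go_minus_nogo[names(g)[g == "remission"]]
  cm <- prep$zmaps$go_minus_nogo[names(g)[g == "HC"]]
  rois <- define_abnormal_rois(pm, cm, prep$atlas)
  expect_s3_class(rois, "abnormal_roi_set")
  expect_true(all(rois$roi_table$overlap >= 10))
  expect_true(!is.unsorted(rois$roi_table$label)) # ascending label order
  # strong effect: the injected regions are recovered
  expect_true(all(c("region_01", "region_04") %in% rois$roi_table$name))
  # raising min_overlap beyond the largest overlap empties the set
  r2 <- define_abnormal_rois(pm, cm, prep$atlas,
                             min_overlap = max(rois$roi_table$overlap) + 1L)
  expect_identical(r2$k, 0L)
})

test_that("ROI-mean time series equal the brute-force voxel averages", {
  fx <- make_prep()
  prep <- fx$prep
  g <- prep$groups
  rois <- define_abnormal_rois(prep$zmaps$go_minus_nogo[names(g)[g == "remission"]],
                               prep$zmaps$go_minus_nogo[names(g)[g == "HC"]],
                               prep$atlas)
  id <- prep$ids[1L]
  ts <- extract_roi_timeseries(prep$bold[[id]], rois)
  expect_identical(dim(ts), c(fx$cfg$n_volumes, rois$k))
  bold <- prep$bold[[id]]$data
  d <- dim(bold)
  for (k in seq_len(rois$k)) {
    vox <- rois$voxels[[k]]
    crd <- fmricv:::index_to_coords(vox, d[1:3])
    naive <- vapply(seq_len(d[4]), function(t) {
      vals <- vapply(seq_len(nrow(crd)), function(i)
        bold[crd[i, 1], crd[i, 2], crd[i, 3], t], 0)
      mean(vals)
    }, 0)
    expect_equal(unname(ts[, k]), naive, tolerance = 1e-12)
  }
  # constant bold -> constant features; one-voxel ROI -> that voxel's series
  const <- volume_series(array(7, dim(prep$bold[[id]]$data)), 3, 2)
  expect_true(all(extract_roi_timeseries(const, rois) == 7))
})

test_that("t_use truncation and TRAIN-fitted scaling behave per contract", {
  set.seed(42)
  mk <- function(ti, k = 2) matrix(rnorm(ti * k), ti, k,
                                   dimnames = list(NULL, c("ra", "rb")))
  train <- list(s1 = mk(300), s2 = mk(307), s3 = mk(310))
  test <- list(t1 = mk(305))
  fm <- build_feature_matrix(train, test)
  expect_identical(fm$t_use, 300L)
  expect_identical(ncol(fm$x), 600L)
  # TEST subject shorter than t_use errors by name
  expect_error(build_feature_matrix(train, list(bad = mk(200))), "bad")
  # TRAIN columns standardized; TEST columns generally not
  tr_rows <- fm$x[fm$train_ids, ]
  expect_equal(unname(colMeans(tr_rows)), rep(0, 600), tolerance = 1e-10)
  expect_equal(unname(apply(tr_rows, 2, sd)), rep(1, 600), tolerance = 1e-10)
  # vectorization is ROI-major and the index map inverts it bijectively
  expect_identical(fm$index_map$roi[1:300], rep("ra", 300))
  expect_identical(fm$index_map$roi[301:600], rep("rb", 300))
  info <- feature_column_info(fm, c(1L, 301L, 450L))
  expect_identical(info$roi, c("ra", "rb", "rb"))
  expect_identical(info$timepoint, c(1L, 1L, 150L))
  expect_identical(nrow(unique(fm$index_map[, c("roi", "timepoint")])), 600L)
  # raw feature values: first column of subject s1 is its ROI-a series
  raw <- fm$x["s1", 1] * fm$scaler_params$scale[1] + fm$scaler_params$center[1]
  expect_equal(unname(raw), unname(train$s1[1, 1]))
})

test_that("TEST data never influence ROI definition, t_use, or the scaler", {
  fx <- make_prep()
  prep <- fx$prep
  g <- prep$groups
  ids <- prep$ids
  train <- c(names(g)[g == "remission"][1:6], names(g)[g == "HC"][1:6])
  test <- setdiff(ids, train)
  run_fold <- function(prep) {
    rois <- define_abnormal_rois(
      prep$zmaps$go_minus_nogo[intersect(train, names(g)[g == "remission"])],
      prep$zmaps$go_minus_nogo[intersect(train, names(g)[g == "HC"])],
      prep$atlas)
    ts <- function(id) extract_roi_timeseries(prep$bold[[id]], rois)
    fm <- build_feature_matrix(setNames(lapply(train, ts), train),
                               setNames(lapply(test, ts), test))
    list(rois = rois, fm = fm)
  }
  ref <- run_fold(prep)
  # perturb every TEST subject's data (maps and bold) drastically
  pert <- prep
  for (id in test) {
    pert$bold[[id]]$data <- pert$bold[[id]]$data * 5 + 100
    pm <- pert$zmaps$go_minus_nogo[[id]]
    pm$values <- pm$values + 50
    pert$zmaps$go_minus_nogo[[id]] <- pm
  }
  alt <- run_fold(pert)
  expect_identical(alt$rois$roi_table, ref$rois$roi_table)
  expect_identical(alt$rois$voxels, ref$rois$voxels)
  expect_identical(alt$fm$t_use, ref$fm$t_use)
  expect_identical(alt$fm$scaler_params, ref$fm$scaler_params)
  # TRAIN rows unchanged; TEST rows change (sanity of the perturbation)
  expect_identical(alt$fm$x[train, ], ref$fm$x[train, ])
  expect_false(isTRUE(all.equal(alt$fm$x[test, ], ref$fm$x[test, ])))
})
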