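#' Voxelwise second-level regression of activation on a clinical metric
#'
#' Per voxel, simple linear regression (intercept + slope) of the
#' subjects' contrast-map values on the metric; the slope t statistic
#' (df n - 2) is converted to z. The design has exactly two columns:
#' no covariate adjustment, by design.
#'
#' @param maps list of first-level [stat_map()]s (one per subject).
#' @param metric numeric vector of the clinical/behavioral score.
#' @return a [stat_map()] with the per-subject residual maps attached
#'   for smoothness estimation.
#' @export
voxelwise_metric_regression <- function(maps, metric) {
  n <- length(maps)
  if (n < 3L) stopf("need >= 3 subjects")
  if (length(metric) != n) stopf("metric length != number of maps")
  if (stats::sd(metric) == 0) stopf("metric has zero variance")
  d <- dim(maps[[1L]]$values)
  Y <- vapply(maps, function(m) as.vector(m$values), numeric(prod(d)))
  x <- metric - mean(metric)
  sxx <- sum(x^2)
  ybar <- rowMeans(Y)
  slope <- (Y %*% x) / sxx
  fitted <- ybar + slope %*% t(x)
  res <- Y - fitted
  df <- n - 2L
  s2 <- rowSums(res^2) / df
  se <- sqrt(s2 / sxx)
  tstat <- ifelse(se > 0, drop(slope) / pmax(se, .Machine$double.xmin), 0)
  z <- array(t_to_z(tstat, df), d)
  out <- stat_map(z, df, maps[[1L]]$contrast, "second")
  attr(out, "residuals") <- lapply(seq_len(n), function(i) array(res[, i], d))
  out
}

#' Cluster-mean activation and per-cluster linear fits
#'
#' For each surviving cluster: the subject-level mean activation over
#' the cluster's voxels is regressed against the metric with both
#' variables standardized, so the standardized coefficient equals the
#' Pearson correlation; two-sided p from the t distribution (df n - 2).
#' Clusters are labelled anatomically by the atlas region(s) with
#' majority overlap.
#'
#' @param cluster_set a [grf_cluster_correct()] result.
#' @param maps list of subject [stat_map()]s.
#' @param metric numeric score vector.
#' @param metric_name name recorded in the rows.
#' @param atlas optional `fmri_atlas` for anatomical labels.
#' @return data.frame: cluster, size, label, metric, beta, p.
#' @export
cluster_mean_and_fit <- function(cluster_set, maps, metric,
                                 metric_name = "metric", atlas = NULL) {
  if (nrow(cluster_set$clusters) == 0L) stopf("no surviving clusters")
  n <- length(maps)
  d <- dim(maps[[1L]]$values)
  Y <- vapply(maps, function(m) as.vector(m$values), numeric(prod(d)))
  rows <- lapply(seq_along(cluster_set$voxels), function(ci) {
    vox <- cluster_set$voxels[[ci]]
    cmean <- colMeans(Y[vox, , drop = FALSE])
    r <- stats::cor(cmean, metric)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
    lab <- "unlabelled"
    if (!is.null(atlas)) {
      regs <- as.vector(atlas$labels)[vox]
      regs <- regs[regs > 0]
      lab <- if (length(regs)) atlas$names[as.integer(names(which.max(table(regs))))]
             else "background"
    }
    data.frame(cluster = cluster_set$clusters$label[ci],
               size = length(vox), label = lab, metric = metric_name,
               beta = r, p = p)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg q-values with discovery flags
#'
#' Step-up BH q-values (monotonicity enforced) computed within one
#' contrast/mood-state/group block; discovery iff q < `q_level`.
#'
#' @param p numeric p-values in [0, 1].
#' @param q_level FDR level.
#' @return data.frame with `p`, `q`, `discovery`.
#' @export
bh_fdr <- function(p, q_level = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q = q, discovery = q < q_level)
}

#' Brain-behavior association analysis for one group block
#'
#' For each metric: voxelwise regression of the subjects' contrast maps
#' on the metric, GRF cluster correction (smoothness estimated from the
#' regression residuals), cluster-mean extraction, per-cluster
#' standardized linear fits, and BH-FDR across all (cluster, metric)
#' rows of the block. Blocks (one per contrast / mood-state / group) are
#' always fit separately; no pooled model exists.
#'
#' @param maps list of subject [stat_map()]s for the block's subjects.
#' @param clinical data.frame or matrix, subjects x metrics.
#' @param atlas optional `fmri_atlas` for labels.
#' @param voxel_p,cluster_p,min_extent GRF thresholds.
#' @param q_level FDR level.
#' @param block_name label of the (contrast, mood-state, group) block.
#' @return an object of class `association_result`: data.frame rows
#'   (cluster, size, label, metric, beta, p, q, discovery); zero rows
#'   when no clusters survive for any metric.
#' @export
clinical_association <- function(maps, clinical, atlas = NULL,
                                 voxel_p = 0.001, cluster_p = 0.05,
                                 min_extent = 10L, q_level = 0.05,
                                 block_name = "block") {
  clinical <- as.data.frame(clinical)
  stopifnot(nrow(clinical) == length(maps))
  rows <- list()
  for (m in names(clinical)) {
    metric <- clinical[[m]]
    zmap <- voxelwise_metric_regression(maps, metric)
    sm <- estimate_smoothness(attr(zmap, "residuals"))
    cs <- grf_cluster_correct(zmap, sm, voxel_p = voxel_p,
                              cluster_p = cluster_p, min_extent = min_extent)
    if (nrow(cs$clusters) == 0L) next
    rows[[length(rows) + 1L]] <-
      cluster_mean_and_fit(cs, maps, metric, metric_name = m, atlas = atlas)
  }
  if (!length(rows)) {
    tab <- data.frame(cluster = integer(), size = integer(),
                      label = character(), metric = character(),
                      beta = numeric(), p = numeric(), q = numeric(),
                      discovery = logical())
  } else {
    tab <- do.call(rbind, rows)
    fdr <- bh_fdr(tab$p, q_level)
    tab$q <- fdr$q
    tab$discovery <- fdr$discovery
  }
  structure(list(block = block_name, table = tab, q_level = q_level),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> block '%s': %d row(s), %d discover%s at q < %g\n",
              x$block, nrow(x$table), sum(x$table$discovery),
              ifelse(sum(x$table$discovery) == 1, "y", "ies"), x$q_level))
  if (nrow(x$table)) print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
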