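#' The six canonical task contrasts
#'
#' Weight vectors over the (Go, NoGo, Neutral) conditions for the six
#' analysis conditions: the emotion-specific Go-NoGo contrast, the
#' combined emotional condition Go+NoGo, the two versus-neutral
#' contrasts, and the two single conditions.
#'
#' @return named list of numeric weight vectors.
#' @export
contrast_specs <- function() {
  list(go_minus_nogo    = c(Go = 1, NoGo = -1, Neutral = 0),
       go_plus_nogo     = c(Go = 1, NoGo = 1, Neutral = 0),
       go_minus_neutral = c(Go = 1, NoGo = 0, Neutral = -1),
       nogo_minus_neutral = c(Go = 0, NoGo = 1, Neutral = -1),
       go               = c(Go = 1, NoGo = 0, Neutral = 0),
       nogo             = c(Go = 0, NoGo = 1, Neutral = 0))
}

#' First-level design matrix
#'
#' One column per condition (its event boxcar convolved with the
#' canonical HRF, sampled at volume acquisition times) plus an intercept.
#'
#' @param events data.frame with `onset`, `duration`, `condition`.
#' @param tr_s repetition time (s).
#' @param n_volumes number of volumes.
#' @param conditions condition names, in design order.
#' @return numeric matrix, volumes x (conditions + 1).
#' @export
first_level_design <- function(events, tr_s, n_volumes,
                               conditions = c("Go", "NoGo", "Neutral")) {
  if (nrow(events) && max(events$onset) >= n_volumes * tr_s)
    stopf("event onsets exceed scan duration")
  cols <- vapply(conditions, function(cn) {
    ev <- events[events$condition == cn, , drop = FALSE]
    if (nrow(ev) == 0L) stopf("condition '%s' has no events", cn)
    convolve_condition(ev$onset, ev$duration, tr_s, n_volumes)
  }, numeric(n_volumes))
  cbind(cols, intercept = 1)
}

# Stable t -> z via the probability integral transform; log-space tails
# avoid infinities at high |t| and df.
t_to_z <- function(t, df) {
  z <- sign(t) * stats::qnorm(stats::pt(abs(t), df, lower.tail = FALSE,
                                        log.p = TRUE),
                              lower.tail = FALSE, log.p = TRUE)
  z[t == 0] <- 0
  z
}

#' 3D z-statistic map container
#'
#' @param values 3D numeric array of z values.
#' @param df degrees of freedom used for the t-to-z conversion.
#' @param contrast contrast name.
#' @param level `"first"` or `"second"`.
#' @return an object of class `stat_map`.
#' @export
stat_map <- function(values, df, contrast, level) {
  structure(list(values = values, df = df, contrast = contrast, level = level),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s-level '%s': %s grid, df %.1f, |z| max %.2f\n",
              x$level, x$contrast, paste(dim(x$values), collapse = "x"),
              x$df, max(abs(x$values))))
  invisible(x)
}

#' First-level contrast z-map
#'
#' Ordinary least squares per voxel; the contrast t statistic
#' \eqn{t = c'\hat\beta / \sqrt{\hat\sigma^2 c'(X'X)^{-1}c}} is converted
#' to z through the t CDF. Voxels with zero residual variance get z = 0
#' (counted in attribute `n_zero_variance`).
#'
#' @param bold a preprocessed [volume_series()].
#' @param design matrix from [first_level_design()].
#' @param contrast named weight vector over conditions (a
#'   [contrast_specs()] entry); padded with 0 for the intercept.
#' @param contrast_name label stored in the map.
#' @return a [stat_map()].
#' @export
first_level_zmap <- function(bold, design, contrast,
                             contrast_name = deparse(substitute(contrast))) {
  d <- dim(bold$data)
  n <- d[4L]
  if (nrow(design) != n) stopf("design rows != volumes")
  Y <- t(matrix(bold$data, prod(d[1:3]), n))
  cvec <- numeric(ncol(design))
  names(cvec) <- colnames(design)
  cvec[names(contrast)] <- contrast
  XtXi <- solve(crossprod(design))
  B <- XtXi %*% crossprod(design, Y)
  res <- Y - design %*% B
  df <- n - qr(design)$rank
  s2 <- colSums(res^2) / df
  # zero residual variance up to floating point relative to the data scale
  zero_var <- s2 <= 1e-20 * pmax(colMeans(Y^2), 1)
  se2 <- s2 * drop(t(cvec) %*% XtXi %*% cvec)
  eff <- drop(cvec %*% B)
  tstat <- ifelse(zero_var, 0, eff / sqrt(pmax(se2, .Machine$double.xmin)))
  nzv <- sum(zero_var)
  if (nzv > 0)
    message(sprintf("first_level_zmap: %d zero-residual-variance voxels set to z = 0", nzv))
  z <- array(t_to_z(tstat, df), d[1:3])
  out <- stat_map(z, df, contrast_name, "first")
  attr(out, "n_zero_variance") <- nzv
  out
}

#' Second-level two-sample group z-map
#'
#' Voxelwise two-sample comparison (group-indicator GLM with pooled
#' variance) of first-level z-maps, with the sign convention group A
#' minus group B (patients minus controls). Returns the residual maps as
#' attribute `residuals` for smoothness estimation.
#'
#' @param maps_a,maps_b lists of first-level [stat_map()]s.
#' @param contrast_name label stored in the map.
#' @return a [stat_map()] with df `nA + nB - 2`.
#' @export
second_level_zmap <- function(maps_a, maps_b,
                              contrast_name = maps_a[[1L]]$contrast) {
  na <- length(maps_a); nb <- length(maps_b)
  if (na < 2L || nb < 2L) stopf("need >= 2 subjects per group (got %d, %d)", na, nb)
  d <- dim(maps_a[[1L]]$values)
  A <- vapply(maps_a, function(m) as.vector(m$values), numeric(prod(d)))
  B <- vapply(maps_b, function(m) as.vector(m$values), numeric(prod(d)))
  ma <- rowMeans(A); mb <- rowMeans(B)
  ssa <- rowSums((A - ma)^2); ssb <- rowSums((B - mb)^2)
  df <- na + nb - 2L
  sp2 <- (ssa + ssb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, (ma - mb) / pmax(se, .Machine$double.xmin), 0)
  z <- array(t_to_z(tstat, df), d)
  out <- stat_map(z, df, contrast_name, "second")
  attr(out, "residuals") <- lapply(seq_len(na + nb), function(i) {
    if (i <= na) array(A[, i] - ma, d) else array(B[, i - na] - mb, d)
  })
  out
}
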