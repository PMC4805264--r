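# Two-stage dual regression: templates + 4D series -> subject time courses
# and spatial maps. All regressions are joint multiple regressions; running
# networks one at a time would let shared variance leak between them.

flatten4d <- function(x) {
  d <- dim(x)
  matrix(x, prod(d[1:3]), d[4])
}

mask_vector <- function(bold) {
  d <- dim(bold$data)
  if (is.null(bold$mask)) rep(TRUE, prod(d[1:3]))
  else {
    m <- as.logical(bold$mask)
    if (length(m) != prod(d[1:3]))
      stop("mask does not match the BOLD grid")
    m
  }
}

check_grids <- function(bold, templates) {
  bd <- dim(bold$data)[1:3]
  td <- templates$grid_dims
  if (!identical(as.integer(bd), as.integer(td)))
    stop(sprintf("BOLD grid %s does not match template grid %s",
                 paste(bd, collapse = "x"), paste(td, collapse = "x")))
}

check_template_rank <- function(X, names) {
  p <- ncol(X)
  if (qr(X)$rank < p) {
    r <- suppressWarnings(stats::cor(X))
    r[!is.finite(r)] <- 1
    diag(r) <- 0
    idx <- which(abs(r) == max(abs(r)), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "template maps are rank deficient over the mask; most collinear pair: %s and %s (|r| = %.3f)",
      names[idx[1]], names[idx[2]], max(abs(r))))
  }
}

#' Stage 1: spatial regression of each volume on the template maps
#'
#' For every time point, the masked volume is regressed jointly on all
#' template maps by ordinary least squares. Each voxel's time series is
#' demeaned over time and the design (template maps) is demeaned over masked
#' voxels, so no intercept column is needed. The fitted coefficients over
#' time are the subject's network time courses.
#'
#' @param bold a `bold4d` (see [simulate_bold()] or [read_volume()] plus
#'   labels).
#' @param templates a `template_set` on the same grid.
#' @return an object of class `time_courses`: `values` (matrix `t` by
#'   `network`), `names`, `variance_normalized = FALSE`.
#' @export
stage1_spatial_regression <- function(bold, templates) {
  check_grids(bold, templates)
  mv <- mask_vector(bold)
  Y <- flatten4d(bold$data)[mv, , drop = FALSE]
  if (anyNA(Y)) stop("BOLD data contain NA within the mask")
  X <- matrix(templates$maps, prod(templates$grid_dims),
              dim(templates$maps)[4])[mv, , drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  check_template_rank(X, templates$names)
  Y <- Y - rowMeans(Y)               # voxelwise demeaning over time
  Y <- sweep(Y, 2, colMeans(Y))      # per-volume demeaning over the mask
  tc <- crossprod(Y, X) %*% chol2inv(chol(crossprod(X)))
  colnames(tc) <- templates$names
  structure(list(values = tc, names = templates$names,
                 variance_normalized = FALSE),
            class = "time_courses")
}

#' Variance-normalise network time courses
#'
#' Scales each time course to unit sample variance (constant columns are
#' left untouched), the conventional normalisation before the temporal
#' stage so that spatial-map units are comparable across subjects.
#'
#' @param tcs a `time_courses` object.
#' @return the same object with unit-variance columns and
#'   `variance_normalized = TRUE`.
#' @export
variance_normalize <- function(tcs) {
  v <- tcs$values
  sds <- apply(v, 2, stats::sd)
  keep <- sds > 0
  v[, keep] <- sweep(v[, keep, drop = FALSE], 2, sds[keep], `/`)
  tcs$values <- v
  tcs$variance_normalized <- TRUE
  tcs
}

#' Stage 2: temporal regression of each voxel on the network time courses
#'
#' Per voxel, the demeaned time series is regressed jointly on all demeaned
#' (and typically variance-normalised) time courses. Returns the coefficient
#' (beta) maps and Z maps, where Z is the OLS t-statistic beta / SE(beta)
#' with residual degrees of freedom `t - n_networks - 1`. Voxels with a
#' constant time series get beta = Z = 0 by convention, which keeps
#' downstream threshold masks well defined. Voxels outside the mask are 0.
#'
#' @param bold a `bold4d`.
#' @param tcs a `time_courses` whose length matches the series.
#' @param convert_to_z if `TRUE`, map each t-statistic through its exact
#'   t-distribution quantile to a standard-normal deviate. At 150 time
#'   points the difference is negligible and the default keeps the raw
#'   t-statistic, whose sign (all that a Z>0 threshold uses) is identical.
#' @return an object of class `subject_network_maps`: `beta` and `zmap`
#'   arrays (`x,y,z,network`), `networks`, `subject_id`, `session`, `group`,
#'   `df`.
#' @export
stage2_temporal_regression <- function(bold, tcs, convert_to_z = FALSE) {
  v <- tcs$values
  d <- dim(bold$data)
  tt <- d[4]
  p <- ncol(v)
  if (nrow(v) != tt)
    stop(sprintf("time courses have %d rows but the series has %d volumes",
                 nrow(v), tt))
  if (tt <= p + 1L)
    stop(sprintf(
      "temporal regression needs t > n_networks + 1 (t = %d, networks = %d): no residual degrees of freedom",
      tt, p))
  mv <- mask_vector(bold)
  Xc <- sweep(v, 2, colMeans(v))
  check_template_rank(Xc, tcs$names)
  G <- crossprod(Xc)
  Ginv <- chol2inv(chol(G))

  Y <- t(flatten4d(bold$data)[mv, , drop = FALSE])   # t x Vm
  if (anyNA(Y)) stop("BOLD data contain NA within the mask")
  Y <- sweep(Y, 2, colMeans(Y))
  B <- Ginv %*% crossprod(Xc, Y)                      # p x Vm
  resid <- Y - Xc %*% B
  df <- tt - p - 1L
  sigma2 <- pmax(colSums(resid^2) / df, 1e-300)
  se <- sqrt(outer(diag(Ginv), sigma2))
  Z <- B / se
  constant <- colSums(Y^2) == 0
  B[, constant] <- 0
  Z[, constant] <- 0
  # Coefficients indistinguishable from zero at double precision are exact
  # zeros: a sign threshold (Z > 0) must not pick up floating-point noise.
  floor_b <- 1e-10 * apply(abs(B), 1, max)
  tiny <- abs(B) < floor_b
  B[tiny] <- 0
  Z[tiny] <- 0
  if (convert_to_z) {
    lp <- stats::pt(-abs(Z), df, log.p = TRUE)
    Z <- sign(Z) * (-stats::qnorm(lp, log.p = TRUE))
  }

  V <- prod(d[1:3])
  beta <- zmap <- matrix(0, V, p)
  beta[mv, ] <- t(B)
  zmap[mv, ] <- t(Z)
  structure(list(beta = array(beta, c(d[1:3], p)),
                 zmap = array(zmap, c(d[1:3], p)),
                 networks = tcs$names,
                 subject_id = bold$subject_id,
                 session = bold$session,
                 group = bold$group,
                 df = df),
            class = "subject_network_maps")
}

#' Dual regression: templates + BOLD -> subject-specific network maps
#'
#' Composition of the two stages: spatial regression for time courses,
#' variance normalisation, then temporal regression for beta and Z maps.
#' Deterministic; Z maps are invariant to affine rescaling of the input
#' data because the normalised time courses absorb the scale.
#'
#' @inheritParams stage1_spatial_regression
#' @inheritParams stage2_temporal_regression
#' @return a `subject_network_maps` with the stage-1 `time_courses`
#'   attached as attribute `"time_courses"`.
#' @export
#' @examples
#' cfg <- simulation_config(grid_dims = c(12, 12, 12), n_networks = 3,
#'                          n_subjects_per_group = 2, n_timepoints = 40,
#'                          seed = 7)
#' tpl <- make_templates(cfg)
#' truth <- simulate_ground_truth(tpl, cfg)
#' maps <- dual_regress(simulate_bold(truth, tpl, cfg, 1, "BL"), tpl)
#' dim(maps$zmap)
dual_regress <- function(bold, templates, convert_to_z = FALSE) {
  tcs <- variance_normalize(stage1_spatial_regression(bold, templates))
  maps <- stage2_temporal_regression(bold, tcs, convert_to_z = convert_to_z)
  attr(maps, "time_courses") <- tcs
  maps
}

#' @export
print.subject_network_maps <- function(x, ...) {
  d <- dim(x$beta)
  cat(sprintf("<subject_network_maps> %s / %s: %d networks on %s grid (df = %d)\n",
              x$subject_id %||% "?", x$session %||% "?", d[4],
              paste(d[1:3], collapse = "x"), x$df))
  invisible(x)
}
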