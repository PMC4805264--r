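#' Configuration for a synthetic two-session resting-state study
#'
#' Bundles every knob of the synthetic-data generator: grid and network
#' geometry, the two-group / two-session design, acquisition length, and the
#' variance components that control reliability. The defaults emulate the
#' design of a longitudinal 3T study of stable relapsing-remitting multiple
#' sclerosis: 14 healthy controls (HC) and 20 patients (MS), scanned at
#' baseline (BL) and 3-month follow-up (FU), 150 volumes at TR = 3 s, nine
#' resting-state networks.
#'
#' The generative model for the spatial map of network `j` in subject `i`,
#' session `s` is
#' \deqn{map_{ijs} = template_j \cdot (1 + b_{ij} + w_{ijs} + \delta\,1[s=FU])}
#' with `b ~ N(0, sigma_between^2)` drawn once per subject x network and
#' `w ~ N(0, sigma_within^2)` per subject x session x network; `delta`
#' (`session_shift`) is a fixed multiplicative session effect shared by all
#' networks. The BOLD series mixes these maps with independent unit-normal
#' time courses plus `N(0, sigma_noise^2)` sensor noise.
#'
#' @param grid_dims integer vector of length 3, voxels per axis.
#' @param n_networks number of template networks.
#' @param n_subjects_per_group subjects per group; a named vector such as
#'   `c(HC = 14, MS = 20)`, or a single integer applied to both groups.
#' @param n_timepoints volumes per session (default 150).
#' @param tr_seconds repetition time in seconds (default 3).
#' @param sigma_between SD of the between-subject amplitude perturbation `b`.
#' @param sigma_within SD of the between-session perturbation `w`; scalar or
#'   named per-group vector (patient groups typically get the larger value).
#' @param sigma_noise temporal Gaussian noise SD of the BOLD mixture.
#' @param session_shift fixed additive session effect on the amplitude at
#'   follow-up (default 0 = no systematic session difference).
#' @param blob_sigma Gaussian radius (voxels) of each template blob; default
#'   `max(1.5, min(grid_dims)/10)`.
#' @param z_peak peak value of each template map in Z-like units.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   datasets.
#' @return an object of class `simulation_config` (a validated list).
#' @seealso [make_templates()], [simulate_ground_truth()], [simulate_bold()]
#' @export
#' @examples
#' cfg <- simulation_config(grid_dims = c(12, 12, 12), n_networks = 3,
#'                          n_subjects_per_group = 4, n_timepoints = 40)
#' cfg$n_timepoints
simulation_config <- function(grid_dims = c(16L, 16L, 16L),
                              n_networks = 9L,
                              n_subjects_per_group = c(HC = 14L, MS = 20L),
                              n_timepoints = 150L,
                              tr_seconds = 3,
                              sigma_between = 0.5,
                              sigma_within = c(HC = 0.05, MS = 0.1),
                              sigma_noise = 6,
                              session_shift = 0,
                              blob_sigma = NULL,
                              z_peak = 4,
                              seed = 1L) {
  if (length(n_subjects_per_group) == 1L && is.null(names(n_subjects_per_group)))
    n_subjects_per_group <- c(HC = n_subjects_per_group, MS = n_subjects_per_group)
  cfg <- list(grid_dims = as.integer(grid_dims),
              n_networks = as.integer(n_networks),
              n_subjects_per_group = as.integer(round(n_subjects_per_group)),
              n_timepoints = as.integer(n_timepoints),
              tr_seconds = as.numeric(tr_seconds),
              sigma_between = as.numeric(sigma_between),
              sigma_within = sigma_within,
              sigma_noise = as.numeric(sigma_noise),
              session_shift = as.numeric(session_shift),
              blob_sigma = blob_sigma,
              z_peak = as.numeric(z_peak),
              seed = as.integer(seed))
  names(cfg$n_subjects_per_group) <- names(n_subjects_per_group)
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (length(cfg$grid_dims) != 3L || any(cfg$grid_dims < 1L))
    stop("grid_dims must be 3 positive integers")
  if (cfg$n_networks < 1L) stop("n_networks must be >= 1")
  if (any(cfg$n_subjects_per_group < 1L))
    stop("n_subjects_per_group entries must be >= 1")
  if (is.null(names(cfg$n_subjects_per_group)))
    stop("n_subjects_per_group must be named by group (e.g. c(HC = 14, MS = 20))")
  if (cfg$n_timepoints < 1L) stop("n_timepoints must be >= 1")
  if (cfg$tr_seconds <= 0) stop("tr_seconds must be positive")
  sds <- c(cfg$sigma_between, unlist(cfg$sigma_within), cfg$sigma_noise)
  if (any(sds < 0)) stop("all SDs (sigma_between, sigma_within, sigma_noise) must be >= 0")
  if (length(cfg$sigma_within) > 1L &&
      !all(names(cfg$n_subjects_per_group) %in% names(cfg$sigma_within)))
    stop("per-group sigma_within must be named for every group")
  invisible(cfg)
}

group_sigma_within <- function(cfg, group) {
  sw <- cfg$sigma_within
  if (length(sw) == 1L) return(as.numeric(sw))
  as.numeric(sw[[group]])
}

# Canonical network labels: the nine-network case gets the standard
# resting-state network names, anything else a generic numbered label.
default_network_names <- function(n) {
  if (n == 9L)
    c("visual_00", "visual_01", "visual_02", "dmn", "sensorimotor",
      "auditory", "executive_control", "frontoparietal_left",
      "frontoparietal_right")
  else
    sprintf("net%02d", seq_len(n) - 1L)
}

#' Generate a stack of synthetic network template maps
#'
#' Places `n_networks` smooth Gaussian blobs at well-separated lattice
#' positions on the voxel grid, truncates each at 3 blob radii (compact
#' support, so "the entire network" has a well-defined footprint), scales to
#' unit peak and then to `z_peak` Z-like units. Blob separation of at least
#' three radii keeps every pairwise spatial correlation below 0.5, so the
#' templates form a usable regression dictionary.
#'
#' @param config a [simulation_config()].
#' @return an object of class `template_set`: list with `maps` (numeric array
#'   `x` by `y` by `z` by `network`, matching the NIfTI convention of volume
#'   index last), `names`, `grid_dims`, `affine` (4x4 voxel-to-world, 2 mm
#'   isotropic), `blob_sigma`, `centres`.
#' @export
#' @examples
#' tpl <- make_templates(simulation_config(grid_dims = c(16, 16, 16),
#'                                         n_networks = 3, seed = 7))
#' dim(tpl$maps)
make_templates <- function(config) {
  validate_config(config)
  dims <- config$grid_dims
  sigma <- config$blob_sigma %||% max(1.5, min(dims) / 10)
  spacing <- max(3L, as.integer(ceiling(3 * sigma)))
  npos <- pmax(floor(dims / spacing), 0L)
  if (prod(npos) < config$n_networks)
    stop(sprintf(paste0(
      "grid %s cannot hold %d separable networks: blob sd %.2f requires ",
      "centre spacing %d voxels, leaving only %d slots; enlarge the grid ",
      "or shrink blob_sigma / n_networks"),
      paste(dims, collapse = "x"), config$n_networks, sigma, spacing,
      prod(npos)))
  centres <- as.matrix(expand.grid(lapply(1:3, function(a) {
    offset <- (dims[a] - npos[a] * spacing) / 2
    offset + (seq_len(npos[a]) - 0.5) * spacing + 0.5
  })))
  ord <- with_preserved_seed(derive_seed(config$seed, 1L),
                             sample.int(nrow(centres)))
  centres <- centres[ord[seq_len(config$n_networks)], , drop = FALSE]
  colnames(centres) <- c("x", "y", "z")

  ax <- lapply(1:3, function(a) seq_len(dims[a]))
  maps <- array(0, dim = c(dims, config$n_networks))
  for (j in seq_len(config$n_networks)) {
    d2 <- outer(outer((ax[[1]] - centres[j, 1])^2,
                      (ax[[2]] - centres[j, 2])^2, `+`),
                (ax[[3]] - centres[j, 3])^2, `+`)
    blob <- exp(-d2 / (2 * sigma^2))
    blob[d2 > (3 * sigma)^2] <- 0         # compact support at 3 radii
    maps[, , , j] <- blob / max(blob) * config$z_peak
  }
  out <- list(maps = maps,
              names = default_network_names(config$n_networks),
              grid_dims = dims,
              affine = diag(c(2, 2, 2, 1)),
              blob_sigma = sigma,
              centres = centres)
  class(out) <- "template_set"
  flat <- matrix(maps, prod(dims), config$n_networks)
  if (config$n_networks > 1L) {
    r <- stats::cor(flat)
    off <- abs(r[upper.tri(r)])
    if (any(off >= 0.5))
      stop("internal error: template maps are not separable (|cor| >= 0.5)")
  }
  if (any(colSums(flat > 0) == 0L))
    stop("internal error: a template map has no positive voxel")
  out
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d networks on %s grid (blob sd %.2f voxels)\n",
              length(x$names), paste(x$grid_dims, collapse = "x"),
              x$blob_sigma))
  cat("  networks:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Draw ground-truth subject/session network maps
#'
#' Realises the generative model: each subject's map of network `j` in
#' session `s` is the template scaled by `1 + b_ij + w_ijs` plus the fixed
#' follow-up shift. The amplitude draws are recorded so parameter-recovery
#' tests can compare estimates against truth.
#'
#' @param templates a [make_templates()] result.
#' @param config the matching [simulation_config()].
#' @return an object of class `ground_truth`: `subject_maps` (array `x,y,z,
#'   network, session, subject`), `subject_amplitudes` (array `subject,
#'   session, network`), `group_labels`, `subject_ids`, `sessions`
#'   (`c("BL","FU")`).
#' @export
simulate_ground_truth <- function(templates, config) {
  validate_config(config)
  if (!identical(as.integer(templates$grid_dims), config$grid_dims))
    stop(sprintf("template grid %s does not match config grid %s",
                 paste(templates$grid_dims, collapse = "x"),
                 paste(config$grid_dims, collapse = "x")))
  if (dim(templates$maps)[4] != config$n_networks)
    stop(sprintf("templates hold %d networks but config declares %d",
                 dim(templates$maps)[4], config$n_networks))
  groups <- names(config$n_subjects_per_group)
  group_labels <- rep(groups, times = config$n_subjects_per_group)
  n_total <- length(group_labels)
  subject_ids <- unlist(lapply(groups, function(g)
    sprintf("%s%02d", g, seq_len(config$n_subjects_per_group[[g]]))))
  J <- config$n_networks
  sessions <- c("BL", "FU")

  amps <- with_preserved_seed(derive_seed(config$seed, 2L), {
    b <- matrix(stats::rnorm(n_total * J, sd = config$sigma_between),
                n_total, J)
    a <- array(0, dim = c(n_total, 2L, J))
    for (i in seq_len(n_total)) {
      sw <- group_sigma_within(config, group_labels[i])
      for (s in 1:2) {
        w <- stats::rnorm(J, sd = sw)
        a[i, s, ] <- 1 + b[i, ] + w + config$session_shift * (s == 2L)
      }
    }
    a
  })

  subject_maps <- array(0, dim = c(config$grid_dims, J, 2L, n_total))
  for (i in seq_len(n_total))
    for (s in 1:2)
      for (j in seq_len(J))
        subject_maps[, , , j, s, i] <- templates$maps[, , , j] * amps[i, s, j]

  out <- list(subject_maps = subject_maps,
              subject_amplitudes = amps,
              group_labels = group_labels,
              subject_ids = subject_ids,
              sessions = sessions)
  class(out) <- "ground_truth"
  out
}

#' Simulate one subject-session 4D BOLD series
#'
#' Forms the low-rank mixture `data(x,y,z,t) = sum_j map_j(x,y,z) c_j(t) +
#' noise`, with one independent standard-normal time course per network and
#' i.i.d. Gaussian sensor noise. The time courses are attached to the result
#' (`$time_courses`) so time-course recovery can be checked. Seeding is per
#' subject-session, so any single series can be regenerated without
#' simulating the whole study.
#'
#' @param truth a [simulate_ground_truth()] result.
#' @param templates the matching [make_templates()] result.
#' @param config the matching [simulation_config()].
#' @param subject subject index or subject id.
#' @param session `"BL"`/`"FU"` or session index 1/2.
#' @return an object of class `bold4d`: `data` (array `x,y,z,t`),
#'   `tr_seconds`, `subject_id`, `session`, `group`, `mask` (NULL = whole
#'   grid), `time_courses` (matrix `t` by `network`).
#' @export
simulate_bold <- function(truth, templates, config, subject, session) {
  validate_config(config)
  i <- if (is.character(subject)) match(subject, truth$subject_ids)
       else as.integer(subject)
  if (is.na(i) || i < 1L || i > length(truth$subject_ids))
    stop("unknown subject: ", subject)
  s <- if (is.character(session)) match(session, truth$sessions)
       else as.integer(session)
  if (is.na(s) || !s %in% 1:2) stop("session must be BL/FU (or 1/2)")

  J <- dim(truth$subject_maps)[4]
  tt <- config$n_timepoints
  V <- prod(config$grid_dims)
  M <- matrix(truth$subject_maps[, , , , s, i], V, J)
  dat <- with_preserved_seed(derive_seed(config$seed, 3L, i, s), {
    tc <- matrix(stats::rnorm(tt * J), tt, J)
    y <- M %*% t(tc)
    if (config$sigma_noise > 0)
      y <- y + matrix(stats::rnorm(V * tt, sd = config$sigma_noise), V, tt)
    list(y = y, tc = tc)
  })
  out <- list(data = array(dat$y, dim = c(config$grid_dims, tt)),
              tr_seconds = config$tr_seconds,
              subject_id = truth$subject_ids[i],
              session = truth$sessions[s],
              group = truth$group_labels[i],
              mask = NULL,
              time_courses = dat$tc)
  class(out) <- "bold4d"
  out
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold4d> %s / %s (%s): %s grid, %d volumes, TR %.1f s\n",
              x$subject_id, x$session, x$group,
              paste(d[1:3], collapse = "x"), d[4], x$tr_seconds))
  invisible(x)
}

#' Write a simulated study to disk as NIfTI volumes plus manifest
#'
#' Writes one gzipped 4D NIfTI per subject-session, the template stack as a
#' single 4D NIfTI (volume index = network), a CSV manifest
#' (`subject_id, group, session, path` with paths relative to the manifest),
#' and the configuration as YAML. Volumes are stored as float32, the NIfTI
#' convention; in-memory arithmetic stays double.
#'
#' @param truth,templates,config matched simulation objects.
#' @param directory output directory (created if needed).
#' @return invisibly, the manifest data frame (also saved as
#'   `manifest.csv`).
#' @export
write_dataset <- function(truth, templates, config, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  write_volume(templates$maps, file.path(directory, "templates.nii.gz"),
               affine = templates$affine)
  rows <- list()
  for (i in seq_along(truth$subject_ids)) {
    for (s in 1:2) {
      bold <- simulate_bold(truth, templates, config, i, s)
      fn <- sprintf("sub-%s_ses-%s_bold.nii.gz", bold$subject_id,
                    bold$session)
      write_volume(bold$data, file.path(directory, fn),
                   affine = templates$affine)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = bold$subject_id, group = bold$group,
        session = bold$session, path = fn, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  cfg <- unclass(config)
  cfg$sigma_within <- as.list(cfg$sigma_within)
  cfg$n_subjects_per_group <- as.list(cfg$n_subjects_per_group)
  yaml::write_yaml(cfg, file.path(directory, "config.yaml"))
  invisible(manifest)
}
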