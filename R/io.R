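# Volume and manifest I/O plus the end-to-end pipeline driver.

#' Read a NIfTI volume
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param expected_grid optional integer vector; if the first three
#'   dimensions differ an error names both shapes.
#' @return numeric array with the 4x4 voxel-to-world transform attached as
#'   attribute `"affine"`.
#' @export
read_volume <- function(path, expected_grid = NULL) {
  if (!file.exists(path)) stop("no such volume: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  affine <- structure(RNifti::xform(img), class = NULL)
  if (!is.null(expected_grid) &&
      !identical(as.integer(dim(arr)[1:3]), as.integer(expected_grid[1:3])))
    stop(sprintf("volume %s has grid %s, expected %s", path,
                 paste(dim(arr)[1:3], collapse = "x"),
                 paste(expected_grid[1:3], collapse = "x")))
  attr(arr, "affine") <- affine
  arr
}

#' Write a NIfTI volume
#'
#' Stores the array as float32 by default (the NIfTI convention for
#' statistical maps and BOLD data); masks should be written with
#' `datatype = "uint8"`.
#'
#' @param volume 3D or 4D numeric/logical array.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-world transform.
#' @param datatype on-disk datatype, e.g. `"float"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, affine = diag(c(2, 2, 2, 1)),
                         datatype = "float") {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  img <- RNifti::asNifti(volume + 0)  # logical -> numeric
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a network mask as a uint8 NIfTI
#'
#' @param mask a `network_mask`.
#' @param path output file.
#' @param affine 4x4 voxel-to-world transform.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, affine = diag(c(2, 2, 2, 1))) {
  write_volume(mask$voxels, path, affine = affine, datatype = "uint8")
}

#' Read a template stack from a 4D NIfTI
#'
#' The fourth dimension indexes networks.
#'
#' @param path 4D NIfTI file.
#' @param names optional network labels (defaults to standard names).
#' @return a `template_set`.
#' @export
read_templates <- function(path, names = NULL) {
  arr <- read_volume(path)
  if (length(dim(arr)) != 4L)
    stop(sprintf("template stack must be 4D, got %dD", length(dim(arr))))
  n <- dim(arr)[4]
  affine <- attr(arr, "affine")
  attr(arr, "affine") <- NULL
  structure(list(maps = arr,
                 names = names %||% default_network_names(n),
                 grid_dims = as.integer(dim(arr)[1:3]),
                 affine = affine, blob_sigma = NA_real_, centres = NULL),
            class = "template_set")
}

#' Read and validate a study manifest
#'
#' The manifest is a CSV with columns `subject_id`, `group`, `session`,
#' `path`; relative paths are resolved against the manifest's directory.
#' Every subject must have exactly one BL and one FU row and every file
#' must exist.
#'
#' @param path manifest CSV.
#' @return validated data frame with absolute paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "session", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  validate_manifest(man)
  man
}

validate_manifest <- function(man) {
  bad_sess <- setdiff(unique(man$session), c("BL", "FU"))
  if (length(bad_sess))
    stop("manifest sessions must be BL/FU; found: ",
         paste(bad_sess, collapse = ", "))
  for (sid in unique(man$subject_id)) {
    rows <- man[man$subject_id == sid, ]
    if (sum(rows$session == "BL") != 1L || sum(rows$session == "FU") != 1L)
      stop(sprintf("subject %s must have exactly one BL and one FU row (has %d BL, %d FU)",
                   sid, sum(rows$session == "BL"), sum(rows$session == "FU")))
    if (length(unique(rows$group)) != 1L)
      stop(sprintf("subject %s is assigned to more than one group", sid))
  }
  missing <- man$path[!file.exists(man$path)]
  if (length(missing))
    stop("manifest points at missing file(s): ",
         paste(missing, collapse = ", "))
  invisible(man)
}

#' Load a simulation config from YAML
#'
#' @param path YAML file written by [write_dataset()] (or hand-written with
#'   the same fields).
#' @return a `simulation_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("n_subjects_per_group", "sigma_within"))
    if (is.list(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  raw$blob_sigma <- raw$blob_sigma %||% NULL
  do.call(simulation_config, raw)
}

#' Run the full reliability pipeline
#'
#' Either simulates a two-session study from `config` or loads one from a
#' `manifest` + `templates`, then dual-regresses every subject-session,
#' builds masks, computes the per-network reliability table and the
#' between-group R12 comparison, and writes `repro_table.csv`,
#' `subject_scores.csv` and `group_comparison.csv` under `out_dir`.
#'
#' @param config a [simulation_config()] (ignored when `manifest` is
#'   given, except that one of the two must be supplied).
#' @param manifest optional manifest data frame or CSV path of an existing
#'   dataset.
#' @param templates optional `template_set` or 4D NIfTI path; required with
#'   `manifest`, built from `config` otherwise.
#' @param out_dir output directory (created if needed).
#' @param threshold Z cutoff for ROI masks and R12 (default 0).
#' @param en_threshold template cutoff for the entire-network mask.
#' @param use summary means from `"zmap"` (default) or `"beta"` maps.
#' @param write_maps also write each subject-session's beta and Z stacks
#'   as NIfTI under `out_dir/maps` (default `FALSE`).
#' @param verbose log per-stage progress and timing to stderr.
#' @return invisibly, a list with `repro` (the [network_reproducibility()]
#'   table), `comparison` (the [group_score_comparison()] table when two
#'   groups are present), `scores`, and `files` (paths written).
#' @export
run_pipeline <- function(config = NULL, manifest = NULL, templates = NULL,
                         out_dir, threshold = 0, en_threshold = 0,
                         use = c("zmap", "beta"), write_maps = FALSE,
                         verbose = TRUE) {
  use <- match.arg(use)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    say("[%s] done in %.1f s", name, proc.time()[["elapsed"]] - t0)
    out
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  maps <- stage("dual-regression", {
    if (!is.null(manifest)) {
      if (is.character(manifest)) manifest <- read_manifest(manifest)
      else validate_manifest(manifest)
      if (is.null(templates))
        stop("templates are required when running from a manifest")
      if (is.character(templates)) templates <- read_templates(templates)
      lapply(seq_len(nrow(manifest)), function(r) {
        arr <- read_volume(manifest$path[r],
                           expected_grid = templates$grid_dims)
        attr(arr, "affine") <- NULL
        bold <- structure(list(data = arr, tr_seconds = NA_real_,
                               subject_id = manifest$subject_id[r],
                               session = manifest$session[r],
                               group = manifest$group[r], mask = NULL),
                          class = "bold4d")
        dual_regress(bold, templates)
      })
    } else {
      if (is.null(config)) stop("supply either a config or a manifest")
      validate_config(config)
      templates <- make_templates(config)
      truth <- simulate_ground_truth(templates, config)
      out <- list()
      for (i in seq_along(truth$subject_ids))
        for (s in c("BL", "FU"))
          out[[length(out) + 1L]] <-
            dual_regress(simulate_bold(truth, templates, config, i, s),
                         templates)
      out
    }
  })

  if (write_maps) {
    stage("write-maps", {
      dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
      for (m in maps) {
        pref <- file.path(out_dir, "maps",
                          sprintf("sub-%s_ses-%s", m$subject_id, m$session))
        write_volume(m$beta, paste0(pref, "_beta.nii.gz"),
                     affine = templates$affine)
        write_volume(m$zmap, paste0(pref, "_z.nii.gz"),
                     affine = templates$affine)
      }
    })
  }

  repro <- stage("reliability-table",
                 network_reproducibility(maps, templates,
                                         threshold = threshold,
                                         en_threshold = en_threshold,
                                         use = use))
  scores <- attr(repro, "subject_scores")
  comparison <- NULL
  if (length(unique(scores$group)) == 2L)
    comparison <- stage("group-comparison", group_score_comparison(scores))

  files <- c(repro = file.path(out_dir, "repro_table.csv"),
             scores = file.path(out_dir, "subject_scores.csv"))
  utils::write.csv(as.data.frame(repro), files[["repro"]], row.names = FALSE)
  utils::write.csv(scores, files[["scores"]], row.names = FALSE)
  if (!is.null(comparison)) {
    files <- c(files,
               comparison = file.path(out_dir, "group_comparison.csv"))
    utils::write.csv(comparison, files[["comparison"]], row.names = FALSE)
  }
  say("wrote %s", paste(files, collapse = ", "))
  invisible(list(repro = repro, comparison = comparison, scores = scores,
                 files = files))
}
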