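# ROI construction: the entire-network (EN) mask from a template map and the
# per-subject BL-and-FU suprathreshold overlap ROI, plus mean extraction.
# Thresholds are strict (> tau): voxels exactly at the threshold are out.

new_network_mask <- function(voxels, network, provenance, threshold,
                             subject_id = NA_character_) {
  structure(list(voxels = voxels, network = network,
                 provenance = provenance, threshold = threshold,
                 subject_id = subject_id),
            class = "network_mask")
}

#' @export
print.network_mask <- function(x, ...) {
  cat(sprintf("<network_mask> %s [%s] thr > %g: %d voxels%s\n",
              x$network %||% "?", x$provenance, x$threshold,
              sum(x$voxels),
              if (is.na(x$subject_id)) "" else paste0(" (", x$subject_id, ")")))
  invisible(x)
}

#' Entire-network mask from a template map
#'
#' Binary mask of template voxels strictly above `threshold`; with the
#' default threshold 0 this is the template's whole footprint — the
#' group-level "entire network" over which mean connectivity is averaged.
#'
#' @param template_map 3D numeric array (one network's template), or a
#'   `template_set` plus `network` index/name.
#' @param threshold template-map cutoff (default 0, matching the Z>0
#'   convention used at subject level).
#' @param network network label (index or name when a `template_set` is
#'   given).
#' @return a `network_mask` with provenance `"entire_network"`.
#' @export
entire_network_mask <- function(template_map, threshold = 0, network = NA) {
  if (inherits(template_map, "template_set")) {
    j <- if (is.character(network)) match(network, template_map$names)
         else as.integer(network)
    if (is.na(j)) stop("unknown network: ", network)
    network <- template_map$names[j]
    template_map <- template_map$maps[, , , j]
  }
  vox <- template_map > threshold
  if (!any(vox))
    stop(sprintf(
      "entire-network mask is empty: threshold %g exceeds the template maximum %g",
      threshold, max(template_map)))
  new_network_mask(vox, network, "entire_network", threshold)
}

#' Per-subject session-overlap ROI mask
#'
#' Voxels suprathreshold (strictly) in both the baseline and the follow-up
#' Z map of the same subject and network — the individual's reproducible
#' core of the network. An empty overlap is flagged with a warning, not an
#' error: the subject then contributes a missing value to ROI statistics
#' rather than a spurious zero.
#'
#' @param z_bl,z_fu 3D Z maps of the two sessions, same grid.
#' @param threshold Z cutoff (default 0, the conventional sign threshold).
#' @param network,subject_id labels carried into the mask.
#' @return a `network_mask` with provenance `"subject_overlap"`.
#' @export
subject_overlap_mask <- function(z_bl, z_fu, threshold = 0,
                                 network = NA, subject_id = NA) {
  if (!identical(dim(z_bl), dim(z_fu)))
    stop(sprintf("session grids differ: %s vs %s",
                 paste(dim(z_bl), collapse = "x"),
                 paste(dim(z_fu), collapse = "x")))
  vox <- (z_bl > threshold) & (z_fu > threshold)
  if (!any(vox))
    warning(sprintf("empty overlap mask (Z > %g) for subject %s, network %s",
                    threshold, subject_id %||% NA, network %||% NA))
  new_network_mask(vox, network, "subject_overlap", threshold,
                   subject_id = as.character(subject_id))
}

#' Mean of a map over a mask
#'
#' The per-subject summary connectivity value: the arithmetic mean of map
#' values over the mask's voxels. Values outside the mask never enter.
#'
#' @param map 3D numeric array on the mask's grid.
#' @param mask a `network_mask` (or logical array).
#' @return scalar mean.
#' @export
mask_mean <- function(map, mask) {
  vox <- if (inherits(mask, "network_mask")) mask$voxels else as.logical(mask)
  if (!identical(dim(map), dim(vox)))
    stop(sprintf("map grid %s does not match mask grid %s",
                 paste(dim(map), collapse = "x"),
                 paste(dim(vox), collapse = "x")))
  if (!any(vox)) stop("cannot take the mean over an empty mask")
  mean(map[vox])
}
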