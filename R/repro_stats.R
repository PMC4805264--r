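# Reliability statistics: ICC(3,1) from the two-way ANOVA decomposition and
# the Dice ratio of overlapping suprathreshold voxels (R12), plus the
# per-network / per-group summary table and threshold sweeps.

#' Intraclass correlation ICC(3,1) from a subjects-by-sessions table
#'
#' Two-way ANOVA with random subject effects and fixed session effects:
#' with `n` subjects and `k` sessions,
#' \deqn{BMS = k \sum_i (\bar y_{i.} - \bar y_{..})^2 / (n-1)}
#' \deqn{JMS = n \sum_j (\bar y_{.j} - \bar y_{..})^2 / (k-1)}
#' \deqn{EMS = SS_{resid} / ((n-1)(k-1))}
#' \deqn{ICC(3,1) = (BMS - EMS) / (BMS + (k-1)\,EMS).}
#' Because the session mean square is removed from the error term, a
#' constant shift of any session column (a fixed session effect) leaves the
#' ICC unchanged; the statistic measures consistency, not absolute
#' agreement. Values near 1 indicate high test-retest reproducibility.
#'
#' Rows with missing entries (e.g. subjects whose overlap ROI was empty) are
#' dropped before the decomposition. Negative raw estimates are clamped to
#' 0 for reporting — the convention used when ICC tables print "0.00" — and
#' the unclamped value is kept alongside. An all-equal table has no
#' between-subject variance to detect, the ICC's own worst case, and yields
#' 0 with a warning.
#'
#' @param values numeric matrix or data frame, one row per subject, one
#'   column per session (two columns, BL and FU, in this design).
#' @return an object of class `icc_result`: `icc` (clamped), `icc_raw`,
#'   `bms`, `ems`, `jms`, `k`, `n`.
#' @export
#' @examples
#' icc31(rbind(c(1, 2), c(2, 4), c(3, 6)))  # BMS 4.5, EMS 0.5, ICC 0.8
icc31 <- function(values) {
  y <- as.matrix(values)
  if (!is.numeric(y)) stop("values must be numeric")
  k <- ncol(y)
  if (k < 2L) stop("need at least k = 2 sessions")
  complete <- stats::complete.cases(y)
  if (sum(!complete) > 0L)
    message(sprintf("icc31: dropping %d incomplete subject row(s)",
                    sum(!complete)))
  y <- y[complete, , drop = FALSE]
  n <- nrow(y)
  if (n < 3L)
    stop(sprintf("need >= 3 complete subject rows for the ANOVA (have %d)", n))

  grand <- mean(y)
  cm_ <- colMeans(y)
  jms <- n * sum((cm_ - grand)^2) / (k - 1)
  # session effects are fixed: removing the column means first makes the
  # shift-invariance of the remaining decomposition exact, not just
  # algebraic, under large session offsets
  yc <- sweep(y, 2, cm_)
  rc <- rowMeans(yc)
  ss_subj <- k * sum((rc - mean(yc))^2)
  ss_err <- sum((sweep(yc, 1, rc))^2)
  ss_total <- ss_subj + ss_err + (k - 1) * jms
  bms <- ss_subj / (n - 1)
  ems <- ss_err / ((n - 1) * (k - 1))

  if (ss_total <= .Machine$double.eps * max(1, sum(y^2))) {
    warning("zero total variance: ICC is undefined (0/0) and reported as 0")
    raw <- NA_real_
    icc <- 0
  } else {
    denom <- bms + (k - 1) * ems
    raw <- if (denom > 0) (bms - ems) / denom else NA_real_
    icc <- max(raw, 0, na.rm = TRUE)
  }
  structure(list(icc = icc, icc_raw = raw, bms = bms, ems = ems, jms = jms,
                 k = k, n = n),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %.3f (raw %.3f); BMS %.4g, EMS %.4g, JMS %.4g; n = %d, k = %d\n",
              x$icc, x$icc_raw, x$bms, x$ems, x$jms, x$n, x$k))
  invisible(x)
}

#' Dice ratio of overlapping suprathreshold voxels (R12)
#'
#' Counts voxels strictly above `threshold` in the baseline Z volume (V1),
#' in the follow-up Z volume (V2), and in both (V_overlap), and returns
#' \deqn{R12 = 2 V_{overlap} / (V1 + V2),} ranging from 0 (no overlap) to 1
#' (perfect overlap). Symmetric in the two sessions.
#'
#' @param z_bl,z_fu 3D Z maps on the same grid.
#' @param threshold strict Z cutoff (default 0).
#' @return an object of class `overlap_result`: `r12`, `v1`, `v2`,
#'   `v_overlap`, `threshold`.
#' @export
#' @examples
#' a <- array(c(1, 1, 1, 1, -1, -1), c(3, 2, 1))
#' dice_r12(a, a)$r12  # 1
dice_r12 <- function(z_bl, z_fu, threshold = 0) {
  if (!identical(dim(z_bl), dim(z_fu)))
    stop(sprintf("session grids differ: %s vs %s",
                 paste(dim(z_bl), collapse = "x"),
                 paste(dim(z_fu), collapse = "x")))
  m1 <- z_bl > threshold
  m2 <- z_fu > threshold
  v1 <- sum(m1); v2 <- sum(m2); vo <- sum(m1 & m2)
  if (v1 + v2 == 0L)
    stop(sprintf("no suprathreshold voxels (Z > %g) in either session: R12 undefined",
                 threshold))
  structure(list(r12 = 2 * vo / (v1 + v2), v1 = v1, v2 = v2,
                 v_overlap = vo, threshold = threshold),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("R12 = %.3f at Z > %g (V1 = %d, V2 = %d, overlap = %d)\n",
              x$r12, x$threshold, x$v1, x$v2, x$v_overlap))
  invisible(x)
}

#' Overlap ratio across a ladder of thresholds
#'
#' Evaluates [dice_r12()] at each threshold of a strictly increasing ladder.
#' Overlap ratios computed from suprathreshold voxel counts are sensitive to
#' the statistical threshold — raising the cutoff thins both sessions'
#' masks and typically lowers the ratio — so reporting a sweep shows how
#' much of the apparent reproducibility hangs on the Z>0 convention.
#'
#' @param z_bl,z_fu 3D Z maps on the same grid.
#' @param thresholds strictly increasing numeric vector.
#' @return data frame with one row per threshold: `threshold`, `v1`, `v2`,
#'   `v_overlap`, `r12` (`NA` where no voxel survives in either session).
#' @export
threshold_sweep <- function(z_bl, z_fu, thresholds) {
  if (length(thresholds) == 0L) stop("thresholds must be non-empty")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  rows <- lapply(thresholds, function(th) {
    res <- tryCatch(dice_r12(z_bl, z_fu, th), error = function(e) NULL)
    if (is.null(res))
      data.frame(threshold = th, v1 = 0L, v2 = 0L, v_overlap = 0L,
                 r12 = NA_real_)
    else
      data.frame(threshold = th, v1 = res$v1, v2 = res$v2,
                 v_overlap = res$v_overlap, r12 = res$r12)
  })
  do.call(rbind, rows)
}

#' Per-network, per-group reliability summary table
#'
#' The headline table of the pipeline: for every network and group it
#' reports the ICC(3,1) of mean connectivity over the entire-network mask
#' (EN), the ICC(3,1) of mean connectivity over each subject's BL-and-FU
#' overlap ROI, and the mean and SD of the per-subject overlap ratio R12.
#' Subjects whose overlap ROI is empty for a network contribute missing
#' values there and are dropped pairwise (with a message), never imputed.
#'
#' @param subject_maps list of `subject_network_maps`, one per
#'   subject-session; every subject must appear with both a BL and an FU
#'   entry.
#' @param templates the `template_set` the maps were regressed against.
#' @param group_labels optional named vector (subject_id -> group);
#'   defaults to the `group` field carried by the maps.
#' @param threshold Z cutoff for the subject overlap ROI and the R12
#'   counts (default 0).
#' @param en_threshold template cutoff for the entire-network mask
#'   (default 0).
#' @param use which map the summary means are taken from: the Z maps
#'   (default) or the raw beta maps.
#' @return data frame of class `repro_table` with columns `network`,
#'   `group`, `n`, `icc_en`, `icc_en_raw`, `icc_roi`, `icc_roi_raw`,
#'   `r12_mean`, `r12_sd`, `threshold`; per-subject values are attached as
#'   attribute `"subject_scores"` (columns `subject_id`, `group`,
#'   `network`, `en_bl`, `en_fu`, `roi_bl`, `roi_fu`, `r12`).
#' @export
network_reproducibility <- function(subject_maps, templates,
                                    group_labels = NULL, threshold = 0,
                                    en_threshold = 0,
                                    use = c("zmap", "beta")) {
  use <- match.arg(use)
  ids <- vapply(subject_maps, function(m) m$subject_id, character(1))
  sessions <- vapply(subject_maps, function(m) m$session, character(1))
  subjects <- unique(ids)
  by_subj <- lapply(subjects, function(sid) {
    bl <- which(ids == sid & sessions == "BL")
    fu <- which(ids == sid & sessions == "FU")
    if (length(bl) != 1L || length(fu) != 1L)
      stop(sprintf("subject %s must have exactly one BL and one FU map (has %d BL, %d FU)",
                   sid, length(bl), length(fu)))
    list(bl = subject_maps[[bl]], fu = subject_maps[[fu]])
  })
  names(by_subj) <- subjects
  groups <- if (!is.null(group_labels)) {
    unname(group_labels[subjects])
  } else {
    vapply(by_subj, function(p) p$bl$group %||% NA_character_, character(1))
  }
  if (anyNA(groups)) stop("missing group label for some subject")
  networks <- templates$names
  J <- length(networks)

  score_rows <- list()
  n_empty <- 0L
  for (j in seq_len(J)) {
    en_mask <- entire_network_mask(templates, threshold = en_threshold,
                                   network = j)
    for (si in seq_along(subjects)) {
      pair <- by_subj[[si]]
      map_bl <- pair$bl[[use]][, , , j]
      map_fu <- pair$fu[[use]][, , , j]
      z_bl <- pair$bl$zmap[, , , j]
      z_fu <- pair$fu$zmap[, , , j]
      roi <- withCallingHandlers(
        subject_overlap_mask(z_bl, z_fu, threshold = threshold,
                             network = networks[j],
                             subject_id = subjects[si]),
        warning = function(w) invokeRestart("muffleWarning"))
      empty <- !any(roi$voxels)
      if (empty) n_empty <- n_empty + 1L
      r12 <- tryCatch(dice_r12(z_bl, z_fu, threshold)$r12,
                      error = function(e) NA_real_)
      score_rows[[length(score_rows) + 1L]] <- data.frame(
        subject_id = subjects[si], group = groups[si],
        network = networks[j],
        en_bl = mask_mean(map_bl, en_mask),
        en_fu = mask_mean(map_fu, en_mask),
        roi_bl = if (empty) NA_real_ else mask_mean(map_bl, roi),
        roi_fu = if (empty) NA_real_ else mask_mean(map_fu, roi),
        r12 = r12, stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, score_rows)
  if (n_empty > 0L)
    message(sprintf(
      "network_reproducibility: %d empty overlap ROI(s); affected subjects dropped pairwise",
      n_empty))

  safe_icc <- function(tab) {
    tryCatch(suppressMessages(suppressWarnings(icc31(tab))),
             error = function(e) list(icc = NA_real_, icc_raw = NA_real_,
                                      n = sum(stats::complete.cases(tab))))
  }
  out_rows <- list()
  for (j in networks) {
    for (g in unique(groups)) {
      sub <- scores[scores$network == j & scores$group == g, ]
      icc_en <- safe_icc(sub[, c("en_bl", "en_fu")])
      icc_roi <- safe_icc(sub[, c("roi_bl", "roi_fu")])
      out_rows[[length(out_rows) + 1L]] <- data.frame(
        network = j, group = g, n = icc_roi$n,
        icc_en = icc_en$icc, icc_en_raw = icc_en$icc_raw,
        icc_roi = icc_roi$icc, icc_roi_raw = icc_roi$icc_raw,
        r12_mean = mean(sub$r12, na.rm = TRUE),
        r12_sd = stats::sd(sub$r12, na.rm = TRUE),
        threshold = threshold, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out_rows)
  rownames(out) <- NULL
  class(out) <- c("repro_table", "data.frame")
  attr(out, "subject_scores") <- scores
  out
}

#' Voxel-wise ICC(3,1) map over the entire-network mask
#'
#' A finer-grained complement to the single mean-connectivity ICC: the
#' ICC(3,1) is computed independently at every voxel of the entire-network
#' mask from the subjects-by-sessions table of that voxel's values.
#'
#' @param subject_maps list of `subject_network_maps` (both sessions per
#'   subject).
#' @param templates the matching `template_set`.
#' @param network network index or name.
#' @param en_threshold template cutoff for the mask (default 0).
#' @param use `"zmap"` (default) or `"beta"`.
#' @return 3D array of clamped ICC values, `NA` outside the mask.
#' @export
voxelwise_icc <- function(subject_maps, templates, network,
                          en_threshold = 0, use = c("zmap", "beta")) {
  use <- match.arg(use)
  j <- if (is.character(network)) match(network, templates$names)
       else as.integer(network)
  if (is.na(j)) stop("unknown network: ", network)
  ids <- vapply(subject_maps, function(m) m$subject_id, character(1))
  sessions <- vapply(subject_maps, function(m) m$session, character(1))
  subjects <- unique(ids)
  n <- length(subjects)
  if (n < 3L) stop("need >= 3 subjects for voxel-wise ICC")
  mask <- entire_network_mask(templates, threshold = en_threshold,
                              network = j)
  mv <- which(mask$voxels)
  grab <- function(sid, ses) {
    idx <- which(ids == sid & sessions == ses)
    if (length(idx) != 1L)
      stop(sprintf("subject %s must have exactly one %s map", sid, ses))
    subject_maps[[idx]][[use]][, , , j][mv]
  }
  y1 <- t(vapply(subjects, grab, numeric(length(mv)), ses = "BL"))
  y2 <- t(vapply(subjects, grab, numeric(length(mv)), ses = "FU"))

  g <- colMeans(rbind(y1, y2))
  sm <- (y1 + y2) / 2
  bms <- 2 * colSums(sweep(sm, 2, g)^2) / (n - 1)
  m1 <- colMeans(y1); m2 <- colMeans(y2)
  jms <- n * ((m1 - g)^2 + (m2 - g)^2)
  ss_tot <- colSums(sweep(y1, 2, g)^2) + colSums(sweep(y2, 2, g)^2)
  ems <- pmax(ss_tot - (n - 1) * bms - jms, 0) / (n - 1)
  denom <- bms + ems
  icc <- ifelse(denom > 0, pmax((bms - ems) / denom, 0), 0)

  out <- array(NA_real_, dim = templates$grid_dims)
  out[mv] <- icc
  out
}
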