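test_that("icc31 reproduces the worked three-subject example", {
  tab <- rbind(c(1, 2), c(2, 4), c(3, 6))
  res <- icc31(tab)
  orc <- oracle_icc31(tab)
  expect_equal(res$bms, 4.5)
  expect_equal(res$jms, 6)
  expect_equal(res$ems, 0.5)
  expect_equal(res$icc, 0.8)
  expect_equal(res$icc, orc$icc, tolerance = 1e-10)
})

test_that("icc31 agrees with the brute-force ANOVA oracle on random tables", {
  set.seed(314)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    tab <- matrix(rnorm(2 * n, mean = 5, sd = 2), n, 2)
    res <- icc31(tab)
    orc <- oracle_icc31(tab)
    expect_equal(res$bms, orc$bms, tolerance = 1e-10)
    expect_equal(res$ems, orc$ems, tolerance = 1e-10)
    expect_equal(res$icc_raw, orc$icc, tolerance = 1e-10)
    expect_equal(res$icc, max(orc$icc, 0), tolerance = 1e-10)
  }
})

test_that("icc31 limits: perfect repetition, fixed session effects, degeneracies", {
  # FU identical to BL with subject spread: EMS 0, ICC 1
  y <- cbind(c(1, 5, 9), c(1, 5, 9))
  res <- icc31(y)
  expect_equal(res$ems, 0)
  expect_equal(res$icc, 1)

  # a constant session shift is absorbed by the session term: ICC unchanged
  base <- cbind(c(1, 5, 9, 2), c(2, 4, 8, 3))
  r0 <- icc31(base)
  for (shift in c(-3, 0.7, 100)) {
    shifted <- base
    shifted[, 2] <- shifted[, 2] + shift
    expect_equal(icc31(shifted)$icc_raw, r0$icc_raw, tolerance = 1e-10)
  }

  # all-equal table: the formula is 0/0 and is reported as 0 with a warning
  expect_warning(rz <- icc31(matrix(3, 4, 2)), "zero total variance")
  expect_equal(rz$icc, 0)

  # incomplete rows are dropped; too few rows is an error
  expect_message(ri <- icc31(rbind(c(1, 2), c(2, 4), c(3, 6), c(9, NA))),
                 "dropping 1")
  expect_equal(ri$n, 3)
  expect_error(suppressMessages(icc31(rbind(c(1, 2), c(2, NA), c(3, 6)))),
               ">= 3 complete")
  expect_error(icc31(cbind(1:4)), "k = 2")
})

test_that("icc31 estimates the variance-component ratio consistently", {
  # y_ij = mu + b_i + e_ij with sb^2 = 3, se^2 = 1 -> true ICC 0.75
  hits <- 0
  for (r in 1:10) {
    set.seed(1000 + r)
    n <- 200
    b <- rnorm(n, sd = sqrt(3))
    y <- cbind(10 + b + rnorm(n), 10 + b + rnorm(n))
    est <- icc31(y)$icc
    if (abs(est - 0.75) <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("dice_r12 identities and counting arithmetic", {
  a <- array(c(1, 2, 3, 4, -1, -1), c(6, 1, 1))
  expect_equal(dice_r12(a, a)$r12, 1)

  # disjoint supports -> 0
  b <- array(c(-1, -1, -1, -1, 1, 1), c(6, 1, 1))
  expect_equal(dice_r12(a, b)$r12, 0)

  # v1 = 4, v2 = 4, v_overlap = 2 -> 0.5
  x <- array(c(1, 1, 1, 1, 0, 0), c(6, 1, 1))
  y <- array(c(1, 1, 0, 0, 1, 1), c(6, 1, 1))
  res <- dice_r12(x, y)
  expect_equal(c(res$v1, res$v2, res$v_overlap), c(4, 4, 2))
  expect_equal(res$r12, 0.5)

  # symmetry, range, consistency of counts
  set.seed(2)
  z1 <- array(rnorm(125), c(5, 5, 5)); z2 <- array(rnorm(125), c(5, 5, 5))
  r12 <- dice_r12(z1, z2)
  expect_equal(dice_r12(z2, z1)$r12, r12$r12)
  expect_gte(r12$r12, 0); expect_lte(r12$r12, 1)
  expect_lte(r12$v_overlap, min(r12$v1, r12$v2))

  # both sessions empty is an error, distinct from r12 = 0
  zz <- array(-1, c(3, 3, 3))
  expect_error(dice_r12(zz, zz), "undefined")
})

test_that("threshold_sweep evaluates the ladder and marks vanishing counts", {
  set.seed(3)
  z1 <- array(rnorm(6^3), c(6, 6, 6)); z2 <- array(rnorm(6^3), c(6, 6, 6))
  sw <- threshold_sweep(z1, z2, c(0, 1.5, 99))
  expect_equal(nrow(sw), 3)
  expect_equal(sw$r12[1], dice_r12(z1, z2, 0)$r12)
  expect_true(is.na(sw$r12[3]))  # nothing survives Z > 99

  # single threshold reduces to dice_r12
  expect_equal(threshold_sweep(z1, z2, 1)$r12, dice_r12(z1, z2, 1)$r12)

  # identical maps stay at 1 below the map maximum
  pos <- array(abs(rnorm(6^3)) + 0.1, c(6, 6, 6))
  expect_equal(threshold_sweep(pos, pos, c(0.0, 0.05))$r12, c(1, 1))

  expect_error(threshold_sweep(z1, z2, c(1, 1)), "strictly increasing")
})

test_that("raising the threshold lowers the mean overlap ratio across subjects", {
  cfg <- tiny_config(grid_dims = c(10, 10, 10), blob_sigma = 1.2,
                     n_subjects_per_group = c(HC = 10, MS = 10),
                     sigma_noise = 4, seed = 77)
  study <- regress_study(cfg)
  r_by_thr <- sapply(c(0, 1.5), function(th) {
    mean(sapply(seq(1, length(study$maps), by = 2), function(b) {
      bl <- study$maps[[b]]; fu <- study$maps[[b + 1]]
      mean(sapply(seq_len(cfg$n_networks), function(j)
        dice_r12(bl$zmap[, , , j], fu$zmap[, , , j], th)$r12))
    }))
  })
  expect_lt(r_by_thr[2], r_by_thr[1])
})

test_that("network_reproducibility assembles the per-network, per-group table", {
  cfg <- tiny_config(seed = 8)
  study <- regress_study(cfg)
  tab <- suppressMessages(
    network_reproducibility(study$maps, study$templates))
  expect_s3_class(tab, "repro_table")
  expect_equal(nrow(tab), cfg$n_networks * 2)  # networks x groups
  expect_setequal(unique(tab$group), c("HC", "MS"))
  expect_true(all(c("icc_en", "icc_en_raw", "icc_roi", "icc_roi_raw",
                    "r12_mean", "r12_sd") %in% names(tab)))
  expect_true(all(tab$icc_roi >= 0 & tab$icc_roi <= 1, na.rm = TRUE))
  expect_true(all(tab$r12_mean >= 0 & tab$r12_mean <= 1, na.rm = TRUE))
  scores <- attr(tab, "subject_scores")
  expect_equal(nrow(scores), cfg$n_networks * 6)

  # missing session -> error naming the subject
  expect_error(network_reproducibility(study$maps[-2], study$templates),
               "HC01")
})

test_that("zero within-subject variance yields perfect overlap and near-perfect ROI ICC", {
  # with sigma_within = sigma_noise = 0 each subject's BL and FU maps share
  # the same support exactly, so R12 = 1; the ROI ICC on beta maps is near 1
  # but not exact, because each session's realised time courses carry their
  # own sample variance into the stage-2 coefficients (the Z maps themselves
  # are 0/0-degenerate without noise, so beta maps are the meaningful scale)
  cfg <- tiny_config(sigma_within = 0, sigma_noise = 0, n_timepoints = 150,
                     n_subjects_per_group = c(HC = 10))
  study <- regress_study(cfg)
  tab <- suppressMessages(network_reproducibility(study$maps,
                                                  study$templates,
                                                  use = "beta"))
  expect_equal(tab$r12_mean, rep(1, cfg$n_networks))
  expect_true(all(tab$icc_roi > 0.9))
})

test_that("growing within-subject amplitude variance degrades ROI ICC", {
  icc_at <- function(sw) {
    cfg <- tiny_config(sigma_within = sw, sigma_noise = 6,
                       n_subjects_per_group = c(HC = 20), seed = 13)
    tab <- suppressMessages(network_reproducibility(
      regress_study(cfg)$maps, make_templates(cfg)))
    mean(tab$icc_roi)
  }
  ladder <- vapply(c(0.05, 0.5, 2), icc_at, numeric(1))
  expect_true(all(diff(ladder) < 0))
})

test_that("growing sensor noise degrades both ROI ICC and overlap", {
  stats_at <- function(sn) {
    cfg <- tiny_config(sigma_within = 0.05, sigma_noise = sn,
                       n_subjects_per_group = c(HC = 20), seed = 13)
    tab <- suppressMessages(network_reproducibility(
      regress_study(cfg)$maps, make_templates(cfg)))
    c(icc = mean(tab$icc_roi), r12 = mean(tab$r12_mean))
  }
  ladder <- sapply(c(2, 8, 30), stats_at)
  expect_true(all(diff(ladder["icc", ]) < 0))
  expect_true(all(diff(ladder["r12", ]) < 0))
})

test_that("voxelwise ICC tracks local signal strength within the network", {
  cfg <- tiny_config(sigma_between = 0.6, sigma_within = 0.02,
                     sigma_noise = 1, n_subjects_per_group = c(HC = 8),
                     seed = 5)
  study <- regress_study(cfg)
  vw <- voxelwise_icc(study$maps, study$templates, 1)
  inside <- entire_network_mask(study$templates, network = 1)$voxels
  expect_true(all(is.na(vw[!inside])))
  # reliability concentrates where the network is strong: the template's
  # upper half massively out-reproduces its weak outer shell
  tm <- study$templates$maps[, , , 1]
  core <- inside & tm > max(tm) / 2
  shell <- inside & tm <= max(tm) / 2
  expect_gt(stats::median(vw[core]), 0.8)
  expect_gt(stats::median(vw[core]), stats::median(vw[shell]))
})
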