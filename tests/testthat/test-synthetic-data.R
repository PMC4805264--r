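test_that("templates are separable, positive, deterministic, and edge cases work", {
  cfg <- simulation_config(grid_dims = c(16, 16, 16), n_networks = 3, seed = 7)
  tpl <- make_templates(cfg)
  expect_equal(dim(tpl$maps), c(16, 16, 16, 3))
  flat <- matrix(tpl$maps, 16^3, 3)
  expect_true(all(colSums(flat > 0) > 0))
  r <- cor(flat)
  expect_lt(max(abs(r[upper.tri(r)])), 0.5)
  expect_equal(apply(flat, 2, max), rep(cfg$z_peak, 3))

  # determinism: same config twice gives identical arrays
  expect_identical(tpl$maps, make_templates(cfg)$maps)

  # single-network set is valid
  tpl1 <- make_templates(simulation_config(grid_dims = c(16, 16, 16),
                                           n_networks = 1, seed = 7))
  expect_equal(dim(tpl1$maps)[4], 1)

  # grid too small to separate the blobs -> configuration error
  expect_error(make_templates(simulation_config(grid_dims = c(6, 6, 6),
                                                n_networks = 9)),
               "cannot hold")
})

test_that("config validation rejects bad values", {
  expect_error(simulation_config(sigma_noise = -1), "SD")
  expect_error(simulation_config(grid_dims = c(8, 8)), "grid_dims")
  expect_error(simulation_config(n_timepoints = 0), "n_timepoints")
  expect_error(simulation_config(n_subjects_per_group = c(HC = 0, MS = 2)),
               "n_subjects_per_group")
})

test_that("ground truth follows the amplitude model", {
  # zero variance everywhere: BL and FU identical across all subjects
  cfg0 <- tiny_config(sigma_between = 0, sigma_within = 0, session_shift = 0)
  tpl <- make_templates(cfg0)
  tr0 <- simulate_ground_truth(tpl, cfg0)
  expect_equal(dim(tr0$subject_maps)[5], 2)  # exactly two sessions
  expect_equal(tr0$subject_maps[, , , , 1, ], tr0$subject_maps[, , , , 2, ])
  expect_equal(max(abs(tr0$subject_maps[, , , 1, 1, 1] - tpl$maps[, , , 1])), 0)

  # zero within-subject variance: each subject's BL map equals its FU map
  cfgb <- tiny_config(sigma_between = 0.5, sigma_within = 0)
  trb <- simulate_ground_truth(make_templates(cfgb), cfgb)
  expect_equal(trb$subject_maps[, , , , 1, ], trb$subject_maps[, , , , 2, ])
  expect_gt(stats::sd(trb$subject_amplitudes[, 1, 1]), 0)

  # session shift adds a fixed amplitude offset at FU only
  cfgs <- tiny_config(sigma_between = 0, sigma_within = 0, session_shift = 0.3)
  trs <- simulate_ground_truth(make_templates(cfgs), cfgs)
  expect_equal(trs$subject_amplitudes[, 2, ] - trs$subject_amplitudes[, 1, ],
               matrix(0.3, 6, 3))

  # group labels match the configured design
  expect_equal(table(trb$group_labels), table(c(rep("HC", 3), rep("MS", 3))))
})

test_that("amplitude perturbations recover their configured SDs at n = 200", {
  cfg <- simulation_config(grid_dims = c(12, 12, 12), n_networks = 2,
                           n_subjects_per_group = c(HC = 200),
                           n_timepoints = 10, sigma_between = 0.5,
                           sigma_within = 0.25, seed = 202)
  truth <- simulate_ground_truth(make_templates(cfg), cfg)
  a <- truth$subject_amplitudes
  # b_ij is the subject-level mean perturbation (w averages out of it only
  # partially, so compare the session-mean SD against sqrt(sb^2 + sw^2/2))
  subj_mean <- (a[, 1, ] + a[, 2, ]) / 2 - 1
  expect_equal(stats::sd(subj_mean[, 1]), sqrt(0.5^2 + 0.25^2 / 2),
               tolerance = 0.10)
  # w_ijs is identifiable from the session difference: Var(diff) = 2 sw^2
  expect_equal(stats::sd(a[, 2, 1] - a[, 1, 1]) / sqrt(2), 0.25,
               tolerance = 0.10)
})

test_that("BOLD mixes maps with stored time courses plus noise", {
  cfg <- tiny_config(n_networks = 1, sigma_noise = 0)
  tpl <- make_templates(cfg)
  truth <- simulate_ground_truth(tpl, cfg)
  bold <- simulate_bold(truth, tpl, cfg, 1, "BL")
  expect_equal(dim(bold$data)[4], cfg$n_timepoints)
  # noiseless single source: every voxel series proportional to c_1(t)
  v <- which(tpl$maps[, , , 1] == max(tpl$maps[, , , 1]), arr.ind = TRUE)[1, ]
  series <- bold$data[v[1], v[2], v[3], ]
  expect_equal(series,
               truth$subject_maps[v[1], v[2], v[3], 1, 1, 1] *
                 bold$time_courses[, 1])

  # determinism and per-session seeding
  again <- simulate_bold(truth, tpl, cfg, 1, "BL")
  expect_identical(bold$data, again$data)
  fu <- simulate_bold(truth, tpl, cfg, 1, "FU")
  expect_false(identical(bold$time_courses, fu$time_courses))

  expect_error(simulate_bold(truth, tpl, cfg, 99, "BL"), "subject")
  expect_error(simulate_bold(truth, tpl, cfg, 1, "XX"), "session")
})

test_that("a 150-volume acquisition yields 150 volumes", {
  cfg <- tiny_config(n_networks = 1, n_timepoints = 150,
                     grid_dims = c(8, 8, 8), blob_sigma = 1)
  tpl <- make_templates(cfg)
  truth <- simulate_ground_truth(tpl, cfg)
  expect_equal(dim(simulate_bold(truth, tpl, cfg, 1, 1)$data)[4], 150)
})

test_that("write_dataset produces a round-trippable on-disk study", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(grid_dims = c(8, 8, 8), n_networks = 2, blob_sigma = 1,
                     n_subjects_per_group = c(HC = 1, MS = 1),
                     n_timepoints = 12)
  tpl <- make_templates(cfg)
  truth <- simulate_ground_truth(tpl, cfg)
  manifest <- write_dataset(truth, tpl, cfg, dir)

  # 2 subjects x 2 sessions -> 4 BOLD files + 1 template file + manifest
  expect_equal(nrow(manifest), 4)
  expect_length(list.files(dir, pattern = "bold\\.nii\\.gz$"), 4)
  expect_true(file.exists(file.path(dir, "templates.nii.gz")))
  subj <- unique(manifest[, c("subject_id", "group")])
  expect_equal(as.vector(table(subj$group)[c("HC", "MS")]),
               as.vector(cfg$n_subjects_per_group))

  # round trip is exact at float32 storage precision
  bold <- simulate_bold(truth, tpl, cfg, 1, "BL")
  back <- read_volume(file.path(dir, manifest$path[manifest$subject_id ==
                        bold$subject_id & manifest$session == "BL"]))
  expect_equal(c(back), c(bold$data), tolerance = 1e-6)

  # manifest and config reload through the readers
  man2 <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(man2$subject_id, manifest$subject_id)
  cfg2 <- read_config(file.path(dir, "config.yaml"))
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$sigma_between, cfg$sigma_between)
})
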