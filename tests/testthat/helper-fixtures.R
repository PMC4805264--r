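# Desk-scale study configurations used across the suite. All fixtures are
# generated in code; nothing is read from disk.

tiny_config <- function(...) {
  defaults <- list(grid_dims = c(12L, 12L, 12L), n_networks = 3L,
                   n_subjects_per_group = c(HC = 3L, MS = 3L),
                   n_timepoints = 40L, sigma_between = 0.5,
                   sigma_within = 0.1, sigma_noise = 4, seed = 42L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# Dual-regress every subject-session of a simulated study.
regress_study <- function(cfg) {
  tpl <- make_templates(cfg)
  truth <- simulate_ground_truth(tpl, cfg)
  maps <- list()
  for (i in seq_along(truth$subject_ids))
    for (s in c("BL", "FU"))
      maps[[length(maps) + 1L]] <-
        dual_regress(simulate_bold(truth, tpl, cfg, i, s), tpl)
  list(cfg = cfg, templates = tpl, truth = truth, maps = maps)
}
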