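test_that("cohort configuration validates fields and names offenders", {
  expect_error(cohort_config(n_nodes = 3), "n_nodes")
  expect_error(cohort_config(age_range = c(10, 5)), "age_range")
  expect_error(cohort_config(coupling_strength = 1), "coupling_strength")
  expect_error(cohort_config(leakage_strength = -0.1), "leakage_strength")
  expect_error(cohort_config(fs = 100), "fs")
  expect_error(cohort_config(duration = 30), "duration")
  expect_error(cohort_config(hub_nodes = c(1, 9999)), "hub_nodes")
  expect_error(cohort_config(artifact_rates = c(spikes = 1)),
               "artifact_rates")
  expect_error(small_cohort_config(local_band = "delta"), "local_band")
})

test_that("cohorts are deterministic and span the stated population", {
  cfg <- cohort_config(n_subjects = 131, age_range = c(7, 29), n_nodes = 16,
                       bands = list(beta = band_beta()), fs = 600, seed = 5)
  coh <- generate_cohort(cfg)
  expect_length(coh, 131)
  ages <- subject_table(coh)$age
  expect_true(all(ages >= 7 & ages <= 29))

  coh2 <- generate_cohort(cfg)
  expect_identical(coh, coh2)                   # byte-identical for one seed

  cfg3 <- cohort_config(n_subjects = 131, age_range = c(7, 29), n_nodes = 16,
                        bands = list(beta = band_beta()), fs = 600, seed = 6)
  expect_false(identical(generate_cohort(cfg3), coh))
})

test_that("planted graphs express the configured age effects", {
  # strong slopes so per-subject topology orders by age
  cfg <- small_cohort_config(n_subjects = 30, n_nodes = 48, seed = 9,
                             age_effect_local = 0.02,
                             age_effect_global = 0.02)
  coh <- generate_cohort(cfg)
  ages <- subject_table(coh)$age
  eloc_beta <- vapply(coh, function(r)
    local_efficiency(threshold_proportional(r$planted$beta, 0.15)), 0)
  eglob_gamma <- vapply(coh, function(r)
    global_efficiency(threshold_proportional(r$planted$gamma, 0.15)), 0)
  expect_gt(spearman_rho(ages, eloc_beta), 0.4)
  expect_gt(spearman_rho(ages, eglob_gamma), 0.4)

  # opposite-signed slopes produce opposite-signed correlations
  cfg2 <- small_cohort_config(n_subjects = 30, n_nodes = 48, seed = 10,
                              age_effect_local = -0.02,
                              age_effect_global = 0.02)
  coh2 <- generate_cohort(cfg2)
  ages2 <- subject_table(coh2)$age
  eloc2 <- vapply(coh2, function(r)
    local_efficiency(threshold_proportional(r$planted$beta, 0.15)), 0)
  expect_lt(spearman_rho(ages2, eloc2), -0.4)
})

test_that("null cohorts carry no age-metric association on average", {
  # Monte-Carlo null: mean Spearman rho across cohorts centred on zero
  rhos <- vapply(1:15, function(s) {
    cfg <- small_cohort_config(n_subjects = 25, n_nodes = 24, seed = 600 + s,
                               age_effect_local = 0, age_effect_global = 0)
    coh <- generate_cohort(cfg)
    ages <- subject_table(coh)$age
    eloc <- vapply(coh, function(r)
      local_efficiency(threshold_proportional(r$planted$beta, 0.15)), 0)
    spearman_rho(ages, eloc)
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("coupled series generator validates its inputs", {
  a <- band_alpha()
  bad <- matrix(0.5, 4, 4)                      # nonzero diagonal
  expect_error(generate_coupled_band_series(4, a, 60, 60,
                                            envelope_coupling = bad),
               "diagonal")
  asym <- matrix(0, 4, 4); asym[1, 2] <- 0.5
  expect_error(generate_coupled_band_series(4, a, 60, 60,
                                            envelope_coupling = asym),
               "symmetric")
  expect_error(generate_coupled_band_series(4, a, 60, 20), "fs too low")
  X <- generate_coupled_band_series(4, a, 60, 60, seed = 2)
  expect_equal(dim(X), c(4, 3600))
  expect_identical(X, generate_coupled_band_series(4, a, 60, 60, seed = 2))
})

test_that("artifact injection is deterministic bookkeeping", {
  cfg <- cohort_config(n_subjects = 1, n_nodes = 8,
                       bands = list(alpha = band_alpha()),
                       duration = 120, fs = 250, seed = 3)
  rec <- generate_cohort(cfg)[[1]]

  none <- generate_artifact_channels(rec, c(spikes = 0, blinks = 0,
                                            motion = 0), seed = 1)
  expect_length(none$artifact_log$spikes, 0)
  expect_equal(nrow(none$artifact_log$blinks), 0)
  expect_length(none$artifact_log$motion_blocks, 0)
  expect_equal(sum(reject_motion_blocks(none$aux$speed, none$aux_fs)), 0)

  five <- generate_artifact_channels(rec, c(spikes = 0, blinks = 0,
                                            motion = 2.5), seed = 2)
  expect_length(five$artifact_log$motion_blocks, 5)   # 2.5/min x 2 min
})

test_that("vertex-label fixtures flip exactly the stated fraction", {
  fix <- generate_vertex_label(10, 500, flip_fraction = 0.5, seed = 1)
  expect_equal(sum(fix$flipped), 5)
  expect_equal(dim(fix$vertices), c(10, 500))

  none <- generate_vertex_label(6, 500, flip_fraction = 0, seed = 2)
  expect_false(any(none$flipped))
  # alignment is then a no-op up to global sign
  out <- align_label_signs(none$vertices)
  expect_true(all(out$flipped) || !any(out$flipped))
})
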