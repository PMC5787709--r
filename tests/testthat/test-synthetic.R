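test_that("noiseless cohorts give per-root geometry back to the fitter", {
  co <- generate_cohort("wt_epidermis_sizer", seed = 9, n_roots = 12,
                        noise_cv = 0)
  profs <- rootzone:::profiles_as_list(co$profiles)
  for (p in profs[1:6]) {
    fit <- fit_profile(p)
    truth <- co$manifest[co$manifest$root_id == p$root_id, ]
    # the meristem is rendered exactly but the EZ snapshot is stochastic,
    # so a one-cell breakpoint shift can blend one EZ cell into the MZ
    # slope; recovery is sub-0.1% rather than exact
    expect_equal(fit$r_MZ, 1.03, tolerance = 1e-3)
    # per-root elongation factor within a few percent (the EZ snapshot is
    # stochastic; the meristem is rendered exactly)
    expect_lt(abs(fit$r_EZ - truth$r_EZ_true) / truth$r_EZ_true, 0.1)
  }
})

test_that("manifest is joinable, one row per emitted root, with true traits", {
  expect_equal(nrow(wt_cohort$manifest), 122)
  expect_setequal(unique(wt_cohort$profiles$root_id),
                  wt_cohort$manifest$root_id)
  # l_diff identity holds for the manifest's closed-form traits
  m <- wt_cohort$manifest
  expect_equal(m$l_max_true, m$l0 * m$r_EZ_true^m$N_EZ_true,
               tolerance = 1e-9)
  # sizer: the stationary mature length is the per-root threshold
  expect_equal(m$l_max_true, m$threshold)
})

test_that("cohort generation is seed-deterministic and presets differ", {
  a <- generate_cohort("pac_like", seed = 4)
  b <- generate_cohort("pac_like", seed = 4)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$manifest, b$manifest)
  c2 <- generate_cohort("pac_like", seed = 5)
  expect_false(identical(a$profiles, c2$profiles))
  # the PAC-like preset has clearly shorter mature cells than WT
  expect_lt(mean(a$manifest$l_max_true), 120)
})

test_that("root-length series are linear after day 4 with the trajectory's slope", {
  co <- generate_cohort("wt_epidermis_sizer", seed = 15, n_roots = 8)
  series <- generate_root_length_series(co, seed = 15, noise_sd_mm = 0)
  for (id in co$manifest$root_id[1:4]) {
    d <- series[series$root_id == id & series$day >= 4, ]
    fit <- stats::lm(root_length_mm ~ day, d)
    expect_gt(summary(fit)$r.squared, 0.999)
    slope_umh <- unname(stats::coef(fit)[2]) * 1000 / 24
    j <- which(co$manifest$root_id == id)
    expect_equal(slope_umh, sim_root_growth_rate(co$roots[[j]]),
                 tolerance = 0.02)
  }
  expect_error(generate_root_length_series(co, days = c(0, 5)), "1..10")
})

test_that("full pipeline recovers the cohort parameters from measured-style data", {
  tr <- wt_traits_fit
  series <- generate_root_length_series(wt_cohort, seed = 101)
  inf <- infer_dynamics(tr, growth = root_growth_rate(series, day_min = 4))
  expect_lt(abs(mean(inf$R_prod, na.rm = TRUE) - 1.75) / 1.75, 0.1)
  expect_lt(abs(mean(inf$r_elong, na.rm = TRUE) - 0.45) / 0.45, 0.1)
  expect_lt(abs(mean(inf$l_diff, na.rm = TRUE) - 160) / 160, 0.1)
})

test_that("mutant-like presets carry their mechanism end to end", {
  bri <- simulate_cohort(preset_params("bri1_like"), seed = 88)
  expect_equal(classify_mechanism(trait_correlations(bri$traits))$verdict,
               "mixed_sizer_timer")
  pac <- simulate_cohort(preset_params("pac_like", n_roots = 60), seed = 89)
  expect_equal(classify_mechanism(trait_correlations(pac$traits))$verdict,
               "sizer")
})
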