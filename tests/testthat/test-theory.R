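test_that("elongation factor follows exp(r_elong / R_prod)", {
  expect_equal(elongation_factor_from_rates(log(2), 1), 2)
  expect_equal(elongation_factor_from_rates(0, 3), 1)
  expect_equal(elongation_factor_from_rates(0.446, 1.75), 1.29,
               tolerance = 5e-3)
  expect_error(elongation_factor_from_rates(0.4, 0), "positive")
})

test_that("closed-form stationary traits match the worked doubling examples", {
  siz <- steady_state_traits("sizer", 10, log(2), 1, 160)
  expect_equal(siz$N_EZ, 4)
  expect_equal(siz$l_max, 160)
  expect_equal(siz$L_EZ, 300)
  expect_equal(siz$R_growth, 160)
  expect_equal(siz$T_EZ, 4)

  tim <- steady_state_traits("timer", 10, log(2), 1, 4)
  expect_equal(unlist(tim[c("N_EZ", "l_max", "L_EZ", "R_growth")]),
               unlist(siz[c("N_EZ", "l_max", "L_EZ", "R_growth")]))

  rul <- steady_state_traits("ruler", 10, log(2), 1, 100)
  expect_equal(rul$N_EZ, 3)
  expect_equal(rul$l_max, 80)
  expect_equal(rul$L_EZ, 140)

  expect_warning(deg <- steady_state_traits("sizer", 10, log(2), 1, 5),
                 "N_EZ = 0")
  expect_equal(deg$N_EZ, 0)
  expect_equal(deg$L_EZ, 0)

  # WT-epidermis-like preset transit time sits in the 6-8 h window
  wt <- steady_state_traits("sizer", 8, 0.45, 1.75, 160)
  expect_gt(wt$T_EZ, 6)
  expect_lt(wt$T_EZ, 8)
})

test_that("threshold insensitivities and the mature-length identity hold exactly", {
  # sizer mature length does not depend on the rates
  for (re in c(0.2, 0.45, 0.9)) for (rp in c(1, 1.75, 3))
    expect_equal(steady_state_traits("sizer", 8, re, rp, 160)$l_max, 160)
  # timer cell number does not depend on the elongation rate
  for (re in c(0.2, 0.45, 0.9))
    expect_equal(steady_state_traits("timer", 8, re, 1.75, 5)$N_EZ, 5 * 1.75)
  # l_diff identity l_max = l_0EZ * r_EZ^N_EZ
  for (m in c("sizer", "timer", "dilution")) {
    tr <- steady_state_traits(m, 8, 0.45, 1.75,
                              switch(m, sizer = 160, timer = 6.5,
                                     dilution = 40), k = 0.1)
    expect_equal(tr$l_max, 8 * tr$r_EZ^tr$N_EZ, tolerance = 1e-12)
  }
})

test_that("noiseless simulations match the closed forms for all four rules", {
  cases <- list(
    sizer = list(pars = det_pars, k = 0),
    timer = list(pars = replace(det_pars, "threshold", 4), k = 0),
    ruler = list(pars = replace(det_pars, "threshold", 100), k = 0),
    dilution = list(pars = replace(det_pars, "threshold", 16), k = 0.2))
  for (m in names(cases)) {
    pars <- cases[[m]]$pars
    traj <- simulate_root_file(pars, m, t_end = 60, k = cases[[m]]$k)
    th <- steady_state_traits(m, pars$l0, pars$r_elong, pars$R_prod,
                              pars$threshold, k = cases[[m]]$k)
    # pre-entry snapshots in the stationary regime
    ev <- traj$cells$entry_time
    ev <- ev[ev > 30 & ev < 55]
    nez <- vapply(ev, function(t) snapshot(traj, t - 1e-9)$N_EZ, 0)
    lez <- vapply(ev, function(t) snapshot(traj, t - 1e-9)$L_EZ, 0)
    expect_lt(abs(mean(nez) - th$N_EZ), 1)
    expect_lt(abs(mean(lez) - th$L_EZ) / th$L_EZ, th$r_EZ - 1)
    # differentiation length and growth rate
    done <- !is.na(traj$cells$stop_time) & traj$cells$stop_time > 30
    expect_equal(mean(traj$cells$stop_length[done]), th$l_max,
                 tolerance = 1e-6)
    expect_equal(sim_root_growth_rate(traj, t_from = 30), th$R_growth,
                 tolerance = 0.02)
  }
})

test_that("relation curves reproduce the per-model theoretical lines", {
  base <- list(l_0EZ = 10, r_elong = log(2), R_prod = 1, threshold = 160)
  # sizer: mature length pinned by the threshold whatever the rate
  cs <- relation_curve("sizer", "lmax_vs_inv_rEZ", "r_elong", base,
                       grid = seq(0.3, 1.2, by = 0.1))
  expect_true(all(cs$y == 160))
  # ruler: EZ length pinned by the threshold distance within one cell
  br <- replace(base, "threshold", 100)
  cr <- relation_curve("ruler", "LEZ_vs_NEZ", "r_elong", br,
                       grid = seq(0.4, 1.0, by = 0.05))
  lmax <- 10 * exp(cr$value)^cr$x       # mature cell length at each point
  expect_true(all(abs(cr$y - 100) < 1.5 * lmax))
  # timer swept by R_prod: straight line through the origin with slope
  # r_elong * T_0
  bt <- replace(base, "threshold", 4)
  ct <- relation_curve("timer", "NEZ_vs_inv_ln_rEZ", "R_prod", bt,
                       grid = seq(0.5, 3, by = 0.25))
  fit <- stats::lm(y ~ x, ct)
  expect_equal(unname(stats::coef(fit)[2]), log(2) * 4, tolerance = 1e-9)
  expect_equal(unname(stats::coef(fit)[1]), 0, tolerance = 1e-9)
  # timer swept by r_elong traces a different line (rate duality)
  ct2 <- relation_curve("timer", "NEZ_vs_inv_ln_rEZ", "r_elong", bt,
                        grid = seq(0.3, 1.2, by = 0.1))
  expect_true(all(ct2$y == 4))   # N_EZ insensitive to the elongation rate
})
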