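test_that("population sampling is degenerate at zero spread and respects positivity", {
  pp <- population_params("sizer", R_prod = 1.75, l0 = 8, r_elong = 0.45,
                          threshold = 160, n_roots = 20)
  pop <- sample_population(pp, seed = 1)
  expect_equal(pop$R_prod, rep(1.75, 20))
  expect_equal(pop$threshold, rep(160, 20))

  # truncated-normal oracle by numerical integration of the >0-restricted
  # normal density
  trunc_mean <- function(mu, sd) {
    z <- stats::integrate(function(x) x * stats::dnorm(x, mu, sd), 0, Inf)$value
    z / (1 - stats::pnorm(0, mu, sd))
  }
  set.seed(2)
  draws <- rootzone:::rnorm_pos(1e4, 1.0, 0.2)
  expect_true(all(draws > 0))
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - trunc_mean(1.0, 0.2)), 3 * se)

  # strong truncation case to actually exercise the rejection loop
  set.seed(3)
  draws2 <- rootzone:::rnorm_pos(1e4, 0.5, 0.5)
  expect_lt(abs(mean(draws2) - trunc_mean(0.5, 0.5)),
            4 * stats::sd(draws2) / sqrt(1e4))

  expect_error(rootzone:::rnorm_pos(10, -5, 0.001, cap = 1e4), "rejection cap")
  expect_error(population_params("sizer", R_prod = 1, l0 = 8,
                                 r_elong = 0.45, threshold = 160,
                                 delta = c(l0 = 1), sigma = c(l0 = 2)),
               "sigma")
})

test_that("deterministic sizer file stops every cell 4 h after entry at 160 um", {
  cl <- det_sizer$cells
  done <- !is.na(cl$stop_time)
  expect_equal(cl$stop_time[done] - cl$entry_time[done],
               rep(4, sum(done)))
  expect_equal(cl$stop_length[done], rep(160, sum(done)))
  # stationary pre-entry snapshot: lengths 20, 40, 80, 160
  s <- snapshot(det_sizer, 20 - 1e-9)
  expect_equal(s$N_EZ, 4)
  expect_equal(s$lengths, c(20, 40, 80, 160), tolerance = 1e-6)
  expect_equal(s$L_EZ, sum(s$lengths))
  expect_equal(s$l_max, 160, tolerance = 1e-6)
})

test_that("deterministic timer file time-averages four EZ cells", {
  expect_equal(mean_nez_at_entries(det_timer, 10), 4, tolerance = 0.01)
  cl <- det_timer$cells
  done <- !is.na(cl$stop_time)
  expect_equal(cl$stop_time[done] - cl$entry_time[done], rep(4, sum(done)))
})

test_that("ruler rule fires at entry events via the center-distance test", {
  cl <- det_ruler$cells
  # hand enumeration: first stop when cells 20 + 40 + 80/2 reach 100 um,
  # i.e. at the entry event at t = 3, stopping the cell born at t = 0
  first <- cl[which(!is.na(cl$stop_time))[1], ]
  expect_equal(first$entry_time, 0)
  expect_equal(first$stop_time, 3)
  expect_equal(first$stop_length, 80)
  s <- snapshot(det_ruler, 20 - 1e-9)
  expect_equal(s$N_EZ, 3)
  expect_equal(s$lengths, c(20, 40, 80), tolerance = 1e-6)
})

test_that("snapshot uses the half-open zone convention at stop instants", {
  # at exactly t = 4 the first sizer cell has stopped (DZ), and the cell
  # entering at t = 4 is already counted in the EZ
  s <- snapshot(det_sizer, 4)
  expect_equal(s$dz_count, 1)
  expect_equal(s$dz_length, 160)
  expect_equal(s$N_EZ, 4)
  # before the first entry the snapshot is empty
  s0 <- snapshot(det_sizer, -1)
  expect_equal(s0$N_EZ, 0)
  expect_true(is.na(s0$l_max))
  expect_error(snapshot(det_sizer, 41), "t_end")
})

test_that("stationarity detection flags short runs and finds the plateau", {
  expect_true(is.finite(detect_stationary(det_sizer, window = 5)))
  short <- simulate_root_file(det_pars, "sizer", t_end = 1)
  expect_true(is.na(detect_stationary(short)))
  expect_match(attr(detect_stationary(short), "reason"), "blocks")
})

test_that("growth rate equals one mature cell per entry interval and growth is linear", {
  expect_equal(sim_root_growth_rate(det_sizer, t_from = 10), 160,
               tolerance = 1e-6)
  expect_error(sim_root_growth_rate(det_sizer, t_from = 39.5), "3 grid points")
  # R^2 of the cumulative DZ length fit on a stochastic run
  pp <- preset_params("wt_epidermis_sizer")
  pop <- sample_population(pp, seed = 4)
  traj <- simulate_root_file(pop[1, ], "sizer", t_end = 240, seed = 4,
                             sigma = pp$sigma)
  grid <- seq(60, 240, by = 1)
  st <- traj$cells[!is.na(traj$cells$stop_time), ]
  o <- order(st$stop_time)
  dz <- c(0, cumsum(st$stop_length[o]))[findInterval(grid, st$stop_time[o]) + 1]
  expect_gt(summary(stats::lm(dz ~ grid))$r.squared, 0.99)
  # no growth before any differentiation
  early <- simulate_root_file(det_pars, "sizer", t_end = 3.5)
  expect_equal(sim_root_growth_rate(early, t_from = 0, dt = 1), 0)
})

test_that("identical seeds give bit-identical trajectories and cohorts", {
  pp <- preset_params("wt_epidermis_timer")
  pop <- sample_population(pp, seed = 9)
  a <- simulate_root_file(pop[1, ], "timer", t_end = 120, seed = 99,
                          sigma = pp$sigma)
  b <- simulate_root_file(pop[1, ], "timer", t_end = 120, seed = 99,
                          sigma = pp$sigma)
  expect_identical(a$cells, b$cells)
  ca <- simulate_cohort(preset_params("wt_epidermis_sizer", n_roots = 15),
                        seed = 5)
  cb <- simulate_cohort(preset_params("wt_epidermis_sizer", n_roots = 15),
                        seed = 5)
  expect_identical(ca$traits, cb$traits)
})

test_that("every created cell is elongating or differentiated exactly once", {
  for (traj in list(det_sizer, det_timer, det_ruler)) {
    cl <- traj$cells
    open <- is.na(cl$stop_time)
    expect_identical(open, is.na(cl$stop_length))
    expect_true(all(cl$stop_time[!open] >= cl$entry_time[!open]))
    expect_true(all(cl$stop_time[!open] <= traj$t_end))
    expect_true(all(diff(cl$entry_time) > 0))
  }
})

test_that("dilution rule reduces to a per-cell sizer at k = 0 and to a timer at large k", {
  pars <- list(R_prod = 1, l0 = 10, r_elong = 0.3, threshold = 16)
  sig <- c(R_prod = 0.05, l0 = 0, r_elong = 0.03)
  dil <- simulate_root_file(pars, "dilution", t_end = 100, seed = 7,
                            sigma = sig, k = 0)
  siz <- simulate_root_file(replace(pars, "threshold", 160), "sizer",
                            t_end = 100, seed = 7, sigma = sig)
  expect_equal(dil$cells$stop_time, siz$cells$stop_time, tolerance = 1e-12)
  expect_equal(dil$cells$stop_length, siz$cells$stop_length,
               tolerance = 1e-12)

  # strong degradation: residence time ~ log(ratio)/k, independent of the
  # cell length, i.e. timer behaviour
  k <- 10
  pars2 <- list(R_prod = 1, l0 = 10, r_elong = 0.3,
                threshold = exp(4 * (k + 0.3)))
  dil2 <- simulate_root_file(pars2, "dilution", t_end = 60, seed = 8,
                             sigma = c(R_prod = 0, l0 = 3, r_elong = 0), k = k)
  dur <- with(dil2$cells, stop_time - entry_time)
  dur <- dur[!is.na(dur)]
  expect_lt(stats::sd(dur) / mean(dur), 1e-6)   # length-independent
  expect_equal(mean(dur), 4, tolerance = 0.01)
})
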