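test_that("an exact two-segment profile is recovered to four decimals", {
  fit <- fit_profile(exact_profile)
  expect_equal(fit$status, "ok")
  expect_equal(fit$k, 26L)
  expect_equal(fit$r_MZ, 1.1, tolerance = 1e-5)
  expect_equal(fit$r_EZ, 1.3, tolerance = 1e-5)
  expect_equal(fit$l_0MZ, 6, tolerance = 1e-4)
  expect_equal(fit$l_0EZ, 6 * 1.1^26, tolerance = 1e-4)
  tr <- extract_traits(fit)
  expect_equal(tr$N_MZ, 26)
  expect_equal(tr$N_EZ, 12)
  expect_equal(tr$l_max, 6 * 1.1^26 * 1.3^12)
  expect_equal(tr$L_EZ, sum(exact_lengths[27:38]))
})

test_that("single-exponential profiles are reported as having no elongation zone", {
  p <- measured_profile(5 * 1.12^(1:25), first_hair_index = 26)
  fit <- fit_profile(p)
  expect_equal(fit$status, "no_EZ")
  tr <- extract_traits(fit)
  expect_equal(tr$N_EZ, 0)
  expect_equal(tr$L_EZ, 0)
  expect_true(is.na(tr$r_EZ))
  expect_true(is.na(tr$l_max))
  expect_equal(tr$r_MZ, 1.12, tolerance = 1e-6)
})

test_that("profiles too short to split are rejected with a reason", {
  p <- measured_profile(c(5, 6, 7, 8, 9), first_hair_index = 6)
  fit <- fit_profile(p)
  expect_equal(fit$status, "rejected")
  expect_match(fit$reason, "cells")
  expect_error(predict(fit), "rejected")
})

test_that("round-trip through simulate() recovers parameters to six significant digits", {
  fit <- fit_profile(exact_profile)
  rendered <- simulate(fit, nsim = 1, cv = 0)[[1]]
  refit <- fit_profile(rendered)
  expect_equal(coef(refit), coef(fit), tolerance = 1e-7)
})

test_that("multiplicative noise does not bias the recovered elongation factor", {
  fit <- fit_profile(exact_profile)
  for (s in c(0.02, 0.05, 0.10)) {
    profs <- simulate(fit, nsim = 40, seed = round(1000 * s), cv = s)
    r_hat <- vapply(profs, function(p) fit_profile(p)$r_EZ, 0)
    expect_lt(abs(stats::median(r_hat, na.rm = TRUE) - 1.3) / 1.3,
              max(4 * s^2, 0.01))
  }
})

test_that("fit methods expose the estimator surface coherently", {
  fit <- fit_profile(exact_profile)
  expect_named(coef(fit), c("k", "r_MZ", "r_EZ", "l_0MZ", "l_0EZ"))
  expect_equal(predict(fit, index = 1:38),
               exact_lengths[1:38], tolerance = 1e-6)
  expect_equal(length(residuals(fit)), 38)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  s <- summary(fit)
  expect_s3_class(s, "summary.zonefit")
  expect_output(print(fit), "elongation zone")
  # plotting draws without error
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("cohort fitting logs exclusion bookkeeping that sums to the cohort size", {
  profs <- c(profiles_ok = list(exact_profile),
             list(measured_profile(5 * 1.12^(1:25), first_hair_index = 26)),
             list(measured_profile(c(5, 6, 7, 8, 9), first_hair_index = 6)))
  tab <- fit_cohort(profs)
  cnt <- attr(tab, "counts")
  expect_equal(sum(cnt), nrow(tab))
  expect_equal(unname(cnt["ok"]), 1L)
  expect_equal(unname(cnt["no_EZ"]), 1L)
  expect_equal(unname(cnt["rejected"]), 1L)
})

test_that("measured cohort fits recover the generating geometry", {
  # shared WT cohort, 5% measurement noise
  m <- merge(wt_traits_fit, wt_cohort$manifest, by = "root_id")
  relerr <- abs(m$r_EZ - m$r_EZ_true) / m$r_EZ_true
  expect_lt(stats::median(relerr, na.rm = TRUE), 0.03)
  expect_lt(abs(mean(m$N_EZ, na.rm = TRUE) - 11.8), 1.5)
  expect_lt(abs(mean(m$l_max, na.rm = TRUE) - 160) / 160, 0.05)
})
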