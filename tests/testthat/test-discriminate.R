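test_that("perfect collinearity gives a unit correlation coefficient", {
  tr <- data.frame(r_EZ = seq(1.2, 1.4, length.out = 12),
                   l_max = rep(150, 12))
  tr$N_EZ <- 2 / log(tr$r_EZ)           # exactly proportional to 1/ln r
  tr$L_EZ <- 3 * tr$N_EZ                # exactly proportional to N
  rel <- trait_correlations(tr)
  r3 <- rel[rel$relation == "NEZ_vs_inv_ln_rEZ", ]
  expect_equal(r3$estimate, 1)
  r1 <- rel[rel$relation == "LEZ_vs_NEZ", ]
  expect_equal(r1$estimate, 1)
  expect_equal(r1$slope, 3, tolerance = 1e-9)
  # a zero-variance margin is flagged undefined
  r2 <- rel[rel$relation == "lmax_vs_inv_rEZ", ]
  expect_equal(r2$method, "undefined")
})

test_that("the Pearson/Spearman switch follows the normality gate only", {
  set.seed(11)
  n <- 60
  x <- rnorm(n, 10, 1)
  tr <- data.frame(r_EZ = 1.2 + (x - 10) / 50, l_max = rnorm(n, 150, 10),
                   N_EZ = x, L_EZ = 40 * x + rnorm(n, 0, 5))
  rel <- trait_correlations(tr)
  expect_equal(rel$method[rel$relation == "LEZ_vs_NEZ"], "pearson")
  # replace one margin by a heavily skewed variable
  tr$L_EZ <- exp(rnorm(n, 0, 1.5)) * 100
  rel2 <- trait_correlations(tr)
  expect_equal(rel2$method[rel2$relation == "LEZ_vs_NEZ"], "spearman")
})

test_that("shuffling one margin destroys a relation's significance", {
  tr <- simulate_cohort(preset_params("wt_epidermis_sizer"), seed = 61)$traits
  set.seed(13)
  p <- replicate(60, {
    sh <- tr
    sh$N_EZ <- sample(sh$N_EZ)
    rel <- trait_correlations(sh)
    rel$p_value[rel$relation == "NEZ_vs_inv_ln_rEZ"]
  })
  expect_gt(stats::median(p), 0.05)
})

test_that("a cohort is indistinguishable from itself and from a re-simulation", {
  tr <- simulate_cohort(preset_params("wt_epidermis_sizer"), seed = 21)$traits
  self <- compare_trait_distributions(tr, tr)
  expect_true(all(self$p_value > 0.99))
  expect_true(attr(self, "pass"))
  hits <- vapply(1:20, function(s) {
    re <- simulate_cohort(preset_params("wt_epidermis_sizer"),
                          seed = 3000 + s)$traits
    attr(compare_trait_distributions(re, tr), "pass")
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("halving the sizer threshold is detected through the mature length", {
  a <- simulate_cohort(preset_params("wt_epidermis_sizer"), seed = 31)$traits
  ppb <- cohort_preset("wt_epidermis_sizer")
  ppb$threshold <- 80
  b <- simulate_cohort(preset_params(ppb), seed = 32)$traits
  cmp <- compare_trait_distributions(b, a)
  expect_lt(cmp$p_value[cmp$trait == "l_max"], 0.01)
  expect_false(attr(cmp, "pass"))
  # a missing trait column is skipped and flagged
  cmp2 <- compare_trait_distributions(a[setdiff(names(a), "R_growth")], a)
  expect_true(cmp2$skipped[cmp2$trait == "R_growth"])
})

test_that("each generating rule is recovered from its own cohorts", {
  for (p in c("wt_epidermis_sizer", "wt_epidermis_timer",
              "wt_epidermis_ruler", "wt_epidermis_dilution")) {
    pp <- preset_params(p)
    verdicts <- vapply(1:5, function(s) {
      tr <- simulate_cohort(pp, seed = 700 + s)$traits
      classify_mechanism(trait_correlations(tr))$verdict
    }, "")
    expected <- switch(pp$model, dilution = "mixed_sizer_timer", pp$model)
    expect_gte(mean(verdicts == expected), 0.8)
  }
})

test_that("the verdict trace records every rule evaluated", {
  tr <- simulate_cohort(preset_params("wt_epidermis_sizer"), seed = 71)$traits
  v <- classify_mechanism(trait_correlations(tr))
  expect_length(v$trace, 5)   # four relations plus the sizer caveat
  expect_match(v$trace[1], "L_EZ~N_EZ")
  expect_match(v$trace[4], "center distance")
  expect_output(print(v), "verdict")
})

test_that("calibration refuses degenerate references and logs its search", {
  tiny <- data.frame(r_EZ = c(1.2, 1.3, 1.25), l_max = c(150, 160, 155),
                     L_EZ = c(700, 750, 720), N_EZ = c(11, 12, 11),
                     R_growth = c(270, 280, 275))
  expect_error(calibrate_model(tiny, "sizer"), "10 roots")
})
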