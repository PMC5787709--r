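# Shared fixtures, built once per test run.

# Deterministic doubling geometry: entry every 1 h, entry length 10 um,
# doubling per hour, so the sizer threshold 160 um is hit exactly 4 h
# after entry and the ruler threshold 100 um after 3 cells.
det_pars <- list(R_prod = 1, l0 = 10, r_elong = log(2), threshold = 160)

det_sizer <- simulate_root_file(det_pars, "sizer", t_end = 40)
det_timer <- simulate_root_file(replace(det_pars, "threshold", 4),
                                "timer", t_end = 40)
det_ruler <- simulate_root_file(replace(det_pars, "threshold", 100),
                                "ruler", t_end = 40)

# Exact two-segment profile: 26 meristem cells (factor 1.1 from 6 um),
# then 12 EZ cells continuing with factor 1.3, hair cell at index 39.
exact_lengths <- c(6 * 1.1^(1:26), 6 * 1.1^26 * 1.3^(1:12), 500)
exact_profile <- measured_profile(exact_lengths, first_hair_index = 39)

# One WT-like measured cohort shared across fitting/inference tests.
wt_cohort <- generate_cohort("wt_epidermis_sizer", seed = 101)
wt_traits_fit <- fit_cohort(wt_cohort$profiles)

# Ground-truth trait table (closed-form per-root values) for the
# decorrelation analyses.
wt_truth <- with(wt_cohort$manifest,
                 data.frame(root_id = root_id, r_EZ = r_EZ_true,
                            N_EZ = N_EZ_true, l_0EZ = l0, R_prod = R_prod,
                            l_max = l_max_true, L_EZ = L_EZ_true))

# time-averaged N_EZ over pre-entry snapshots after t_from
mean_nez_at_entries <- function(traj, t_from) {
  cl <- traj$cells
  ev <- cl$entry_time[cl$entry_time > t_from]
  mean(vapply(ev, function(t) snapshot(traj, t - 1e-9)$N_EZ, 0))
}
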