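#' Built-in synthetic cohort presets
#'
#' Named parameter bundles for the synthetic-cohort generator. The
#' wild-type epidermis presets are back-solved from the published cohort
#' statistics through the stationary closed forms (entry interval about
#' 0.57 h, entry length 8 um, elongation rate 0.45 /h and a mature-length
#' threshold of 160 um jointly reproduce an elongation factor near 1.29,
#' about 11.8 EZ cells, a 6-7 h transit time and a growth rate near
#' 280 um/h); they are derived values, not published parameter tables.
#' Threshold spreads follow the published relative variabilities (35%
#' Ruler, 7% Timer, 26% Sizer); the remaining between-root spreads are
#' back-solved from the dispersion of the elongation factor and of the EZ
#' cell count, and within-root spreads default to half the between-root
#' ones. \code{bri1_like} is a dilution-with-degradation cohort with
#' reduced rates (a mixed Sizer-Timer mechanism); \code{pac_like} is a
#' Sizer cohort with a reduced threshold.
#'
#' @param name One of \code{"wt_epidermis_sizer"},
#'   \code{"wt_epidermis_timer"}, \code{"wt_epidermis_ruler"},
#'   \code{"wt_epidermis_dilution"}, \code{"wt_cortex_sizer"},
#'   \code{"bri1_like"}, \code{"pac_like"}.
#' @return A list of class \code{"cohort_preset"} with the population
#'   parameters, the meristem rendering parameters (cell count mean and
#'   sd, meristem elongation factor), the measurement-noise CV and the
#'   cohort size.
#' @export
cohort_preset <- function(name = c("wt_epidermis_sizer", "wt_epidermis_timer",
                                   "wt_epidermis_ruler",
                                   "wt_epidermis_dilution", "wt_cortex_sizer",
                                   "bri1_like", "pac_like")) {
  name <- match.arg(name)
  ## shared WT epidermal rates (derived from the cohort closed forms)
  wt <- list(R_prod = 1.75, l0 = 8, r_elong = 0.45,
             delta_rel = c(R_prod = 0.17, l0 = 0.20, r_elong = 0.25),
             n_roots = 122L,
             meristem = list(N_MZ_mean = 26.2, N_MZ_sd = 2.5, r_MZ = 1.03))
  p <- switch(name,
    wt_epidermis_sizer = c(wt, list(model = "sizer", threshold = 160,
                                    delta_thr_rel = 0.26, k = 0)),
    wt_epidermis_timer = c(wt, list(model = "timer", threshold = 11.8 / 1.75,
                                    delta_thr_rel = 0.07, k = 0)),
    wt_epidermis_ruler = c(wt, list(model = "ruler", threshold = 590,
                                    delta_thr_rel = 0.35, k = 0)),
    ## decay at a third of the elongation rate (mid-range mixed regime):
    ## residence time log(threshold)/(r_elong + k) keeps about 11.8 EZ cells
    wt_epidermis_dilution = c(wt, list(model = "dilution", threshold = 57,
                                       delta_thr_rel = 0.20, k = 0.15)),
    wt_cortex_sizer = {
      w <- wt
      w$r_elong <- 0.47
      w$n_roots <- 30L
      w$meristem <- list(N_MZ_mean = 31.1, N_MZ_sd = 2.5, r_MZ = 1.03)
      c(w, list(model = "sizer", threshold = 143, delta_thr_rel = 0.32,
                k = 0))
    },
    bri1_like = {
      w <- wt
      w$R_prod <- 0.9; w$l0 <- 6; w$r_elong <- 0.30
      w$n_roots <- 126L
      w$meristem <- list(N_MZ_mean = 22, N_MZ_sd = 2.5, r_MZ = 1.03)
      c(w, list(model = "dilution", threshold = 55, delta_thr_rel = 0.20,
                k = 0.10))
    },
    pac_like = {
      w <- wt
      w$R_prod <- 1.2; w$l0 <- 7; w$r_elong <- 0.40
      w$n_roots <- 28L
      c(w, list(model = "sizer", threshold = 90, delta_thr_rel = 0.14,
                k = 0))
    })
  p$name <- name
  p$noise_cv <- 0.05
  p$t_end <- 240
  structure(p, class = "cohort_preset")
}

#' @export
print.cohort_preset <- function(x, ...) {
  cat("Cohort preset '", x$name, "' (", x$model, " rule, n = ", x$n_roots,
      ")\n", sep = "")
  cat(sprintf("  R_prod %.2f cells/h, l0 %.1f um, r_elong %.2f /h, threshold %.3g (rel sd %.0f%%)\n",
              x$R_prod, x$l0, x$r_elong, x$threshold, 100 * x$delta_thr_rel))
  cat(sprintf("  meristem: %.1f +/- %.1f cells, r_MZ %.2f; noise CV %.0f%%\n",
              x$meristem$N_MZ_mean, x$meristem$N_MZ_sd, x$meristem$r_MZ,
              100 * x$noise_cv))
  invisible(x)
}

#' Population parameters implied by a preset
#'
#' @param preset A [cohort_preset()] (or its name).
#' @param n_roots Optional cohort-size override.
#' @return A [population_params()] object.
#' @export
preset_params <- function(preset, n_roots = NULL) {
  if (is.character(preset)) preset <- cohort_preset(preset)
  stopifnot(inherits(preset, "cohort_preset"))
  dr <- preset$delta_rel
  population_params(preset$model, R_prod = preset$R_prod, l0 = preset$l0,
                    r_elong = preset$r_elong, threshold = preset$threshold,
                    k = preset$k,
                    delta = c(R_prod = dr[["R_prod"]] * preset$R_prod,
                              l0 = dr[["l0"]] * preset$l0,
                              r_elong = dr[["r_elong"]] * preset$r_elong,
                              threshold = preset$delta_thr_rel * preset$threshold),
                    n_roots = if (is.null(n_roots)) preset$n_roots else n_roots,
                    t_end = preset$t_end)
}

#' Generate a measured-style synthetic cohort with ground truth
#'
#' Emulates a deposited per-root cell-length dataset: for every root of the
#' preset, a cell file is simulated to its stationary regime and observed
#' once, just before a late differentiation event (when the EZ/DZ boundary
#' — the latest hair-bulge appearance — is sharply defined). The observed
#' elongation-zone lengths are prepended with a static geometric meristem
#' segment (the meristem is rendered, not simulated: its only role is to
#' exercise the breakpoint fit) whose last cell matches the youngest EZ
#' cell for continuity, and followed by one first-root-hair marker cell
#' (the most recently differentiated cell). Every length is then
#' multiplied by mean-one lognormal measurement noise. Roots that fail to
#' reach stationarity are regenerated with an incremented sub-seed.
#'
#' @param preset A [cohort_preset()] or its name.
#' @param seed Integer seed; all randomness derives from it.
#' @param n_roots,noise_cv Optional overrides of the preset values.
#' @return A list of class \code{"synthetic_cohort"}: \code{profiles}
#'   (long-format data frame: root_id, genotype, day, tissue, cell_index,
#'   cell_length_um, is_first_hair), \code{manifest} (one row per root:
#'   true per-root parameters, true stationary traits from the closed
#'   forms, realized snapshot traits, observation time, attempts), and
#'   \code{roots} (the trajectories).
#' @export
generate_cohort <- function(preset, seed = 1L, n_roots = NULL,
                            noise_cv = NULL) {
  if (is.character(preset)) preset <- cohort_preset(preset)
  stopifnot(inherits(preset, "cohort_preset"))
  if (is.null(noise_cv)) noise_cv <- preset$noise_cv
  if (noise_cv < 0 || noise_cv >= 0.3) stop("noise_cv must be in [0, 0.3)")
  pp <- preset_params(preset, n_roots = n_roots)
  roots_pars <- sample_population(pp, seed = seed)
  mz <- preset$meristem
  tissue <- if (grepl("cortex", preset$name)) "cortex" else "epidermis"
  prof_rows <- vector("list", nrow(roots_pars))
  man_rows <- vector("list", nrow(roots_pars))
  roots <- vector("list", nrow(roots_pars))
  for (j in seq_len(nrow(roots_pars))) {
    attempt <- 0L
    repeat {
      sj <- derive_seed(seed, j, attempt)
      traj <- simulate_root_file(roots_pars[j, ], model = pp$model,
                                 t_end = pp$t_end, seed = sj,
                                 sigma = pp$sigma, k = pp$k)
      ts <- detect_stationary(traj)
      cand <- if (is.na(ts)) numeric(0)
              else stationary_stop_times(traj, max(ts, 0.6 * pp$t_end))
      if (length(cand) || attempt >= 5L) break
      attempt <- attempt + 1L
    }
    if (!length(cand))
      stop("root ", j, " never reached stationarity after 6 attempts; ",
           "check the preset parameters")
    t_obs <- cand[sample.int(length(cand), 1L)] - 1e-9
    snap <- snapshot(traj, t_obs)
    ez <- snap$lengths                       # youngest first
    ## the most recently differentiated cell plays the first-hair marker
    stopped <- traj$cells$stop_time
    done <- which(!is.na(stopped) & stopped <= t_obs)
    hair_len <- if (length(done))
      traj$cells$stop_length[done[which.max(stopped[done])]]
    else snap$l_max * 1.05
    n_mz <- max(4L, round(stats::rnorm(1, mz$N_MZ_mean, mz$N_MZ_sd)))
    ## continuity: the last meristem cell sits one meristem step below the
    ## first EZ cell
    l_0mz <- ez[1] / mz$r_MZ^(n_mz + 1)
    lens <- c(l_0mz * mz$r_MZ^seq_len(n_mz), ez, hair_len)
    lens <- lens * lognormal_noise(length(lens), noise_cv)
    n_cells <- length(lens)
    prof_rows[[j]] <- data.frame(
      root_id = roots_pars$root_id[j], genotype = preset$name,
      day = 8L, tissue = tissue, cell_index = seq_len(n_cells),
      cell_length_um = lens,
      is_first_hair = as.integer(seq_len(n_cells) == n_cells))
    th <- steady_state_traits(pp$model, l_0EZ = roots_pars$l0[j],
                              r_elong = roots_pars$r_elong[j],
                              R_prod = roots_pars$R_prod[j],
                              threshold = roots_pars$threshold[j], k = pp$k)
    man_rows[[j]] <- data.frame(
      root_id = roots_pars$root_id[j], preset = preset$name, seed = sj,
      attempts = attempt,
      R_prod = roots_pars$R_prod[j], l0 = roots_pars$l0[j],
      r_elong = roots_pars$r_elong[j], threshold = roots_pars$threshold[j],
      r_EZ_true = th$r_EZ, N_EZ_true = th$N_EZ, l_max_true = th$l_max,
      L_EZ_true = th$L_EZ, R_growth_true = th$R_growth, T_EZ_true = th$T_EZ,
      N_MZ = n_mz, t_obs = t_obs, N_EZ_obs = snap$N_EZ,
      l_max_obs = snap$l_max)
    roots[[j]] <- traj
  }
  structure(list(profiles = do.call(rbind, prof_rows),
                 manifest = do.call(rbind, man_rows),
                 roots = roots, preset = preset, seed = seed,
                 noise_cv = noise_cv),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort '", x$preset$name, "': ", nrow(x$manifest),
      " roots, ", nrow(x$profiles), " cells, noise CV ",
      100 * x$noise_cv, "%\n", sep = "")
  invisible(x)
}

#' Daily root-length series for a synthetic cohort
#'
#' Renders per-root root-length-versus-day tables from the trajectories of
#' a synthetic cohort (or a fresh one generated from a preset). The total
#' simulated length (differentiated plus elongation zone) is read on an
#' effective clock that is linear with a fixed lag from day 4 onward and
#' ramps quadratically before it, emulating the sub-linear early growth of
#' seedlings, and additive Gaussian measurement noise is applied. After
#' day 4 the daily slope equals the trajectory's stationary growth rate up
#' to noise.
#'
#' @param cohort A \code{"synthetic_cohort"} (or a preset / preset name,
#'   from which a cohort is generated with \code{seed}).
#' @param days Postgermination days observed (subset of 1..10).
#' @param seed Seed for the measurement noise (and cohort generation when
#'   a preset is given).
#' @param noise_sd_mm Additive noise sd (mm).
#' @param lag_days Lag of the linear regime.
#' @return Data frame \code{root_id}, \code{day}, \code{root_length_mm}.
#' @export
generate_root_length_series <- function(cohort, days = 1:10, seed = 1L,
                                        noise_sd_mm = 0.1, lag_days = 1.5) {
  if (!inherits(cohort, "synthetic_cohort"))
    cohort <- generate_cohort(cohort, seed = seed)
  if (!all(days %in% 1:10)) stop("days must lie in 1..10")
  set.seed(derive_seed(seed, 999983L))
  u <- ifelse(days >= 4, 24 * (days - lag_days),
              24 * (4 - lag_days) * (days / 4)^2)
  rows <- lapply(seq_along(cohort$roots), function(j) {
    traj <- cohort$roots[[j]]
    len <- vapply(u, function(t) {
      s <- snapshot(traj, min(t, traj$t_end))
      s$dz_length + s$L_EZ
    }, 0) / 1000
    data.frame(root_id = cohort$manifest$root_id[j], day = days,
               root_length_mm = len + stats::rnorm(length(days), 0,
                                                   noise_sd_mm))
  })
  do.call(rbind, rows)
}
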