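#' Simulate one root cell file under a differentiation rule
#'
#' Event-driven simulation of a single file of elongating cells. Cells enter
#' the elongation zone (EZ) sequentially; the i-th inter-arrival interval is
#' \code{1/R_prod_i} with \code{R_prod_i} drawn from the within-root
#' Gaussian. Each cell receives an entry length \code{l0_i} and a relative
#' elongation rate \code{r_i}, and then grows exponentially,
#' \code{l_i(t) = l0_i * exp(r_i * (t - t_i))}, until it differentiates:
#' \itemize{
#'   \item \strong{timer}: at fixed residence time, \code{t_i + T0}.
#'   \item \strong{sizer}: when its length reaches the threshold length
#'     (immediately if it enters at or above it).
#'   \item \strong{dilution}: when an initial signal concentration, diluted
#'     by expansion and degraded at rate \code{k}, falls below threshold;
#'     closed form \code{tau = log(ratio) / (r_i + k)}. \code{k = 0} is a
#'     Sizer with per-cell threshold \code{l0_i * ratio}; large \code{k}
#'     approaches a Timer.
#'   \item \strong{ruler}: evaluated only at cell-entry events. Just before
#'     a new cell is created, any elongating cell whose center lies at or
#'     beyond the threshold distance from the meristem end stops. The
#'     center distance of a cell is the summed current length of all
#'     younger elongating cells plus half its own length.
#' }
#' The dynamics start from a single cell at time 0 and run to \code{t_end};
#' cells still elongating then have open (\code{NA}) stop fields.
#'
#' @param pars Per-root parameters: a one-row data frame or named list with
#'   \code{R_prod}, \code{l0}, \code{r_elong}, \code{threshold} (means for
#'   this root), e.g. one row of [sample_population()].
#' @param model Differentiation rule, as in [population_params()].
#' @param t_end Final time (h).
#' @param seed Optional integer seed.
#' @param sigma Named within-root standard deviations for \code{R_prod},
#'   \code{l0}, \code{r_elong} (the threshold is root-specific and has no
#'   within-root spread). Defaults to all zero.
#' @param k Dilution-rule decay rate (1/h).
#'
#' @return An object of class \code{"root_file"}: a list with \code{model},
#'   \code{pars}, \code{sigma}, \code{k}, \code{t_end} and \code{cells}, a
#'   data frame with one row per created cell (\code{index},
#'   \code{entry_time}, \code{l0}, \code{r_elong}, \code{stop_time},
#'   \code{stop_length}; stop fields \code{NA} while still elongating).
#' @seealso [snapshot()], [detect_stationary()], [sim_root_growth_rate()]
#' @export
simulate_root_file <- function(pars, model = c("sizer", "timer", "ruler", "dilution"),
                               t_end = 240, seed = NULL, sigma = NULL, k = 0) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  pars <- as.list(pars)
  need <- c("R_prod", "l0", "r_elong", "threshold")
  if (!all(need %in% names(pars)))
    stop("pars must provide ", paste(need, collapse = ", "))
  for (p in need) if (!is.finite(pars[[p]]) || pars[[p]] <= 0)
    stop("non-positive parameter: ", p)
  if (model == "dilution" && pars$threshold <= 1)
    stop("dilution threshold ratio must exceed 1")
  sigma <- fill_named(sigma, c("R_prod", "l0", "r_elong"))

  ## sequential entries: first cell at t = 0, then closed intervals
  n_guess <- max(16L, ceiling(t_end * pars$R_prod * 1.3) + 8L)
  entry <- numeric(0)
  last <- 0
  repeat {
    rp <- rnorm_pos(n_guess, pars$R_prod, sigma[["R_prod"]])
    entry <- c(entry, last + cumsum(1 / rp))
    if (entry[length(entry)] > t_end) break
    last <- entry[length(entry)]
  }
  entry <- c(0, entry[entry <= t_end])
  n <- length(entry)
  l0 <- rnorm_pos(n, pars$l0, sigma[["l0"]])
  rr <- rnorm_pos(n, pars$r_elong, sigma[["r_elong"]])

  stop_time <- rep(NA_real_, n)
  if (model == "timer") {
    stop_time <- entry + pars$threshold
  } else if (model == "sizer") {
    stop_time <- entry + pmax(0, log(pars$threshold / l0) / rr)
  } else if (model == "dilution") {
    stop_time <- entry + log(pars$threshold) / (rr + k)
  } else { # ruler: evaluate at each entry event, before the new cell exists
    elong <- integer(0)                # indices of elongating cells, oldest first
    for (e in seq_len(n)) {
      if (length(elong)) {
        te <- entry[e]
        len <- l0[elong] * exp(rr[elong] * (te - entry[elong]))
        ## center distance from meristem end: younger cells' lengths + half own
        center <- rev(cumsum(rev(len))) - len / 2
        hit <- center >= pars$threshold
        if (any(hit)) {
          stop_time[elong[hit]] <- te
          elong <- elong[!hit]
        }
      }
      elong <- c(elong, e)
    }
  }
  open <- !is.na(stop_time) & stop_time > t_end
  stop_time[open] <- NA_real_
  stop_length <- l0 * exp(rr * (stop_time - entry))

  structure(list(model = model, pars = pars, sigma = sigma,
                 k = if (model == "dilution") k else 0, t_end = t_end,
                 cells = data.frame(index = seq_len(n), entry_time = entry,
                                    l0 = l0, r_elong = rr,
                                    stop_time = stop_time,
                                    stop_length = stop_length)),
            class = "root_file")
}

#' @export
print.root_file <- function(x, ...) {
  n <- nrow(x$cells)
  ndz <- sum(!is.na(x$cells$stop_time))
  cat("Simulated root cell file (", x$model, " rule)\n", sep = "")
  cat(n, "cells entered over", format(x$t_end), "h;",
      ndz, "differentiated,", n - ndz, "still elongating\n")
  invisible(x)
}

#' @export
plot.root_file <- function(x, what = c("n_ez", "length"), ...) {
  what <- match.arg(what)
  tt <- sort(unique(c(x$cells$entry_time, stats::na.omit(x$cells$stop_time))))
  if (what == "n_ez") {
    nez <- vapply(tt + 1e-9, function(t) snapshot(x, min(t, x$t_end))$N_EZ, 0)
    graphics::plot(tt, nez, type = "s", xlab = "time (h)",
                   ylab = expression(N[EZ] ~ "(cells)"), ...)
  } else {
    len <- vapply(tt, function(t) {
      s <- snapshot(x, t)
      s$dz_length + s$L_EZ
    }, 0)
    graphics::plot(tt, len / 1000, type = "l", xlab = "time (h)",
                   ylab = "simulated root length (mm)", ...)
  }
  invisible(x)
}

#' Observe the elongation zone of a simulated root file at one time
#'
#' Reports the cells elongating at \code{t_obs}, each at its current
#' exponential length. Zone membership uses the half-open convention
#' \code{[entry, stop)}: a cell entering exactly at \code{t_obs} is counted
#' in the EZ and a cell stopping exactly at \code{t_obs} is counted in the
#' differentiation zone (DZ).
#'
#' @param x A \code{"root_file"} object.
#' @param t_obs Observation time (h), at most \code{t_end}.
#' @return A list of class \code{"root_snapshot"}: \code{t_obs},
#'   \code{lengths} (um, youngest cell first), \code{N_EZ}, \code{L_EZ}
#'   (sum of lengths), \code{l_max} (current length of the oldest
#'   elongating cell, the EZ cell next to the root hair), \code{dz_length}
#'   (summed final lengths of differentiated cells) and \code{dz_count}.
#' @export
snapshot <- function(x, t_obs) {
  stopifnot(inherits(x, "root_file"))
  if (t_obs > x$t_end) stop("t_obs exceeds t_end")
  cl <- x$cells
  in_ez <- cl$entry_time <= t_obs & (is.na(cl$stop_time) | cl$stop_time > t_obs)
  done <- !is.na(cl$stop_time) & cl$stop_time <= t_obs
  idx <- which(in_ez)
  idx <- idx[order(cl$entry_time[idx], decreasing = TRUE)]  # youngest first
  len <- cl$l0[idx] * exp(cl$r_elong[idx] * (t_obs - cl$entry_time[idx]))
  structure(list(t_obs = t_obs, lengths = len, N_EZ = length(idx),
                 L_EZ = sum(len),
                 l_max = if (length(len)) len[length(len)] else NA_real_,
                 dz_length = sum(cl$stop_length[done]), dz_count = sum(done)),
            class = "root_snapshot")
}

#' @export
print.root_snapshot <- function(x, ...) {
  cat("Snapshot at t =", format(x$t_obs), "h: N_EZ =", x$N_EZ,
      " L_EZ =", round(x$L_EZ, 1), "um  l_max =", round(x$l_max, 1),
      "um\nDZ:", x$dz_count, "cells,", round(x$dz_length, 1), "um\n")
  invisible(x)
}

## N_EZ evaluated just before each entry event (the new cell not yet counted,
## cells stopping exactly then already in the DZ)
n_ez_at_entries <- function(x) {
  cl <- x$cells
  stops <- sort(cl$stop_time[!is.na(cl$stop_time)])
  (seq_len(nrow(cl)) - 1L) - findInterval(cl$entry_time, stops)
}

#' Detect the onset of the stationary regime
#'
#' A simulated file starts from a single cell and passes through a transient
#' during which the number of elongating cells builds up. All cohort
#' statistics are taken after the transient. The onset is found from the
#' number of EZ cells recorded at successive entry events: the series is cut
#' into consecutive blocks of \code{window} events, and the start of the
#' first block whose mean differs from the previous block's mean by less
#' than \code{tol} (relative) is returned.
#'
#' @param x A \code{"root_file"} object.
#' @param window Number of entry events per averaging block.
#' @param tol Relative tolerance between consecutive block means.
#' @return Onset time t* in hours, or \code{NA} if the file never
#'   stabilizes within \code{t_end} (too few events, or the tolerance is
#'   never met); the reason is attached as attribute \code{"reason"}.
#' @export
detect_stationary <- function(x, window = 20L, tol = 0.05) {
  stopifnot(inherits(x, "root_file"))
  nez <- n_ez_at_entries(x)
  nb <- length(nez) %/% window
  if (nb < 2L)
    return(structure(NA_real_, reason = "fewer than two averaging blocks"))
  bm <- vapply(seq_len(nb), function(b)
    mean(nez[((b - 1L) * window + 1L):(b * window)]), 0)
  for (b in 2:nb) {
    if (bm[b - 1L] > 0 && abs(bm[b] - bm[b - 1L]) <= tol * bm[b - 1L])
      return(x$cells$entry_time[(b - 1L) * window + 1L])
  }
  structure(NA_real_, reason = "block means never settled within tolerance")
}

#' Stationary root growth rate of a simulated file
#'
#' Least-squares slope of the cumulative differentiated-zone length against
#' time, sampled on a regular grid after \code{t_from}. In the stationary
#' regime this equals the product of the meristematic activity and the
#' mature cell length.
#'
#' @param x A \code{"root_file"} object.
#' @param t_from Start of the fitting window (h); defaults to the detected
#'   stationarity onset.
#' @param dt Grid spacing (h).
#' @return Growth rate in um/h. Zero before any differentiation.
#' @export
sim_root_growth_rate <- function(x, t_from = NULL, dt = 1) {
  stopifnot(inherits(x, "root_file"))
  if (is.null(t_from)) {
    t_from <- detect_stationary(x)
    if (is.na(t_from)) stop("no stationary window: ", attr(t_from, "reason"))
  }
  grid <- seq(t_from, x$t_end, by = dt)
  if (length(grid) < 3L) stop("need at least 3 grid points after t_from")
  st <- x$cells$stop_time[!is.na(x$cells$stop_time)]
  sl <- x$cells$stop_length[!is.na(x$cells$stop_time)]
  o <- order(st)
  dz <- c(0, cumsum(sl[o]))[findInterval(grid, st[o]) + 1L]
  if (all(dz == 0)) return(0)
  unname(stats::coef(stats::lm.fit(cbind(1, grid), dz))[2L])
}

## observation times anchored at boundary-advancing differentiation events:
## profiles are read just before the oldest elongating cell enters the DZ,
## when the EZ/DZ boundary (first hair bulge) is sharply defined and the
## last EZ cell sits at its differentiation length. Under within-root
## variability cells can stop out of entry order; only stops of the
## entry-order-oldest elongating cell qualify. Returns candidate stop times
## in (t_min, t_end].
stationary_stop_times <- function(x, t_min) {
  st <- x$cells$stop_time          # cells ordered by entry time
  older_max <- cummax(c(-Inf, ifelse(is.na(st), Inf, st)))[seq_along(st)]
  ok <- !is.na(st) & older_max <= st & st > t_min & st <= x$t_end
  sort(st[ok])
}

#' Simulate a cohort of root files and extract per-root phenotypic traits
#'
#' Runs [simulate_root_file()] for every root of a cohort and reduces each
#' trajectory to the trait set used throughout the discrimination analyses:
#' the elongation factor \code{r_EZ} (estimated from the log-linear length
#' profile of the EZ snapshot), \code{N_EZ}, \code{L_EZ}, \code{l_max} and
#' the root growth rate \code{R_growth}. Each root is observed once, just
#' before a differentiation event drawn at random from the late stationary
#' window, so that the oldest EZ cell sits at its final length.
#'
#' @param params A [population_params()] object.
#' @param seed Integer seed; per-root streams are derived from it.
#' @param keep_roots Keep the trajectory objects in the result?
#' @param window,tol Stationarity detection settings, see
#'   [detect_stationary()].
#' @return A list of class \code{"sim_cohort"} with \code{traits} (data
#'   frame: root_id, realized per-root parameter means, t_star, t_obs,
#'   r_EZ, N_EZ, L_EZ, l_max, R_growth) and, if requested, \code{roots}.
#'   Roots that never reach stationarity are dropped and counted in
#'   attribute \code{"n_excluded"} of the traits table.
#' @export
simulate_cohort <- function(params, seed = 1L, keep_roots = FALSE,
                            window = 20L, tol = 0.05) {
  stopifnot(inherits(params, "population_params"))
  roots_pars <- sample_population(params, seed = seed)
  n <- nrow(roots_pars)
  rows <- vector("list", n)
  roots <- if (keep_roots) vector("list", n) else NULL
  excluded <- 0L
  for (j in seq_len(n)) {
    sj <- derive_seed(seed, j)
    traj <- simulate_root_file(roots_pars[j, ], model = params$model,
                               t_end = params$t_end, seed = sj,
                               sigma = params$sigma, k = params$k)
    ts <- detect_stationary(traj, window = window, tol = tol)
    if (is.na(ts)) { excluded <- excluded + 1L; next }
    cand <- stationary_stop_times(traj, max(ts, 0.6 * params$t_end))
    if (!length(cand)) cand <- stationary_stop_times(traj, ts)
    if (!length(cand)) { excluded <- excluded + 1L; next }
    t_obs <- cand[sample.int(length(cand), 1L)] - 1e-9
    snap <- snapshot(traj, t_obs)
    rows[[j]] <- data.frame(
      root_id = roots_pars$root_id[j],
      R_prod = roots_pars$R_prod[j], l0 = roots_pars$l0[j],
      r_elong = roots_pars$r_elong[j], threshold = roots_pars$threshold[j],
      t_star = as.numeric(ts), t_obs = t_obs,
      r_EZ = profile_elongation_factor(snap$lengths),
      N_EZ = snap$N_EZ, L_EZ = snap$L_EZ, l_max = snap$l_max,
      R_growth = sim_root_growth_rate(traj, t_from = ts))
    if (keep_roots) roots[[j]] <- traj
  }
  traits <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(traits) <- NULL
  traits$inv_r_EZ <- 1 / traits$r_EZ
  traits$inv_ln_r_EZ <- 1 / log(traits$r_EZ)
  attr(traits, "n_excluded") <- excluded
  structure(list(traits = traits, roots = roots, params = params,
                 seed = seed), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort (", x$params$model, " rule): ",
      nrow(x$traits), " roots\n", sep = "")
  print(round(colMeans(x$traits[c("r_EZ", "N_EZ", "L_EZ", "l_max",
                                  "R_growth")], na.rm = TRUE), 3))
  invisible(x)
}

## slope of log(length) on EZ rank; the exponential of the slope is the
## elongation factor. Needs at least 4 cells.
profile_elongation_factor <- function(lengths) {
  n <- length(lengths)
  if (n < 4L) return(NA_real_)
  x <- seq_len(n) - (n + 1) / 2
  y <- log(lengths)
  exp(sum(x * (y - mean(y))) / sum(x * x))
}

## deterministic per-root sub-seed, kept within 32-bit integer range
derive_seed <- function(seed, j, attempt = 0L) {
  as.integer((as.numeric(seed) * 48271 + j * 7919 + attempt * 104729) %%
               2147483647)
}
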