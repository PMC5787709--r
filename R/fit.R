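#' A measured single-root cell-length profile
#'
#' One root's ordered cell lengths, indexed from the first cell distal to
#' the quiescent center (index 1) outward, together with the position of
#' the first root-hair (mature) cell, which marks the exclusive end of the
#' elongation zone.
#'
#' @param lengths Positive cell lengths (um), ordered by position.
#' @param first_hair_index Index of the first mature cell;
#'   \code{length(lengths) + 1} (the default) means no hair cell was
#'   observed within the measured span.
#' @param root_id,genotype,day,tissue Metadata carried through to trait
#'   tables.
#' @return An object of class \code{"measured_profile"}.
#' @export
measured_profile <- function(lengths, first_hair_index = length(lengths) + 1L,
                             root_id = "root_001", genotype = "",
                             day = NA_integer_,
                             tissue = c("epidermis", "cortex")) {
  tissue <- match.arg(tissue)
  lengths <- as.numeric(lengths)
  if (length(lengths) < 4L) stop("a profile needs at least 4 cells")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("cell lengths must be positive and finite")
  first_hair_index <- as.integer(first_hair_index)
  if (first_hair_index < 2L || first_hair_index > length(lengths) + 1L)
    stop("first_hair_index must lie in 2..n+1")
  structure(list(lengths = lengths, first_hair_index = first_hair_index,
                 root_id = root_id, genotype = genotype, day = day,
                 tissue = tissue),
            class = "measured_profile")
}

#' @export
print.measured_profile <- function(x, ...) {
  cat("Cell-length profile ", x$root_id, " (", x$tissue, "): ",
      length(x$lengths), " cells, first hair at index ",
      x$first_hair_index, "\n", sep = "")
  invisible(x)
}

#' Fitting constraints for the two-segment profile fit
#'
#' The admissibility rules for the breakpoint search of [fit_profile()]:
#' minimum segment sizes, the requirement that the EZ slope exceed the MZ
#' slope, and a floor on the EZ elongation factor. The defaults reproduce
#' the two-segment log-linear geometry of measured profiles while remaining
#' tunable.
#'
#' @param min_mz Minimum number of meristem cells (breakpoint floor).
#' @param min_ez Minimum number of elongation-zone cells.
#' @param r_min Minimum admissible elongation factor \code{r_EZ}.
#' @param r_max Maximum admissible \code{r_EZ}: guards against degenerate
#'   near-zero-residual fits of a very short, steep tail segment in
#'   profiles with strong cell-to-cell length inversions (biological
#'   elongation factors are well below this cap).
#' @param min_gap Minimum ratio between the EZ and MZ elongation factors:
#'   a profile whose best split separates the two slopes by less than this
#'   factor is a single exponential for practical purposes and is reported
#'   as having no elongation zone.
#' @param l0ez_from \code{"fit"} evaluates \code{l_0EZ} from the EZ segment
#'   line at the breakpoint index (robust to single-cell noise);
#'   \code{"raw"} uses the measured length of the breakpoint cell.
#' @return A list of class \code{"fit_config"}.
#' @export
fit_config <- function(min_mz = 4L, min_ez = 2L, r_min = 1.05, r_max = 3,
                       min_gap = 1.02, l0ez_from = c("fit", "raw")) {
  l0ez_from <- match.arg(l0ez_from)
  stopifnot(min_mz >= 2L, min_ez >= 2L, r_min > 1, r_max > r_min,
            min_gap >= 1)
  structure(list(min_mz = as.integer(min_mz), min_ez = as.integer(min_ez),
                 r_min = r_min, r_max = r_max, min_gap = min_gap,
                 l0ez_from = l0ez_from),
            class = "fit_config")
}

## simple-regression helper returning slope, intercept and SSE
ls_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- if (sxx > 0) sum((x - mx) * (y - my)) / sxx else 0
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  c(slope = slope, intercept = intercept, sse = sum(res^2))
}

#' Two-segment exponential fit of a root cell-length profile
#'
#' The automated zonation fit: cell lengths up to (and excluding) the first
#' root-hair cell are log10-transformed and, for every admissible
#' breakpoint k, straight lines are fit by least squares to segments
#' \code{[1..k]} (meristem) and \code{[k+1..m]} (elongation zone). The
#' breakpoint minimizing the total residual sum of squares, subject to the
#' constraints of [fit_config()] (EZ slope above MZ slope, \code{r_EZ}
#' above its floor, minimum segment sizes), defines the meristem size; the
#' segment slopes give the zone elongation factors,
#' \code{r = 10^slope}. Ties in the residual sum of squares are broken
#' toward the larger breakpoint: in ideal two-segment geometry the EZ line
#' extrapolates exactly through the last meristem cell, so that boundary
#' cell ties between the segments and belongs to the meristem. Profiles
#' with no admissible breakpoint
#' (single-exponential profiles) get status \code{"no_EZ"} and are treated
#' as having an empty elongation zone; profiles with fewer than
#' \code{min_mz + min_ez} usable cells are \code{"rejected"}.
#'
#' @param profile A [measured_profile()], or a bare numeric vector of cell
#'   lengths (then \code{first_hair_index} defaults past the end).
#' @param config A [fit_config()].
#' @return An object of class \code{"zonefit"} with components \code{k}
#'   (breakpoint, last meristem cell), \code{r_MZ}, \code{r_EZ},
#'   \code{l_0MZ}, \code{l_0EZ}, per-segment slopes/intercepts (log10) and
#'   residual sums of squares, \code{status} (\code{"ok"}, \code{"no_EZ"},
#'   \code{"rejected"}), \code{m} (cells used) and the profile.
#' @seealso [extract_traits()], [fit_cohort()]
#' @examples
#' lens <- c(6 * 1.1^(1:26), 6 * 1.1^26 * 1.3^(1:12))
#' fit <- fit_profile(measured_profile(lens, first_hair_index = 39))
#' coef(fit)["r_EZ"]  # 1.3
#' @export
fit_profile <- function(profile, config = fit_config()) {
  if (is.numeric(profile)) profile <- measured_profile(profile)
  stopifnot(inherits(profile, "measured_profile"),
            inherits(config, "fit_config"))
  m <- profile$first_hair_index - 1L
  base <- list(profile = profile, config = config, m = m,
               k = NA_integer_, slope_mz = NA_real_, int_mz = NA_real_,
               slope_ez = NA_real_, int_ez = NA_real_,
               r_MZ = NA_real_, r_EZ = NA_real_,
               l_0MZ = NA_real_, l_0EZ = NA_real_,
               sse_mz = NA_real_, sse_ez = NA_real_)
  if (m < config$min_mz + config$min_ez) {
    base$status <- "rejected"
    base$reason <- sprintf("only %d cells before the first hair (need %d)",
                           m, config$min_mz + config$min_ez)
    return(structure(base, class = "zonefit"))
  }
  idx <- seq_len(m)
  y <- log10(profile$lengths[idx])
  best <- NULL
  best_sse <- Inf
  log10_rmin <- log10(config$r_min)
  for (k in (m - config$min_ez):config$min_mz) {
    f1 <- ls_line(idx[1:k], y[1:k])
    f2 <- ls_line(idx[(k + 1):m], y[(k + 1):m])
    if (f2[["slope"]] < f1[["slope"]] + log10(config$min_gap)) next
    if (f2[["slope"]] < log10_rmin || f2[["slope"]] > log10(config$r_max)) next
    sse <- f1[["sse"]] + f2[["sse"]]
    if (sse < best_sse - 1e-12) {   # strict improvement: ties keep larger k
      best_sse <- sse
      best <- list(k = k, f1 = f1, f2 = f2)
    }
  }
  if (is.null(best)) {
    base$status <- "no_EZ"
    f <- ls_line(idx, y)
    base$slope_mz <- f[["slope"]]; base$int_mz <- f[["intercept"]]
    base$r_MZ <- 10^f[["slope"]]; base$l_0MZ <- 10^f[["intercept"]]
    base$sse_mz <- f[["sse"]]
    return(structure(base, class = "zonefit"))
  }
  base$status <- "ok"
  base$k <- best$k
  base$slope_mz <- best$f1[["slope"]]; base$int_mz <- best$f1[["intercept"]]
  base$slope_ez <- best$f2[["slope"]]; base$int_ez <- best$f2[["intercept"]]
  base$sse_mz <- best$f1[["sse"]]; base$sse_ez <- best$f2[["sse"]]
  base$r_MZ <- 10^base$slope_mz
  base$r_EZ <- 10^base$slope_ez
  base$l_0MZ <- 10^base$int_mz
  base$l_0EZ <- if (config$l0ez_from == "fit")
    10^(base$int_ez + base$slope_ez * best$k)
  else profile$lengths[best$k]
  structure(base, class = "zonefit")
}

#' @export
print.zonefit <- function(x, digits = 4, ...) {
  cat("Two-segment exponential profile fit (", x$status, ")\n", sep = "")
  if (x$status == "ok")
    cat("  meristem: cells 1..", x$k, "  r_MZ = ",
        signif(x$r_MZ, digits), "\n  elongation zone: cells ", x$k + 1,
        "..", x$m, "  r_EZ = ", signif(x$r_EZ, digits), "\n", sep = "")
  else if (x$status == "no_EZ")
    cat("  single-exponential profile, N_EZ = 0 (r_MZ = ",
        signif(x$r_MZ, digits), ")\n", sep = "")
  else cat(" ", x$reason, "\n")
  invisible(x)
}

#' @export
summary.zonefit <- function(object, ...) {
  structure(list(fit = object,
                 coef = coef(object),
                 rse = if (object$status == "ok")
                   sqrt((object$sse_mz + object$sse_ez) / max(1, object$m - 4))
                 else NA_real_),
            class = "summary.zonefit")
}

#' @export
print.summary.zonefit <- function(x, ...) {
  print(x$fit)
  cat("coefficients:\n")
  print(signif(x$coef, 5))
  if (!is.na(x$rse))
    cat("residual standard error (log10 length):", signif(x$rse, 3), "\n")
  invisible(x)
}

#' @export
coef.zonefit <- function(object, ...) {
  c(k = as.numeric(object$k), r_MZ = object$r_MZ, r_EZ = object$r_EZ,
    l_0MZ = object$l_0MZ, l_0EZ = object$l_0EZ)
}

#' Predicted cell lengths from a fitted two-segment profile
#'
#' @param object A \code{"zonefit"}.
#' @param index Cell indices at which to evaluate; defaults to the cells
#'   used in the fit.
#' @param type \code{"length"} (um) or \code{"log10"}.
#' @param ... Unused.
#' @export
predict.zonefit <- function(object, index = seq_len(object$m),
                            type = c("length", "log10"), ...) {
  type <- match.arg(type)
  if (object$status == "rejected") stop("cannot predict from a rejected fit")
  k <- if (object$status == "ok") object$k else object$m
  ly <- ifelse(index <= k,
               object$int_mz + object$slope_mz * index,
               object$int_ez + object$slope_ez * index)
  if (type == "log10") ly else 10^ly
}

#' @export
fitted.zonefit <- function(object, ...) predict(object)

#' @export
residuals.zonefit <- function(object, ...) {
  log10(object$profile$lengths[seq_len(object$m)]) -
    predict(object, type = "log10")
}

#' @export
plot.zonefit <- function(x, ...) {
  p <- x$profile
  n <- length(p$lengths)
  graphics::plot(seq_len(n), p$lengths, log = "y",
                 xlab = "cell position from the QC",
                 ylab = "cell length (um)",
                 col = ifelse(seq_len(n) >= p$first_hair_index,
                              "grey60", "black"), ...)
  if (x$status %in% c("ok", "no_EZ")) {
    k <- if (x$status == "ok") x$k else x$m
    ii <- seq_len(k)
    graphics::lines(ii, 10^(x$int_mz + x$slope_mz * ii), col = "forestgreen")
    if (x$status == "ok") {
      jj <- (k + 1):x$m
      graphics::lines(jj, 10^(x$int_ez + x$slope_ez * jj), col = "orange")
      graphics::abline(v = k + 0.5, lty = 3)
    }
  }
  if (p$first_hair_index <= n)
    graphics::abline(v = p$first_hair_index - 0.5, lty = 3, col = "grey60")
  invisible(x)
}

#' Render noiseless or noisy profiles from a fitted model
#'
#' Draws synthetic profiles from the two-segment exponential geometry of a
#' fit, with optional multiplicative lognormal measurement noise. Useful
#' for round-trip validation of the fitting procedure.
#'
#' @param object A \code{"zonefit"} with status \code{"ok"}.
#' @param nsim Number of profiles.
#' @param seed Optional seed.
#' @param cv Coefficient of variation of the multiplicative noise (0 gives
#'   the exact fitted geometry).
#' @param ... Unused.
#' @return A list of [measured_profile()] objects.
#' @export
simulate.zonefit <- function(object, nsim = 1, seed = NULL, cv = 0, ...) {
  if (object$status != "ok") stop("can only simulate from an 'ok' fit")
  if (!is.null(seed)) set.seed(seed)
  base <- predict(object)
  lapply(seq_len(nsim), function(s) {
    l <- base * lognormal_noise(length(base), cv)
    measured_profile(l, first_hair_index = object$m + 1L,
                     root_id = sprintf("sim_%03d", s),
                     tissue = object$profile$tissue)
  })
}

## mean-one multiplicative lognormal noise with coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Per-root phenotypic traits from a profile fit
#'
#' Combines the fitted zonation with the measured lengths into the trait
#' record used downstream: meristem and EZ cell counts, EZ length (sum of
#' measured EZ cell lengths), the mature cell length \code{l_max} (the
#' measured EZ cell adjacent to the first root-hair cell), the zone
#' elongation factors and derived columns \code{1/r_EZ} and
#' \code{1/ln(r_EZ)}. Roots with no elongation zone keep \code{N_EZ = 0}
#' and \code{L_EZ = 0} with undefined \code{r_EZ} and \code{l_max}; the
#' undefined fields propagate as \code{NA} so such roots drop out of any
#' analysis that needs them.
#'
#' @param fit A \code{"zonefit"}.
#' @param profile The profile; defaults to the one stored in the fit.
#' @return A one-row data frame.
#' @export
extract_traits <- function(fit, profile = fit$profile) {
  stopifnot(inherits(fit, "zonefit"))
  fhi <- profile$first_hair_index
  out <- data.frame(root_id = profile$root_id, genotype = profile$genotype,
                    day = profile$day, tissue = profile$tissue,
                    status = fit$status,
                    N_MZ = NA_real_, N_EZ = NA_real_, L_EZ = NA_real_,
                    l_max = NA_real_, r_MZ = fit$r_MZ, r_EZ = NA_real_,
                    l_0MZ = fit$l_0MZ, l_0EZ = NA_real_)
  if (fit$status == "ok") {
    k <- fit$k
    out$N_MZ <- k
    out$N_EZ <- (fhi - 1L) - k
    out$L_EZ <- sum(profile$lengths[(k + 1):(fhi - 1L)])
    out$l_max <- profile$lengths[fhi - 1L]
    out$r_EZ <- fit$r_EZ
    out$l_0EZ <- fit$l_0EZ
  } else if (fit$status == "no_EZ") {
    out$N_MZ <- fit$m
    out$N_EZ <- 0
    out$L_EZ <- 0
  }
  out$inv_r_EZ <- 1 / out$r_EZ
  out$inv_ln_r_EZ <- 1 / log(out$r_EZ)
  out
}

#' Fit every profile of a cohort and assemble the trait table
#'
#' @param profiles A list of [measured_profile()] objects, or a long-format
#'   data frame as produced by [generate_cohort()] / read by
#'   [read_profiles()].
#' @param config A [fit_config()].
#' @return A data frame with one row per root (see [extract_traits()]);
#'   attribute \code{"counts"} tallies ok / no_EZ / rejected fits.
#' @export
fit_cohort <- function(profiles, config = fit_config()) {
  if (is.data.frame(profiles)) profiles <- profiles_as_list(profiles)
  rows <- lapply(profiles, function(p) extract_traits(fit_profile(p, config)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "counts") <- table(factor(out$status,
                                      levels = c("ok", "no_EZ", "rejected")))
  out
}
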