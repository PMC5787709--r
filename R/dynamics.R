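#' Root growth rate from root-length time series
#'
#' Least-squares slope of root length against postgermination day,
#' converted to um/h. Only days at or after \code{day_min} enter the fit,
#' because early root growth is sub-linear (growth becomes linear around
#' day 4). Two modes mirror the two measurement designs: a cohort-level
#' rate from the slope of the per-day mean lengths (separate plant sets),
#' or a per-root rate from an individual fit to each tracked root.
#'
#' @param lengths Data frame with columns \code{root_id}, \code{day},
#'   \code{root_length_mm}.
#' @param day_min First day included in the fit.
#' @param approach \code{"per_root"} (one rate per root) or \code{"cohort"}
#'   (slope of the daily means).
#' @return For \code{"per_root"}, a data frame \code{root_id},
#'   \code{R_growth} (um/h; \code{NA} with fewer than 3 usable days, the
#'   dropped roots are listed in attribute \code{"dropped"}). For
#'   \code{"cohort"}, a single number.
#' @export
root_growth_rate <- function(lengths, day_min = 4,
                             approach = c("per_root", "cohort")) {
  approach <- match.arg(approach)
  need <- c("root_id", "day", "root_length_mm")
  if (!all(need %in% names(lengths)))
    stop("lengths table needs columns ", paste(need, collapse = ", "))
  use <- lengths[lengths$day >= day_min, , drop = FALSE]
  mm_day_to_um_h <- 1000 / 24
  if (approach == "cohort") {
    daily <- stats::aggregate(root_length_mm ~ day, use, mean)
    if (nrow(daily) < 3L) stop("need at least 3 days at or after day_min")
    return(unname(stats::coef(stats::lm(root_length_mm ~ day, daily))[2L]) *
             mm_day_to_um_h)
  }
  ids <- unique(lengths$root_id)
  slope <- vapply(ids, function(id) {
    d <- use[use$root_id == id, ]
    if (nrow(d) < 3L) return(NA_real_)
    unname(stats::coef(stats::lm(root_length_mm ~ day, d))[2L])
  }, 0)
  out <- data.frame(root_id = ids, R_growth = slope * mm_day_to_um_h)
  attr(out, "dropped") <- ids[is.na(slope)]
  out
}

#' Complete a trait table with inferred dynamical traits
#'
#' From the fitted static traits and a root growth rate, the stationary
#' identities give the dynamical traits: the model mature cell length
#' \code{l_diff = l_0EZ * r_EZ^N_EZ}, the meristematic activity
#' \code{R_prod = R_growth / l_diff}, the relative elongation rate
#' \code{r_elong = R_prod * log(r_EZ)} and the elongation-zone transit time
#' \code{T_EZ = N_EZ / R_prod}. Rows with \code{r_EZ <= 1} or missing
#' inputs are skipped (their inferred columns stay \code{NA}) and listed in
#' attribute \code{"skipped"}.
#'
#' @param traits Trait table containing \code{r_EZ}, \code{N_EZ},
#'   \code{l_0EZ} (or \code{l_max}) and \code{R_growth}. If
#'   \code{R_growth} is missing, supply it via \code{growth}.
#' @param growth Optional per-root growth table from [root_growth_rate()],
#'   joined on \code{root_id}.
#' @param l_diff_source \code{"raw"} (default) uses the measured mature
#'   cell length \code{l_max}; \code{"fit"} uses the fitted identity
#'   \code{l_0EZ * r_EZ^N_EZ}. The identity is exact in the model, but as
#'   an estimator it compounds three fitted quantities exponentially, so
#'   its per-root error is much larger than that of the directly measured
#'   mature length and the inverted \code{R_prod} inherits a noticeable
#'   upward (Jensen) bias; the raw measurement is therefore the default
#'   denominator.
#' @return The trait table with columns \code{l_diff}, \code{R_prod},
#'   \code{r_elong}, \code{T_EZ} added or filled.
#' @export
infer_dynamics <- function(traits, growth = NULL,
                           l_diff_source = c("raw", "fit")) {
  l_diff_source <- match.arg(l_diff_source)
  if (!is.null(growth)) {
    traits$R_growth <- NULL
    traits <- merge(traits, growth, by = "root_id", all.x = TRUE, sort = FALSE)
  }
  if (is.null(traits$R_growth))
    stop("R_growth is required (supply 'growth' or a column)")
  l_diff <- if (l_diff_source == "fit")
    traits$l_0EZ * traits$r_EZ^traits$N_EZ else traits$l_max
  usable <- !is.na(traits$r_EZ) & traits$r_EZ > 1 &
    !is.na(l_diff) & !is.na(traits$R_growth)
  traits$l_diff <- ifelse(usable, l_diff, NA_real_)
  traits$R_prod <- ifelse(usable, traits$R_growth / l_diff, NA_real_)
  traits$r_elong <- ifelse(usable, traits$R_prod * log(traits$r_EZ), NA_real_)
  traits$T_EZ <- ifelse(usable, traits$N_EZ / traits$R_prod, NA_real_)
  attr(traits, "skipped") <- traits$root_id[!usable]
  traits
}
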