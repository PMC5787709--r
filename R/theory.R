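#' Elongation factor from the dynamical rates
#'
#' In the noiseless stationary file, consecutive EZ cells differ in age by
#' the entry interval \code{1/R_prod} and grow exponentially at rate
#' \code{r_elong}, so adjacent cell lengths differ by the factor
#' \code{r_EZ = exp(r_elong / R_prod)}. Equivalently, \code{1/ln(r_EZ)} is
#' the ratio of the meristematic activity to the elongation rate.
#'
#' @param r_elong Relative cell elongation rate (1/h), >= 0.
#' @param R_prod Meristematic activity (cells/h), > 0.
#' @return The elongation factor \code{r_EZ} (dimensionless, >= 1).
#' @examples
#' elongation_factor_from_rates(log(2), 1)   # 2
#' elongation_factor_from_rates(0.446, 1.75) # about 1.29
#' @export
elongation_factor_from_rates <- function(r_elong, R_prod) {
  if (any(R_prod <= 0)) stop("R_prod must be positive")
  if (any(r_elong < 0)) stop("r_elong must be non-negative")
  exp(r_elong / R_prod)
}

#' Closed-form stationary traits for each differentiation rule
#'
#' Stationary elongation-zone traits of the noiseless cell-file model. With
#' \code{r_EZ = exp(r_elong/R_prod)} and the rank-k EZ cell of length
#' \code{l_0EZ * r_EZ^k} (rank 0 being the last meristematic cell):
#' \itemize{
#'   \item \strong{sizer} (threshold = mature length \code{l_diff0}):
#'     \code{N_EZ = log(threshold/l_0EZ)/log(r_EZ)}, \code{l_max = threshold}.
#'   \item \strong{timer} (threshold = residence time \code{T0}):
#'     \code{N_EZ = T0 * R_prod}, \code{l_max = l_0EZ * exp(r_elong*T0)}.
#'   \item \strong{dilution} (threshold = concentration ratio, decay
#'     \code{k}): residence time \code{tau = log(threshold)/(r_elong + k)},
#'     then as the timer with \code{T0 = tau}.
#'   \item \strong{ruler} (threshold = distance \code{L_0}): \code{N_EZ} is
#'     the smallest integer N whose oldest cell center,
#'     \code{sum_{q=1}^{N-1} l_0EZ r_EZ^q + l_0EZ r_EZ^N / 2}, lies at or
#'     beyond \code{L_0}; \code{l_max = l_0EZ * r_EZ^N_EZ}.
#' }
#' All rules share \code{L_EZ = l_0EZ * r_EZ * (r_EZ^N_EZ - 1)/(r_EZ - 1)}
#' (continuous in \code{N_EZ}), the transit time \code{T_EZ = N_EZ/R_prod},
#' the mature-length identity \code{l_diff = l_0EZ * r_EZ^N_EZ} and the
#' growth rate \code{R_growth = R_prod * l_max}.
#'
#' @param model Differentiation rule.
#' @param l_0EZ Entry length (um).
#' @param r_elong Relative elongation rate (1/h).
#' @param R_prod Meristematic activity (cells/h).
#' @param threshold Rule-specific threshold (see above).
#' @param k Dilution decay rate (1/h).
#' @param integer_N Round \code{N_EZ} up to an integer (per-snapshot
#'   interpretation) instead of returning the time-average value.
#' @return A list of class \code{"steady_traits"}: \code{N_EZ},
#'   \code{l_max}, \code{L_EZ}, \code{r_EZ}, \code{R_growth}, \code{T_EZ}.
#' @examples
#' steady_state_traits("sizer", 10, log(2), 1, 160) # N_EZ 4, l_max 160
#' @export
steady_state_traits <- function(model = c("sizer", "timer", "ruler", "dilution"),
                                l_0EZ, r_elong, R_prod, threshold, k = 0,
                                integer_N = FALSE) {
  model <- match.arg(model)
  if (any(c(l_0EZ, R_prod, threshold) <= 0) || r_elong < 0)
    stop("inputs must be positive (r_elong may be zero)")
  r_EZ <- elongation_factor_from_rates(r_elong, R_prod)
  if (model == "sizer") {
    if (threshold <= l_0EZ) {
      warning("sizer threshold at or below the entry length: N_EZ = 0")
      N <- 0
    } else N <- log(threshold / l_0EZ) / log(r_EZ)
    l_max <- threshold
  } else if (model %in% c("timer", "dilution")) {
    tau <- if (model == "timer") threshold else {
      if (threshold <= 1) stop("dilution threshold ratio must exceed 1")
      log(threshold) / (r_elong + k)
    }
    N <- tau * R_prod
    l_max <- l_0EZ * exp(r_elong * tau)
  } else { # ruler
    N <- ruler_cell_count(l_0EZ, r_EZ, threshold)
    l_max <- l_0EZ * r_EZ^N
  }
  if (integer_N) N <- ceiling(N)
  L_EZ <- geometric_zone_length(l_0EZ, r_EZ, N)
  structure(list(model = model, N_EZ = N, l_max = l_max, L_EZ = L_EZ,
                 r_EZ = r_EZ, R_growth = R_prod * l_max,
                 T_EZ = N / R_prod),
            class = "steady_traits")
}

#' @export
print.steady_traits <- function(x, ...) {
  cat("Stationary traits (", x$model, " rule):\n", sep = "")
  v <- unlist(x[c("N_EZ", "l_max", "L_EZ", "r_EZ", "R_growth", "T_EZ")])
  print(round(v, 4))
  invisible(x)
}

## smallest integer N whose oldest-cell center reaches the threshold
## distance; the center distance includes all younger EZ cells plus half of
## the tested cell itself
ruler_cell_count <- function(l_0EZ, r_EZ, L_0, n_max = 1e6) {
  for (N in seq_len(n_max)) {
    younger <- if (N > 1) sum(l_0EZ * r_EZ^seq_len(N - 1)) else 0
    if (younger + l_0EZ * r_EZ^N / 2 >= L_0) return(N)
  }
  stop("ruler threshold unreachable within ", n_max, " cells")
}

geometric_zone_length <- function(l_0EZ, r_EZ, N) {
  if (N == 0) return(0)
  if (abs(r_EZ - 1) < 1e-12) return(l_0EZ * N)
  l_0EZ * r_EZ * (r_EZ^N - 1) / (r_EZ - 1)
}

#' Theoretical trait-pair relationship curves
#'
#' Sweeps one model parameter over a grid and records the stationary traits
#' as (x, y) pairs for one of the three diagnostic relations: elongation
#' zone length against cell number (\code{"LEZ_vs_NEZ"}), mature cell
#' length against \code{1/r_EZ} (\code{"lmax_vs_inv_rEZ"}), or cell number
#' against \code{1/ln(r_EZ)} (\code{"NEZ_vs_inv_ln_rEZ"}). For the Timer
#' rule the curve differs depending on whether the elongation rate or the
#' meristematic activity is swept (two distinct theoretical lines); for the
#' Ruler and Sizer rules the relations are set by the length profile alone.
#' Sweeping the threshold traces the common threshold-dependence line that
#' all rules share.
#'
#' @param model Differentiation rule.
#' @param relation One of \code{"LEZ_vs_NEZ"}, \code{"lmax_vs_inv_rEZ"},
#'   \code{"NEZ_vs_inv_ln_rEZ"}.
#' @param swept Parameter swept: \code{"r_elong"}, \code{"R_prod"} or
#'   \code{"threshold"}.
#' @param base Named list with the fixed values of \code{l_0EZ},
#'   \code{r_elong}, \code{R_prod}, \code{threshold} (and \code{k} for the
#'   dilution rule).
#' @param grid Numeric vector of values for the swept parameter.
#' @param integer_N Passed to [steady_state_traits()].
#' @return Data frame with columns \code{model}, \code{relation},
#'   \code{swept}, \code{value} (the swept value), \code{x}, \code{y}.
#' @export
relation_curve <- function(model, relation = c("LEZ_vs_NEZ", "lmax_vs_inv_rEZ",
                                               "NEZ_vs_inv_ln_rEZ"),
                           swept = c("r_elong", "R_prod", "threshold"),
                           base, grid, integer_N = FALSE) {
  relation <- match.arg(relation)
  swept <- match.arg(swept)
  stopifnot(is.list(base), length(grid) >= 1)
  if (is.null(base$k)) base$k <- 0
  rows <- lapply(grid, function(v) {
    b <- base
    b[[swept]] <- v
    tr <- steady_state_traits(model, b$l_0EZ, b$r_elong, b$R_prod,
                              b$threshold, k = b$k, integer_N = integer_N)
    xy <- switch(relation,
                 LEZ_vs_NEZ = c(tr$N_EZ, tr$L_EZ),
                 lmax_vs_inv_rEZ = c(1 / tr$r_EZ, tr$l_max),
                 NEZ_vs_inv_ln_rEZ = c(1 / log(tr$r_EZ), tr$N_EZ))
    data.frame(model = model, relation = relation, swept = swept,
               value = v, x = xy[1], y = xy[2])
  })
  do.call(rbind, rows)
}
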