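#' Cohort-level population parameters for the cell-file simulator
#'
#' Bundles the cohort means, between-root spreads (Delta) and within-root
#' spreads (sigma) of the four parameters that govern a simulated root cell
#' file: the meristematic activity \code{R_prod} (cells/h; the inter-arrival
#' interval of cells entering the elongation zone is \code{1/R_prod}), the
#' entry length \code{l0} (um), the relative elongation rate \code{r_elong}
#' (1/h), and the model-specific differentiation threshold. The threshold is
#' a distance from the meristem end (um) for the Ruler rule, a residence
#' time (h) for the Timer rule, a cell length (um) for the Sizer rule, and a
#' dimensionless initial-to-threshold concentration ratio for the dilution
#' rule (whose decay rate \code{k}, 1/h, is a fixed cohort constant).
#'
#' Per-root parameter means are drawn from Gaussians \code{N(p, Delta_p)}
#' and per-cell values from \code{N(p_j, sigma_p)}; draws that are zero or
#' negative are discarded and redrawn. The differentiation threshold is
#' root-specific but shared by all cells of the same root, so it carries no
#' within-root spread.
#'
#' @param model One of \code{"ruler"}, \code{"timer"}, \code{"sizer"},
#'   \code{"dilution"}.
#' @param R_prod,l0,r_elong,threshold Cohort means (units above).
#' @param k Decay rate (1/h) of the dilution-rule signal; ignored by the
#'   other rules. \code{k = 0} reduces the dilution rule to a Sizer.
#' @param delta Named numeric vector of between-root standard deviations for
#'   any of \code{R_prod}, \code{l0}, \code{r_elong}, \code{threshold}.
#'   Unnamed entries of the full length 4 are taken in that order. Missing
#'   entries default to 0.
#' @param sigma Named numeric vector of within-root standard deviations for
#'   \code{R_prod}, \code{l0}, \code{r_elong}. Defaults to \code{delta/2},
#'   reflecting that variability between cells of one root is smaller than
#'   between roots.
#' @param n_roots Number of root files in the cohort.
#' @param t_end Final simulation time in hours (default 240 h = 10 days).
#'
#' @return An object of class \code{"population_params"}.
#' @seealso [sample_population()], [simulate_root_file()], [simulate_cohort()]
#' @export
population_params <- function(model = c("sizer", "timer", "ruler", "dilution"),
                              R_prod, l0, r_elong, threshold, k = 0,
                              delta = NULL, sigma = NULL,
                              n_roots = 122L, t_end = 240) {
  model <- match.arg(model)
  means <- c(R_prod = R_prod, l0 = l0, r_elong = r_elong,
             threshold = threshold)
  if (any(!is.finite(means)) || any(means <= 0))
    stop("all parameter means must be positive and finite")
  if (model == "dilution") {
    if (threshold <= 1)
      stop("dilution threshold is the ratio c_0/c_thr and must exceed 1")
    if (k < 0) stop("decay rate k must be >= 0")
  }
  delta <- fill_named(delta, names(means))
  sig_names <- c("R_prod", "l0", "r_elong")
  if (is.null(sigma)) sigma <- delta[sig_names] / 2
  sigma <- fill_named(sigma, sig_names)
  if (any(delta < 0) || any(sigma < 0))
    stop("delta and sigma must be non-negative")
  if (any(sigma > delta[sig_names] + 1e-12))
    stop("within-root spread sigma must not exceed between-root spread delta")
  if (n_roots < 1) stop("n_roots must be >= 1")
  if (t_end <= 0) stop("t_end must be positive")
  structure(list(model = model, means = means, k = k,
                 delta = delta, sigma = sigma,
                 n_roots = as.integer(n_roots), t_end = t_end),
            class = "population_params")
}

fill_named <- function(x, nms) {
  out <- stats::setNames(rep(0, length(nms)), nms)
  if (is.null(x)) return(out)
  if (is.null(names(x))) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, length(nms)), nms)
    else if (length(x) == length(nms)) names(x) <- nms
    else stop("unnamed spread vector must have length 1 or ", length(nms))
  }
  bad <- setdiff(names(x), nms)
  if (length(bad)) stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
  out[names(x)] <- x
  out
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population parameters (", x$model, " rule)\n", sep = "")
  tab <- rbind(mean = x$means, delta = x$delta,
               sigma = c(x$sigma, threshold = 0))
  print(round(tab, 4))
  if (x$model == "dilution") cat("decay k:", x$k, "/h\n")
  cat("n_roots:", x$n_roots, "  t_end:", x$t_end, "h\n")
  invisible(x)
}

#' Positive-truncated Gaussian draws
#'
#' Draws from N(mean, sd) rejecting values <= 0, as the simulator requires
#' for all rate and length parameters. A rejection cap guards against
#' configurations whose acceptance probability is negligible.
#'
#' @param n Number of draws.
#' @param mean,sd Gaussian parameters; \code{sd = 0} returns the mean.
#' @param cap Maximum total number of raw draws before giving up.
#' @return Numeric vector of length \code{n}, all entries > 0.
#' @keywords internal
rnorm_pos <- function(n, mean, sd, cap = 1e6) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    if (mean <= 0) stop("degenerate draw at non-positive mean")
    return(rep(mean, n))
  }
  out <- numeric(n)
  need <- seq_len(n)
  drawn <- 0
  while (length(need)) {
    m <- length(need)
    drawn <- drawn + m
    if (drawn > cap)
      stop("positivity rejection cap exceeded: infeasible configuration ",
           "(mean ", mean, ", sd ", sd, ")")
    x <- stats::rnorm(m, mean, sd)
    ok <- x > 0
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Draw per-root parameter means for a simulated cohort
#'
#' Each root j receives a mean for every parameter from the between-root
#' Gaussian \code{N(p, Delta_p)}, with non-positive values rejected and
#' redrawn. Deterministic under a fixed seed.
#'
#' @param params A [population_params()] object.
#' @param seed Integer seed, or \code{NULL} to use the current RNG state.
#' @return A data frame with one row per root: \code{root_id},
#'   \code{R_prod}, \code{l0}, \code{r_elong}, \code{threshold}.
#' @export
sample_population <- function(params, seed = NULL) {
  stopifnot(inherits(params, "population_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_roots
  out <- data.frame(root_id = sprintf("root_%03d", seq_len(n)))
  for (p in names(params$means))
    out[[p]] <- rnorm_pos(n, params$means[[p]], params$delta[[p]])
  out
}
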