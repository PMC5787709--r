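#' Break the meristem-elongation coupling by random recoupling
#'
#' Randomly recouples the per-root \code{N_EZ} values with the
#' \code{(r_EZ, l_0EZ, R_prod)} tuples, which stay together, destroying the
#' correlation between \code{N_EZ} and \code{1/ln(r_EZ)} while leaving
#' every marginal distribution untouched. The identity permutation is
#' excluded (redrawn) so the decorrelation intent is guaranteed.
#'
#' @param traits Trait table with complete \code{r_EZ}, \code{N_EZ},
#'   \code{l_0EZ} rows (\code{R_prod} optional but carried).
#' @param seed Optional seed.
#' @return The table with \code{N_EZ} permuted; the permutation is
#'   attached as attribute \code{"permutation"}.
#' @export
decouple_pairs <- function(traits, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  need <- c("r_EZ", "N_EZ", "l_0EZ")
  if (!all(need %in% names(traits)))
    stop("traits must contain ", paste(need, collapse = ", "))
  ok <- stats::complete.cases(traits[need])
  tr <- traits[ok, , drop = FALSE]
  n <- nrow(tr)
  if (n < 5L) stop("need at least 5 complete rows to decouple")
  repeat {
    perm <- sample.int(n)
    if (any(perm != seq_len(n))) break
  }
  tr$N_EZ <- tr$N_EZ[perm]
  attr(tr, "permutation") <- perm
  tr
}

#' Mature cell length and root growth implied by the trait identities
#'
#' Applies the stationary identities \code{l_diff = l_0EZ * r_EZ^N_EZ} and
#' \code{R_growth = R_prod * l_diff} to every root of a trait table,
#' optionally normalizing each to its group mean (relative values).
#'
#' @param traits Trait table with \code{r_EZ}, \code{N_EZ}, \code{l_0EZ}
#'   and optionally \code{R_prod} (without it only \code{l_diff} is
#'   computed).
#' @param relative Also return values divided by their mean.
#' @return The table with \code{l_diff} (and \code{R_growth}; plus
#'   \code{rel_l_diff} / \code{rel_R_growth} when \code{relative}) added.
#' @export
derived_growth <- function(traits, relative = FALSE) {
  need <- c("r_EZ", "N_EZ", "l_0EZ")
  if (!all(need %in% names(traits)))
    stop("traits must contain ", paste(need, collapse = ", "))
  traits$l_diff <- traits$l_0EZ * traits$r_EZ^traits$N_EZ
  if (!is.null(traits$R_prod))
    traits$R_growth <- traits$R_prod * traits$l_diff
  if (relative) {
    traits$rel_l_diff <- traits$l_diff / mean(traits$l_diff, na.rm = TRUE)
    if (!is.null(traits$R_prod))
      traits$rel_R_growth <- traits$R_growth / mean(traits$R_growth,
                                                    na.rm = TRUE)
  }
  traits
}

#' Permutation test for the variance-buffering role of the coupling
#'
#' Quantifies how much the observed coupling of \code{N_EZ} with
#' \code{1/ln(r_EZ)} suppresses the between-root spread of the mature cell
#' length and of root growth: the sd of \code{l_diff} (and
#' \code{R_growth}) under the observed pairing is compared with its
#' distribution over random recouplings. The reported one-sided P-value is
#' the fraction of permutations whose sd is at most the observed one
#' (add-one estimator), i.e. how unusually small the coupled spread is
#' under the decoupled null.
#'
#' @param traits Trait table (see [decouple_pairs()]); \code{R_prod} is
#'   required for the \code{R_growth} arm.
#' @param n_perm Number of random recouplings.
#' @param seed Seed for the permutation stream.
#' @return A list of class \code{"decorrelation_test"} with, per variable:
#'   observed sd, median permuted sd, inflation factor (median permuted /
#'   observed) and P-value.
#' @export
decorrelation_test <- function(traits, n_perm = 1000L, seed = 1L) {
  set.seed(seed)
  base <- derived_growth(traits)
  has_growth <- !is.null(traits$R_prod)
  sd_obs <- c(l_diff = stats::sd(base$l_diff, na.rm = TRUE),
              R_growth = if (has_growth)
                stats::sd(base$R_growth, na.rm = TRUE) else NA_real_)
  perm_sd <- matrix(NA_real_, n_perm, 2,
                    dimnames = list(NULL, c("l_diff", "R_growth")))
  for (b in seq_len(n_perm)) {
    d <- derived_growth(decouple_pairs(traits))
    perm_sd[b, 1] <- stats::sd(d$l_diff, na.rm = TRUE)
    if (has_growth) perm_sd[b, 2] <- stats::sd(d$R_growth, na.rm = TRUE)
  }
  vars <- if (has_growth) c("l_diff", "R_growth") else "l_diff"
  res <- lapply(vars, function(v) {
    ps <- perm_sd[, v]
    list(sd_observed = sd_obs[[v]], sd_permuted_median = stats::median(ps),
         inflation = stats::median(ps) / sd_obs[[v]],
         p_value = (1 + sum(ps <= sd_obs[[v]])) / (n_perm + 1))
  })
  names(res) <- vars
  structure(c(res, list(n_perm = n_perm, n = nrow(base))),
            class = "decorrelation_test")
}

#' @export
print.decorrelation_test <- function(x, ...) {
  cat("Decorrelation permutation test (", x$n_perm, " recouplings, n = ",
      x$n, " roots)\n", sep = "")
  for (v in intersect(c("l_diff", "R_growth"), names(x)))
    cat(sprintf("  %-8s sd %.2f -> %.2f decoupled (x%.2f), P = %.4g\n",
                v, x[[v]]$sd_observed, x[[v]]$sd_permuted_median,
                x[[v]]$inflation, x[[v]]$p_value))
  invisible(x)
}

#' Twofold meristematic-activity scenarios
#'
#' Rescales \code{1/ln(r_EZ)} by each factor — equivalent to changing the
#' meristematic activity \code{R_prod} by that factor at fixed elongation
#' rate — and evaluates the consequences for the mature cell length and
#' root growth. With the coupling preserved, \code{N_EZ} is co-scaled by
#' the same factor so that \code{N_EZ * ln(r_EZ)} is invariant, which
#' leaves \code{l_diff} exactly unchanged while \code{R_growth} scales
#' with the factor; without it, \code{N_EZ} is held at its original
#' values. Non-integer rescaled cell numbers are permitted in this
#' theoretical construction. Groups are compared by one-way ANOVA when
#' every group passes Shapiro-Wilk normality, and by the Kruskal-Wallis
#' rank ANOVA otherwise.
#'
#' @param traits Trait table with \code{r_EZ}, \code{N_EZ}, \code{l_0EZ},
#'   \code{R_prod}.
#' @param factors Scale factors applied to \code{1/ln(r_EZ)}.
#' @param preserve_correlation Co-scale \code{N_EZ} with the factor?
#' @param alpha_normal Normality-gate level for the ANOVA/Kruskal choice.
#' @return A list of class \code{"meristem_scenarios"}: \code{data} (long
#'   table: scenario, root_id, l_diff, R_growth, relative values) and
#'   \code{tests} (per variable: test used, statistic, P).
#' @export
meristem_scenarios <- function(traits, factors = c(0.5, 1, 2),
                               preserve_correlation = TRUE,
                               alpha_normal = 0.05) {
  if (any(factors <= 0)) stop("factors must be positive")
  need <- c("r_EZ", "N_EZ", "l_0EZ", "R_prod")
  if (!all(need %in% names(traits)))
    stop("traits must contain ", paste(need, collapse = ", "))
  tr <- traits[stats::complete.cases(traits[need]), , drop = FALSE]
  rows <- lapply(factors, function(f) {
    ln_r <- log(tr$r_EZ) / f           # 1/ln r scaled by f
    N <- if (preserve_correlation) tr$N_EZ * f else tr$N_EZ
    l_diff <- tr$l_0EZ * exp(N * ln_r)
    R_growth <- (f * tr$R_prod) * l_diff
    data.frame(scenario = sprintf("R_prod x%g", f), factor = f,
               root_id = tr$root_id, l_diff = l_diff, R_growth = R_growth,
               rel_l_diff = l_diff / mean(l_diff),
               rel_R_growth = R_growth / mean(R_growth))
  })
  data <- do.call(rbind, rows)
  tests <- do.call(rbind, lapply(c("l_diff", "R_growth"), function(v) {
    vals <- split(data[[v]], data$scenario)
    normal <- all(vapply(vals, function(g)
      stats::sd(g) > 0 && stats::shapiro.test(g)$p.value > alpha_normal,
      TRUE))
    if (normal) {
      a <- summary(stats::aov(data[[v]] ~ data$scenario))[[1]]
      data.frame(variable = v, test = "anova", statistic = a$`F value`[1],
                 p_value = a$`Pr(>F)`[1])
    } else {
      kw <- stats::kruskal.test(data[[v]], factor(data$scenario))
      data.frame(variable = v, test = "kruskal",
                 statistic = unname(kw$statistic), p_value = kw$p.value)
    }
  }))
  structure(list(data = data, tests = tests, factors = factors,
                 preserve_correlation = preserve_correlation),
            class = "meristem_scenarios")
}

#' @export
print.meristem_scenarios <- function(x, ...) {
  cat("Meristematic-activity scenarios (coupling ",
      if (x$preserve_correlation) "preserved" else "broken", ")\n", sep = "")
  agg <- stats::aggregate(cbind(l_diff, R_growth) ~ scenario, x$data, mean)
  print(agg, row.names = FALSE)
  print(x$tests, row.names = FALSE)
  invisible(x)
}
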