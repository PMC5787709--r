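#' Correlation statistics for the three diagnostic trait pairs
#'
#' Computes, over a per-root trait table, the three relations that carry
#' the mechanistic signature of cell-elongation termination: (1)
#' elongation-zone length against its cell number, (2) mature cell length
#' against \code{1/r_EZ}, and (3) EZ cell number against
#' \code{1/ln(r_EZ)}; plus a fourth, auxiliary relation, the center
#' distance \code{log(L_EZ - l_max/2)} against \code{log(r_EZ - 1)}. The
#' center distance of the mature cell from the meristem end is exactly the
#' quantity a Ruler thresholds, so under that rule it is independent of
#' the profile geometry, while under length- or time-thresholding rules it
#' scales with \code{l_max (r_EZ/(r_EZ-1) - 1/2)} and co-varies with
#' \code{r_EZ}. For each relation, Shapiro-Wilk normality of both
#' margins decides the test: Pearson when both pass at
#' \code{alpha_normal}, Spearman otherwise; the switch is never mixed
#' within a relation. The least-squares slope and its standard error are
#' reported alongside (the slope of relation 3 estimates the log mature /
#' entry length ratio, i.e. the differentiation threshold in units of
#' \code{ln r_EZ}). Only roots with defined \code{r_EZ} and \code{l_max}
#' enter any relation.
#'
#' @param traits Trait table with \code{r_EZ}, \code{l_max}, \code{L_EZ},
#'   \code{N_EZ} (derived inverse columns are recomputed if absent).
#' @param alpha_normal Normality-gate level.
#' @return A data frame of class \code{"trait_correlations"} with one row
#'   per relation: \code{relation}, \code{method}, \code{estimate},
#'   \code{p_value}, \code{n}, \code{slope}, \code{slope_se},
#'   \code{x_mean}, \code{y_mean}.
#' @export
trait_correlations <- function(traits, alpha_normal = 0.05) {
  keep <- !is.na(traits$r_EZ) & !is.na(traits$l_max) & traits$r_EZ > 1
  tr <- traits[keep, , drop = FALSE]
  if (nrow(tr) < 10L) stop("need at least 10 complete records")
  tr$inv_r_EZ <- 1 / tr$r_EZ
  tr$inv_ln_r_EZ <- 1 / log(tr$r_EZ)
  ctr <- pmax(tr$L_EZ - tr$l_max / 2, 0)
  tr$log_center <- ifelse(ctr > 0, log(ctr + (ctr == 0)), NA_real_)
  tr$log_rEZ_m1 <- log(tr$r_EZ - 1)
  spec <- list(LEZ_vs_NEZ = c("N_EZ", "L_EZ"),
               lmax_vs_inv_rEZ = c("inv_r_EZ", "l_max"),
               NEZ_vs_inv_ln_rEZ = c("inv_ln_r_EZ", "N_EZ"),
               center_vs_rEZ = c("log_rEZ_m1", "log_center"))
  rows <- lapply(names(spec), function(rel) {
    x <- tr[[spec[[rel]][1]]]
    y <- tr[[spec[[rel]][2]]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 10L || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(relation = rel, method = "undefined",
                        estimate = NA_real_, p_value = NA_real_, n = n,
                        slope = NA_real_, slope_se = NA_real_,
                        x_mean = mean(x), y_mean = mean(y)))
    normal <- stats::shapiro.test(x)$p.value > alpha_normal &&
      stats::shapiro.test(y)$p.value > alpha_normal
    ct <- if (normal) stats::cor.test(x, y, method = "pearson")
          else suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                                exact = FALSE))
    fit <- suppressWarnings(summary(stats::lm(y ~ x)))$coefficients
    data.frame(relation = rel,
               method = if (normal) "pearson" else "spearman",
               estimate = unname(ct$estimate), p_value = ct$p.value, n = n,
               slope = fit[2, 1], slope_se = fit[2, 2],
               x_mean = mean(x), y_mean = mean(y))
  })
  structure(do.call(rbind, rows), class = c("trait_correlations",
                                            "data.frame"))
}

#' Wilcoxon comparison of the five phenotypic trait distributions
#'
#' Two-sided Wilcoxon rank-sum tests between a candidate cohort (typically
#' simulated) and a reference cohort for each of the five phenotypic
#' traits: \code{r_EZ}, \code{l_max}, \code{L_EZ}, \code{N_EZ},
#' \code{R_growth}. A model parameterization is considered to account for
#' the reference when no trait differs at the \code{alpha} level.
#'
#' @param candidate,reference Trait tables (>= 10 rows each).
#' @param alpha Pass level; the cohort passes when all P-values exceed it.
#' @param traits Trait columns to compare; columns missing from either
#'   table are skipped and flagged.
#' @return Data frame \code{trait}, \code{p_value}, \code{n_candidate},
#'   \code{n_reference}, \code{skipped}; attribute \code{"pass"} is the
#'   all-traits verdict.
#' @export
compare_trait_distributions <- function(candidate, reference, alpha = 0.01,
                                        traits = c("r_EZ", "l_max", "L_EZ",
                                                   "N_EZ", "R_growth")) {
  if (nrow(candidate) < 10L || nrow(reference) < 10L)
    stop("both cohorts need at least 10 roots")
  rows <- lapply(traits, function(tt) {
    if (is.null(candidate[[tt]]) || is.null(reference[[tt]]))
      return(data.frame(trait = tt, p_value = NA_real_, n_candidate = 0L,
                        n_reference = 0L, skipped = TRUE))
    x <- stats::na.omit(candidate[[tt]])
    y <- stats::na.omit(reference[[tt]])
    p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    data.frame(trait = tt, p_value = p, n_candidate = length(x),
               n_reference = length(y), skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(out$p_value[!out$skipped] > alpha)
  attr(out, "alpha") <- alpha
  out
}

#' Rule-based mechanism verdict from the diagnostic relations
#'
#' Operationalizes the correlation-signature argument as an explicit rule
#' table over the relations of [trait_correlations()] (numbered (1)
#' L_EZ ~ N_EZ, (2) l_max ~ 1/r_EZ, (3) N_EZ ~ 1/ln(r_EZ), (4) the
#' auxiliary center-distance relation):
#' \itemize{
#'   \item \strong{sizer}: (2) non-significant (the mature length is
#'     pinned by the threshold) with (3) positive, significant and
#'     proportional, and (1) positive and significant.
#'   \item \strong{timer}: (2) negative and significant (the mature length
#'     couples to \code{r_EZ} through the elongation rate) while (3) is
#'     non-significant or variance-compressed: the fitted slope of (3)
#'     falls below \code{compression} times the proportionality ratio
#'     \code{mean(N_EZ)/mean(1/ln r_EZ)}, i.e. \code{N_EZ} does not track
#'     \code{1/ln(r_EZ)} proportionally because it is set by the residence
#'     time rather than by the length profile.
#'   \item \strong{ruler}: (2) negative and significant, (3) proportional
#'     (not compressed), and the center distance of the mature cell from
#'     the meristem end — the quantity a Ruler thresholds — uncorrelated
#'     with the profile geometry: relation (4) at or above
#'     \code{center_cut}.
#'   \item \strong{mixed_sizer_timer}: as ruler but with the center
#'     distance clearly anti-correlated with the geometry ((4) below
#'     \code{center_cut}) — the signature of a diluted-and-degraded
#'     signal, partway between the Sizer ((4) strongly negative) and the
#'     Timer ((4) positive).
#'   \item otherwise \strong{inconclusive}.
#' }
#' A Timer driven purely by meristematic-activity variation is
#' indistinguishable from a Sizer by these relations alone; when the sizer
#' branch fires, the trace records that caveat.
#'
#' @param relations A \code{"trait_correlations"} table.
#' @param alpha Significance level for the relation tests.
#' @param compression Slope-ratio threshold for the variance-compression
#'   test of relation (3).
#' @param center_cut Boundary on the relation-(4) coefficient between the
#'   ruler regime (near zero) and the mixed regime (clearly negative).
#' @return A list of class \code{"mechanism_verdict"}: \code{verdict},
#'   \code{trace} (character log of every rule evaluated),
#'   \code{relations}, \code{alpha}.
#' @export
classify_mechanism <- function(relations, alpha = 0.01, compression = 0.30,
                               center_cut = -0.15) {
  stopifnot(inherits(relations, "trait_correlations"))
  g <- function(rel) relations[relations$relation == rel, ]
  r1 <- g("LEZ_vs_NEZ"); r2 <- g("lmax_vs_inv_rEZ")
  r3 <- g("NEZ_vs_inv_ln_rEZ"); r4 <- g("center_vs_rEZ")
  sig <- function(r) nrow(r) == 1L && !is.na(r$p_value) &&
    r$method != "undefined" && r$p_value < alpha
  sig1 <- sig(r1); sig2 <- sig(r2); sig3 <- sig(r3)
  pos1 <- isTRUE(r1$estimate > 0); neg2 <- isTRUE(r2$estimate < 0)
  pos3 <- isTRUE(r3$estimate > 0)
  prop3 <- r3$y_mean / r3$x_mean
  compressed3 <- isTRUE(r3$slope < compression * prop3)
  z4 <- if (nrow(r4)) r4$estimate else NA_real_
  trace <- c(
    sprintf("(1) L_EZ~N_EZ: %s r=%.3f P=%.3g -> %ssignificant%s",
            r1$method, r1$estimate, r1$p_value, if (sig1) "" else "non-",
            if (sig1) sprintf(", %s", if (pos1) "positive" else "negative") else ""),
    sprintf("(2) l_max~1/r_EZ: %s r=%.3f P=%.3g -> %ssignificant%s",
            r2$method, r2$estimate, r2$p_value, if (sig2) "" else "non-",
            if (sig2) sprintf(", %s", if (neg2) "negative" else "positive") else ""),
    sprintf("(3) N_EZ~1/ln(r_EZ): %s r=%.3f P=%.3g slope=%.2f (proportional slope %.2f) -> %ssignificant, %scompressed",
            r3$method, r3$estimate, r3$p_value, r3$slope, prop3,
            if (sig3) "" else "non-", if (compressed3) "" else "not "),
    sprintf("(4) center distance ~ geometry: r=%.3f (cut %.2f) -> %s",
            z4, center_cut,
            if (is.na(z4)) "unavailable"
            else if (z4 >= center_cut) "geometry-independent (ruler-like)"
            else "anti-correlated (sizer/mixed side)"))
  verdict <-
    if (sig3 && pos3 && !sig2 && sig1 && pos1 && !compressed3) {
      trace <- c(trace, paste("sizer rule fired; note: a Timer driven only",
                              "by meristematic-activity variation matches",
                              "the same signature"))
      "sizer"
    } else if (sig2 && neg2 && (!sig3 || compressed3)) "timer"
    else if (sig2 && neg2 && !compressed3 && isTRUE(z4 >= center_cut)) "ruler"
    else if (sig2 && neg2 && !compressed3 && sig3 && pos3 &&
             isTRUE(z4 < center_cut)) "mixed_sizer_timer"
    else "inconclusive"
  structure(list(verdict = verdict, trace = trace, relations = relations,
                 alpha = alpha, compression = compression,
                 center_cut = center_cut),
            class = "mechanism_verdict")
}

#' @export
print.mechanism_verdict <- function(x, ...) {
  cat("Mechanism verdict:", x$verdict, "\n")
  for (l in x$trace) cat(" ", l, "\n")
  invisible(x)
}

#' Full mechanism report for a trait table
#'
#' Convenience wrapper assembling the relation statistics, the verdict and
#' (optionally) the five-trait Wilcoxon comparison against a reference
#' cohort into one object, exportable as JSON via [write_report()].
#'
#' @param traits Candidate trait table.
#' @param reference Optional reference trait table.
#' @param alpha Significance level for the verdict (and Wilcoxon pass).
#' @param alpha_normal Normality-gate level for the correlation tests.
#' @return A list of class \code{"mechanism_report"}.
#' @export
mechanism_report <- function(traits, reference = NULL, alpha = 0.01,
                             alpha_normal = 0.05) {
  rels <- trait_correlations(traits, alpha_normal = alpha_normal)
  verdict <- classify_mechanism(rels, alpha = alpha)
  cmp <- if (!is.null(reference))
    compare_trait_distributions(traits, reference, alpha = alpha)
  structure(list(relations = rels, verdict = verdict, comparison = cmp,
                 n = nrow(traits)), class = "mechanism_report")
}

#' @export
print.mechanism_report <- function(x, ...) {
  cat("Mechanism report over", x$n, "roots\n")
  print(x$verdict)
  if (!is.null(x$comparison)) {
    cat("Five-trait Wilcoxon comparison (pass =",
        attr(x$comparison, "pass"), "):\n")
    print(x$comparison, row.names = FALSE)
  }
  invisible(x)
}

#' Calibrate a differentiation rule against a reference cohort
#'
#' Coarse-to-fine search for population parameters whose simulated cohort
#' is statistically indistinguishable from a reference cohort in all five
#' phenotypic traits (two-sided Wilcoxon rank-sum, all P above
#' \code{alpha}). The means are initialized from the stationary identities
#' applied to the reference cohort means (threshold from \code{l_max},
#' \code{N_EZ} or \code{L_EZ} according to the rule; \code{R_prod} from
#' \code{R_growth/l_max}; \code{r_elong} from \code{R_prod ln r_EZ}). The
#' closed forms refer to the noiseless file, whereas observed cohorts
#' carry slow straggler cells that inflate the snapshot \code{N_EZ}, so a
#' single probe cohort is simulated at the initial means and the entry
#' length corrected for the residual mismatch (in \code{N_EZ} for the
#' length- and distance-thresholding rules, in \code{l_max} for the
#' time-based ones); the search then scans a grid of threshold scale
#' factors and relative threshold spreads. The first passing parameter
#' set is returned together with the full search log; an exhausted grid
#' is an informative no-fit result, not an error.
#'
#' @param reference Reference trait table with the five traits.
#' @param model Candidate rule.
#' @param seed Integer seed (one sub-seed per candidate, for
#'   comparability).
#' @param alpha Wilcoxon pass level.
#' @param scale_grid Multiplicative factors applied to the initial
#'   threshold mean.
#' @param delta_thr_grid Relative between-root threshold spreads tried.
#' @param delta_rel Relative between-root spreads of the shared parameters.
#' @param k Dilution decay rate (used only by that rule).
#' @param t_end Simulation horizon (h).
#' @return A list of class \code{"calibration"}: \code{pass},
#'   \code{params} (the passing [population_params()], or \code{NULL}),
#'   \code{comparison}, \code{search_log}.
#' @export
calibrate_model <- function(reference, model, seed = 1L, alpha = 0.01,
                            scale_grid = c(1, 0.95, 1.05, 0.9, 1.1),
                            delta_thr_grid = c(0.05, 0.15, 0.25, 0.35),
                            delta_rel = c(R_prod = 0.17, l0 = 0.20,
                                          r_elong = 0.25),
                            k = 0.2, t_end = 240) {
  if (nrow(reference) < 10L)
    stop("reference cohort too small for calibration (need >= 10 roots)")
  mu <- function(v) mean(reference[[v]], na.rm = TRUE)
  r_EZ <- mu("r_EZ"); N_EZ <- mu("N_EZ"); l_max <- mu("l_max")
  R_prod0 <- mu("R_growth") / l_max
  r_elong0 <- R_prod0 * log(r_EZ)
  l_00 <- l_max / r_EZ^N_EZ
  thr0 <- switch(model,
                 sizer = l_max,
                 timer = N_EZ / R_prod0,
                 dilution = exp((r_elong0 + k) * N_EZ / R_prod0),
                 ruler = {
                   N <- max(2L, round(N_EZ))
                   sum(l_00 * r_EZ^seq_len(N - 1)) + l_00 * r_EZ^N / 2
                 })
  make_pp <- function(l0, thr, dthr) {
    population_params(model, R_prod = R_prod0, l0 = l0,
                      r_elong = r_elong0, threshold = thr, k = k,
                      delta = c(R_prod = delta_rel[["R_prod"]] * R_prod0,
                                l0 = delta_rel[["l0"]] * l0,
                                r_elong = delta_rel[["r_elong"]] * r_elong0,
                                threshold = dthr * thr),
                      n_roots = nrow(reference), t_end = t_end)
  }
  ## probe run: correct the entry length for the straggler-driven mismatch
  ## between closed-form and snapshot traits
  probe <- simulate_cohort(make_pp(l_00, thr0, 0.15),
                           seed = derive_seed(seed, 0L))$traits
  ## medians, not means: the pass criterion is rank-based and several
  ## trait distributions are strongly skewed
  if (model %in% c("sizer", "ruler")) {
    dN <- stats::median(probe$N_EZ, na.rm = TRUE) -
      stats::median(reference$N_EZ, na.rm = TRUE)
    l_00 <- min(0.9 * l_max, l_00 * r_EZ^dN)   # raising l0 lowers N_EZ
  } else {
    l_00 <- l_00 * stats::median(reference$l_max, na.rm = TRUE) /
      stats::median(probe$l_max, na.rm = TRUE)
  }
  log_rows <- list()
  cnt <- 0L
  for (dthr in delta_thr_grid) for (sc in scale_grid) {
    cnt <- cnt + 1L
    pp <- make_pp(l_00, sc * thr0, dthr)
    sim <- simulate_cohort(pp, seed = derive_seed(seed, cnt))
    cmp <- compare_trait_distributions(sim$traits, reference, alpha = alpha)
    log_rows[[cnt]] <- data.frame(candidate = cnt, threshold = sc * thr0,
                                  delta_thr_rel = dthr,
                                  min_p = min(cmp$p_value, na.rm = TRUE),
                                  pass = attr(cmp, "pass"))
    if (attr(cmp, "pass"))
      return(structure(list(pass = TRUE, params = pp, comparison = cmp,
                            search_log = do.call(rbind, log_rows)),
                       class = "calibration"))
  }
  structure(list(pass = FALSE, params = NULL, comparison = NULL,
                 search_log = do.call(rbind, log_rows)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  if (x$pass) {
    cat("Calibration passed (all five traits Wilcoxon P >",
        attr(x$comparison, "alpha"), ") after",
        nrow(x$search_log), "candidate(s)\n")
    print(x$params)
  } else {
    cat("Calibration exhausted its grid without a passing candidate\n")
    cat("best min P:", max(x$search_log$min_p), "\n")
  }
  invisible(x)
}
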