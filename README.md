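# rootzone

Stochastic cell-file models and trait inference for root developmental
zonation.

## The problem

In a growing *Arabidopsis* root, cells leave the meristem, elongate up to
tenfold within hours, and then abruptly differentiate — the first
root-hair bulge marks the end of the elongation zone (EZ). What stops a
cell's elongation? Three classical hypotheses exist, named by analogy
with cell-cycle size control: a **Ruler** (stop at a threshold distance
from the meristem), a **Timer** (stop after a threshold residence time),
and a **Sizer** (stop at a threshold cell length); a fourth, mechanistic
variant — a signal diluted by expansion and degraded at rate *k* —
interpolates between Sizer (*k* = 0) and Timer (large *k*).

Marginal phenotypes cannot separate these rules: each can be parameterized
to match the observed distributions of the elongation factor
r<sub>EZ</sub>, mature cell length l<sub>max</sub>, EZ length
L<sub>EZ</sub>, EZ cell number N<sub>EZ</sub>, and root growth rate
R<sub>growth</sub>. What separates them are the *correlation signatures*
between trait pairs across individual roots. `rootzone` implements, in
one tested pipeline:

* an event-driven stochastic simulator of single cell files under all
  four termination rules, with two-level (between-root Δ, within-root σ)
  Gaussian parameter variability;
* closed-form stationary traits built on the noiseless geometry
  r<sub>EZ</sub> = exp(r<sub>elong</sub>/R<sub>prod</sub>),
  l<sub>diff</sub> = l<sub>0EZ</sub>·r<sub>EZ</sub><sup>N<sub>EZ</sub></sup>,
  R<sub>growth</sub> = R<sub>prod</sub>·l<sub>diff</sub>;
* the automated two-segment exponential fit of per-root cell-length
  profiles (`fit_profile()`, the package's central estimator, with the
  usual `print`/`summary`/`coef`/`predict`/`plot`/`residuals`/`simulate`
  methods);
* algebraic inference of the dynamical traits R<sub>prod</sub>,
  r<sub>elong</sub>, T<sub>EZ</sub> from fitted traits plus root-length
  time series;
* the correlation-signature engine (Pearson/Spearman with a normality
  gate, five-trait Wilcoxon calibration, and a rule-based mechanism
  verdict);
* decorrelation and twofold-meristematic-activity scenario analyses of
  the N<sub>EZ</sub> ↔ 1/ln(r<sub>EZ</sub>) coupling;
* a synthetic-cohort generator with per-root ground-truth manifests, so
  the entire pipeline is testable without any external data.

It is aimed at quantitative root biologists and modelers who want to
simulate termination rules, fit their own cell-length profiles (long
CSV/TSV: `root_id, genotype, day, tissue, cell_index, cell_length_um,
is_first_hair`), or re-run the discrimination logic on new genotypes and
treatments.

## Worked example

Generate a wild-type-like epidermal cohort (122 roots, Sizer rule, 5%
measurement noise), fit every profile, infer the dynamics, and ask which
mechanism the cohort supports:

```r
library(rootzone)

cohort <- generate_cohort("wt_epidermis_sizer", seed = 1)
traits <- fit_cohort(cohort$profiles)

# profiles round-trip through the same CSV schema your own data would use
paths <- write_cohort(cohort, tempdir())
profs <- read_profiles(paths[1])
fit_profile(profs[[1]])
#> Two-segment exponential profile fit (ok)
#>   meristem: cells 1..31  r_MZ = 1.031
#>   elongation zone: cells 32..40  r_EZ = 1.386

series   <- generate_root_length_series(cohort, seed = 1)
inferred <- infer_dynamics(traits,
                           growth = root_growth_rate(series, day_min = 4))
round(colMeans(inferred[c("r_EZ", "N_MZ", "N_EZ", "l_max", "R_growth",
                          "R_prod", "r_elong", "T_EZ")], na.rm = TRUE), 3)
#>     r_EZ     N_MZ     N_EZ    l_max R_growth   R_prod  r_elong     T_EZ
#>    1.308   28.574   10.852  159.909  280.431    1.765    0.452    6.170

mechanism_report(inferred)
#> Mechanism report over 122 roots
#> Mechanism verdict: sizer
#>   (1) L_EZ~N_EZ: spearman r=0.772 P=2.1e-25 -> significant, positive
#>   (2) l_max~1/r_EZ: spearman r=0.019 P=0.835 -> non-significant
#>   (3) N_EZ~1/ln(r_EZ): spearman r=0.762 P=2.37e-24 slope=1.64 (proportional slope 2.52) -> significant, not compressed
#>   (4) center distance ~ geometry: r=-0.564 (cut -0.15) -> anti-correlated (sizer/mixed side)
#>   sizer rule fired; note: a Timer driven only by meristematic-activity variation matches the same signature
```

Reading the numbers: adjacent EZ cells are on average 1.31× longer than
their younger neighbour; roots carry about 11 elongating cells that
mature at about 160 µm; growth near 280 µm/h implies a meristematic
activity of 1.76 cells/h, an elongation rate of 0.45 /h, and a 6.2 h
transit through the EZ. The mature cell length is uncorrelated with the
profile geometry (relation 2) while the cell number tracks
1/ln(r<sub>EZ</sub>) proportionally (relation 3) — the Sizer signature,
correctly recovered from a Sizer-generated cohort.

The `vignettes/rootzone-methods.Rmd` vignette documents the model, every
tunable parameter, the fitting constraints, the verdict rule table and
its cuts, and the generator's scope and limitations.

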