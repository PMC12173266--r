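---
title: "Two-sample MR mediation analysis with medmr: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR mediation analysis with medmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medmr)
```

## The scientific problem

Observational associations between molecular traits (say, a plasma lipid
species) and disease are confounded and can run in either direction.
Two-sample Mendelian randomization (MR) uses genetic variants as
instruments: a variant that shifts the exposure, is independent of
confounders, and affects the outcome only through the exposure identifies
the causal effect of the exposure on the outcome from two independent GWAS
— one for the SNP–exposure associations, one for the SNP–outcome
associations.

`medmr` implements the full two-phase mediation design around this idea:

* **Phase 1** — a bidirectional screen. For each candidate exposure the
  forward analysis (exposure → outcome) estimates the total effect *c*, and
  a reverse analysis (outcome → exposure, effect *d*) guards against
  reverse causation. The screen passes when the forward effect is
  significant and the reverse effect is not.
* **Phase 2** — two-step mediation. For each exposure–mediator pair, two
  further univariable MR runs estimate the exposure → mediator effect *a*
  and the mediator → outcome effect *b*. The mediated effect is the product
  *a·b*, the mediated proportion is *(a·b)/c*, and the direct effect is
  *c′ = c − a·b*.

All outcome-side effects are log odds ratios when the outcome is binary, so
the mediation algebra lives on the log-odds scale throughout.

## The estimators

Given harmonized per-variant pairs (β̂X_j, β̂Y_j) with outcome standard
errors σ_j and weights w_j = 1/σ_j²:

* **Wald ratio** (one instrument): β̂ = β̂Y/β̂X with first-order SE
  σY/|β̂X|.
* **IVW** (primary): the weighted least-squares slope through the origin,
  β̂ = Σ w_j β̂X_j β̂Y_j / Σ w_j β̂X_j². The default for two or more
  instruments is the *multiplicative random-effects* variant, which
  inflates the fixed-effect SE by √max(1, Q/(n−1)); it equals the
  fixed-effect estimate but is robust under balanced heterogeneity. The
  fixed-effect variant is available by flag (`mr_ivw(..., "fe")`).
* **MR-Egger** (secondary): weighted least squares of β̂Y on β̂X with an
  unconstrained intercept, after orienting every pair so β̂X ≥ 0 (the
  InSIDE convention; this flips the intercept's sign, not the slope's). The
  intercept estimates directional pleiotropy; "no horizontal pleiotropy" is
  declared when its p ≥ .05. SEs carry the max(1, σ̂) residual-SD floor.
  P-values are two-sided normal by default, with a t-distribution (df n−2)
  variant behind a flag.
* **Weighted median** (secondary): the per-variant Wald ratios ordered,
  with weights β̂X_j²/σ_j² normalized; the estimate interpolates at
  cumulative weight 0.5, and is consistent while at least half the weight
  comes from valid instruments. Its SE has no closed form; a seeded
  parametric bootstrap (default 1000 resamples of both β̂X and β̂Y from
  their sampling distributions) is used.
* **Cochran Q**: Σ w_j (β̂Y_j − f(β̂X_j))² with df n−1 (IVW) or n−2
  (Egger); p from the upper chi-square tail.
* **Leave-one-out**: the IVW estimate re-fit omitting each variant in
  turn; an omission is flagged when it changes the estimate's sign or
  leaves the full-set 95% CI. The reference interval is the fixed-effect
  one: a dominant outlier inflates the random-effects interval and would
  otherwise mask its own influence.
* **MR-PRESSO**: the observed leave-one-out weighted residual sum of
  squares is compared with its parametric null distribution (each replicate
  redraws β̂X* and β̂Y* from the fitted IVW model) for a global test;
  per-variant simulated tail p-values, Bonferroni-adjusted, flag outliers.
  The default removal threshold is adjusted p < 1, i.e. every flagged
  outlier is removed — a deliberately literal, configurable reading of the
  "P < 1" convention — and a distortion test compares the post-removal
  shift against random removals of the same size.

The mediated effect's interval uses the unstandardized delta method,
SE(a·b) = √(a²·SE_b² + b²·SE_a²), chosen for determinism; a seeded
Monte-Carlo product-distribution interval is available
(`mediated_effect_ci(..., method = "montecarlo")`). The proportion is
reported only when a·b and c agree in sign; otherwise the pathway is
flagged inconsistent and the proportion withheld, since a "proportion"
above 1 or below 0 has no mediation interpretation.

## Instrument selection

Three stages, each a contraction of the variant set, with every fate
recorded in a selection report:

1. **P-value screen**: p < 5×10⁻⁵ for molecular traits; p < 5×10⁻⁸ when a
   disease outcome is used as the exposure of the reverse analysis.
2. **Greedy clumping**: repeatedly take the smallest-p remaining variant as
   an index and drop same-chromosome variants within 10,000 kb whose LD r²
   with it is ≥ 0.001. Ties in p are broken by (chromosome, position,
   identifier) so the result is independent of row order. LD comes from a
   caller-supplied lookup (long-format pair table, dense matrix, or
   function); a `no_ld` mode prunes by distance alone and is labelled an
   approximation. Computing LD from a genotype reference panel is out of
   scope.
3. **F-statistic filter**: per-variant F = [R²/(1−R²)]·[(N−K−1)/K] with
   K = 1 instrument per variant, keeping F > 10. K is interpreted as the
   number of instruments — the only reading under which a per-SNP F filter
   is meaningful. R² defaults to the t-statistic identity
   t²/(t²+N−2), which needs no allele frequency; the standardized-trait
   alternative 2·EAF·(1−EAF)·β² is behind a flag.

## Harmonization rules

Exposure and outcome records are aligned to the exposure's effect allele:
swapped allele pairs have the outcome beta negated and frequency
complemented. Palindromic variants (A/T, C/G) cannot be strand-resolved
from alleles alone: those with exposure effect-allele frequency inside
[0.42, 0.58] (configurable) are excluded as ambiguous; outside the window
the two frequencies must fall on the same side of 0.5, and a disagreement
is interpreted as a strand flip and corrected. Palindromic variants with a
missing frequency are excluded, as are allele sets that match neither
directly nor by swap. A strict mode (`drop_all_palindromic`) excludes every
palindromic variant. Alleles are normalized to upper case; indels are
rejected (the pipeline is SNP-only); every exclusion carries a reason code
and kept + excluded always equals the variant-ID intersection.

## The synthetic-data generator

Because real lipidome/metabolome/disease GWAS cannot be bundled, every
stage is verified against simulated summary statistics with known truth.
Three *disjoint* cohorts (two-sample MR assumes no sample overlap) share
one variant panel and allele coding; phenotypes follow

* X = Σ γ_j G_j + ε,
* M = a·X + Σ α_j G_j + ε,
* logit P(Y=1) = β₀ + b·M + c′·X + Σ (δ_j + η_j) G_j,

with disjoint instrument sets: γ on 30 exposure instruments, α on 30
mediator instruments, and η on 30 outcome-specific disease loci. The
mediator needs its own instruments for the b-path to be identified — if its
only genetic signal came through the exposure's instruments, the
mediator → outcome analysis would be confounded by the direct path c′ and
would estimate b + c′/a rather than b. Likewise the outcome needs its own
loci for the reverse-direction analysis to have genuine instruments; a
disease GWAS's genome-wide hits are large-effect by construction (an
autoimmune outcome's major loci dwarf trait-mediated SNP effects), which is
why η's scale (0.4 per allele on the log-odds scale) exceeds the molecular
traits' γ and α (0.15). δ is horizontal pleiotropy on the exposure
instruments: zero, balanced (zero-mean), or directional (shifted-mean).

Defaults are the study conditions used throughout the tests: cohort sizes
7174 (exposure) and 8299 (mediator) — the scale of the lipidome and
metabolite GWAS the design emulates — and a desk-scale binary cohort of
20,000 at 5% prevalence (a biobank-scale disease cohort is not runnable on
a desktop; 20,000 with ~1000 cases keeps per-SNP log-OR standard errors in
a realistic range). Allele frequencies are uniform on [0.05, 0.5];
γ ~ N(0, 0.15²) over 30 instruments yields ~20% explained exposure variance
and per-variant F around 40–60, comfortably clear of the F > 10 filter.
Genotypes are Hardy–Weinberg binomial draws, optionally with block-wise
correlation via a Gaussian copula (the realized dosage correlation is
attenuated relative to the latent one — enough LD to exercise clumping,
not a coalescent model). Continuous-trait associations are per-variant
ordinary least squares; binary-outcome associations are genuine per-variant
logistic regressions (compiled Newton scoring over the six
genotype-by-case counts, identical to `glm` at convergence), so outcome
betas are real log odds ratios. The intercept β₀ is solved so the mean
case probability matches the requested prevalence. Everything is
reproducible from a single scenario seed, and `write_fixtures()` /
`read_fixtures()` round-trip the tables exactly at full precision.

What the simulation does *not* emulate: realistic human LD maps,
population stratification, sample overlap, assortative mating, and
selection effects in real GWAS. Passing tests therefore demonstrate the
statistical machinery under its stated assumptions, not robustness to every
failure mode of real data.

## Verification studies and their problem sizes

The test suite runs, among unit and property tests:

* **Oracle equivalence** — IVW and Egger against an independent
  grid-plus-parabolic-refinement minimizer and a weighted `lm` fit, 100
  random instances, agreement to 10⁻⁸.
* **Null calibration** — 2000 replicates of the global-null scenario
  (30 instruments, no pleiotropy, binary outcome): the IVW type-I error,
  Cochran-Q rejection rate, and Egger-intercept rejection rate at the .05
  level are each required to lie in [0.03, 0.07].
* **Parameter recovery** — 500 replicates of a = 0.3, b = 0.4, c′ = 0.1
  (true proportion 6/11 ≈ 0.545) with the continuous-outcome mode; the
  median estimated mediated proportion must be within ±0.08 of truth.
  The continuous mode is used because the structural coefficients are
  defined on the (collapsible) linear scale; logistic marginal per-SNP
  effects are non-collapsible, so binary-mode b and c estimates are
  attenuated by a few percent relative to the liability-scale coefficients
  — a real property of logistic GWAS, not an estimator defect. The
  attenuation largely cancels in the mediated proportion, which is why the
  end-to-end binary run still recovers the proportion.
  A caveat this study surfaces honestly: with realistic instrument
  strength (F̄ ≈ 50) the IVW estimates of a, b, c carry a small
  weak-instrument/winner's-curse attenuation of order 1/F̄ (≈ 2% of the
  effect, plus selection effects at the 5×10⁻⁵ threshold). At 500
  replicates the Monte-Carlo SE of the mean is far smaller than this bias,
  so a "mean within 3 Monte-Carlo SEs of truth" check fails by
  construction at these study conditions — the median-proportion check
  passes because the attenuation cancels in the ratio.
* **Outlier machinery** — 200 replicates of 10 near-equal-strength
  instruments with one outcome beta displaced by +10 SE. Ten instruments,
  not thirty: a +10·SE displacement shifts the pooled IVW estimate by
  10/√n standard errors, so the leave-one-out flag rule (omission outside
  the full-set 95% CI) can only exceed 95% detection when n ≲ 12. Ten also
  matches typical per-lipid instrument counts at the 5×10⁻⁵ threshold.
  MR-PRESSO and leave-one-out must each flag the implanted variant in
  ≥ 95% of replicates.
* **Funnel accounting** — a constructed 10-variant fixture in which every
  variant's fate (p-value screen, clump, F-filter, kept) is known by
  construction and must be reproduced exactly.
* **Determinism** — a manifest-driven rerun must reproduce every result
  table byte for byte.

`scripts/acceptance.R` recomputes all of these from scratch against the
installed package and writes them as JSON.

## Numerical and design notes

* Seeds are mandatory for every stochastic component (weighted-median
  bootstrap, MR-PRESSO, Monte-Carlo intervals, the simulator); the
  pipeline's run manifest records the configuration and seed, and result
  TSVs are written at full precision (17 significant digits) so reruns are
  byte-identical.
* Clumping tie-breaks, ordered report columns, and exact serialization are
  what make end-to-end determinism hold; nothing in the pipeline drops a
  variant silently — harmonization, clumping, the F-filter and MR-PRESSO
  all log removals, and stage counts reconcile by construction.
* The reverse arm of the bidirectional screen can be vacuous when the
  outcome GWAS has no genome-wide-significant variants (common at
  desk-scale cohort sizes for a binary trait); the screen then passes on
  the forward evidence alone and the reverse p-value is reported as
  missing.
* No multiple-testing correction is applied across pathways by default,
  mirroring the design the package reproduces; `batch_screen(p_adjust =
  "bonferroni")` or `"fdr"` applies one to the a- and b-path gates.
* Significance gates (.05 everywhere) are configuration values, not
  constants.

## Known limitations

Univariable MR only: the b-path is a univariable mediator → outcome
analysis, so the mediated effect inherits that estimator's assumptions
(no multivariable-MR adjustment for the exposure). Steiger directionality
filtering, SIMEX-corrected Egger, mode-based and contamination-mixture
estimators, GWAS-VCF input, build liftover, and multi-allelic variants are
out of scope. The weighted-median SE is bootstrap-based and therefore
carries Monte-Carlo noise of order 1/√n_boot.
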