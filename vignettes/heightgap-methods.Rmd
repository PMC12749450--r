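---
title: "Height-GaP: model, calibration and life-course analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Height-GaP: model, calibration and life-course analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The quantity being estimated

Adult standing height is determined jointly by common genetic variation and
by the conditions under which a person grew. The package separates the two:
a polygenic height score aggregates the genetic part, a stratum-specific
linear calibration turns the score into *genotype-predicted height*, and the
residual — measured minus predicted height, in centimetres — is the
*height-GaP*. A negative height-GaP (a "deficit") is read as growth realized
below genetic potential, and is analysed both as an outcome of early-life
growth conditions and as a predictor of later-life mortality.

### Polygenic score

For participant $i$ with effect-allele dosages $d_{ij} \in [0,2]$ and
published per-allele weights $w_j$ (cm),

$$\mathrm{PGS}_i = \sum_j w_j \, \tilde d_{ij}, \qquad
  \tilde d_{ij} = \begin{cases} d_{ij} & \text{observed} \\
  2\,\mathrm{EAF}_j & \text{missing,} \end{cases}$$

where $\mathrm{EAF}_j$ is the effect-allele frequency computed in the
participant's own cohort. Substituting the *expected diploid dosage*
$2\,\mathrm{EAF}$ is the standard scoring convention; because the phrase
"assigned the effect allele frequency" also admits the reading
$\tilde d = \mathrm{EAF}$, that variant is available behind
`missing_impute = "eaf"`, but it only rescales imputed variants by a factor
of two and is not the default.

Weight tables are reconciled with the genotype source's ref/alt orientation
before scoring (`harmonize()`): the dosage is used directly when the effect
allele is alt, flipped as $2-d$ when it is ref, matched through the reverse
complement when the strands disagree, and dropped when the variant is
strand-ambiguous (A/T, C/G) or irreconcilable. Dropping palindromic SNVs
loses a little information but is deterministic; frequency-based resolution
was deliberately not implemented. Only single-nucleotide A/C/G/T alleles
are accepted — rejecting indels at parse time keeps the swap/flip algebra
exact.

### Calibration and height-GaP

Within each stratum $s$ (cohort × sex by default, optionally × race/ethnic
label — a configuration choice, mirroring the fact that the score's
variance explained differs by ancestry and sex),

$$H_i = \alpha_s + \beta_s\,\mathrm{PGS}_i + \varepsilon_i,
\qquad \widehat H_i = \alpha_s + \beta_s\,\mathrm{PGS}_i,
\qquad \mathrm{GaP}_i = H_i - \widehat H_i .$$

Because the calibration is ordinary least squares with an intercept,
height-GaP has mean zero and zero correlation with the score within every
stratum by construction; these identities (to 1e-8) are tested, as is the
exact reconstruction $H = \widehat H + \mathrm{GaP}$. Consequently *mean*
height-GaP carries no information — the signal is in its spread and in who
sits where. The SD of height-GaP ($\sigma_{\mathrm{GaP}}$, about 5 cm under
the default generator) is recomputed on the analysis sample of each
downstream model rather than fixed globally.

Percentile summaries use the linear-interpolation convention
(`quantile(type = 7)`), and because a "95th percentile range" admits two
readings, both the 2.5th–97.5th and the 5th–95th ranges are emitted.

## The synthetic cohort

The generator (`sim_config()`, `simulate_cohort()`) produces the study
conditions the analyses assume, with every generating value recorded in a
truth object:

* genotypes: biallelic SNVs in Hardy–Weinberg proportions, effect-allele
  frequencies uniform on 0.05–0.95, truth weights standard normal, 2% of
  dosages missing;
* heights: $H_i = \mu_{\mathrm{sex}} + c\,G_i + \sum_k \theta_k X_{ik} +
  \varepsilon_i$ with $G_i$ the standardized genetic value and $c =
  \sigma_\varepsilon \sqrt{r^2/(1-r^2)}$ chosen analytically so the score
  explains $r^2 = 0.38$ of within-sex variance (the published scores
  explain 35–40%); sex means 166/176 cm; $\sigma_\varepsilon = 5.1$ cm
  gives total SD ≈ 6.5 cm and $\sigma_{\mathrm{GaP}} \approx 5$ cm;
* exposures: birthweight $N(3.4, 0.5^2)$ kg at +2.22 cm/kg, deprivation
  quintiles at −0.2 cm/quintile, maternal smoking to −1.51 cm,
  breastfeeding to −1.03 cm, gestational age to −4.09 cm — the magnitudes
  reported for early-life growth conditions; effects are mean-centred so
  sex means are preserved. Exposures act directly on height and hence on
  height-GaP, since calibration removes only the score-linear part;
* survival: inverse-transform Weibull (default exponential) with linear
  predictor $\gamma \,(-\mathrm{GaP}/\sigma_{\mathrm{GaP}}) +
  \beta_{\mathrm{age}}(\mathrm{age}-\bar{\mathrm{age}})$, default $\gamma =
  \log 1.11$ per 1-SD deficit, administrative censoring at 15 years, cause
  labels (CHD / stroke / other) multinomial among deaths;
* later-life height loss: per-sex onset (55/58 y), a per-sample annualized
  rate drawn by inverse CDF from a percentile grid (default 0–0.4 cm/yr,
  median 0.2), two height measurements 3–7 years apart with 0.3 cm
  stadiometer noise.

What the generator does **not** emulate: linkage disequilibrium,
assortative mating, population structure (ancestry PCs are independent
noise), exposure–exposure correlation, and informative censoring. Passing
tests therefore demonstrate the estimators recover known truth under the
assumed model, not robustness to those real-data features.

## Early-life association models

For each exposure, paired Gaussian models of height-GaP are fitted —
linear, and a natural cubic spline with 4 df and knots at exposure
quantiles (df configurable; df = 1 reduces to the raw exposure, which is
the nesting sanity check) — and compared by AIC. Ordinal exposures use
their quantile coding in the linear arm and the saturated category coding
in the "spline" arm; categorical exposures are saturated in both. Adjusted
models add age at assessment, sex and genotype-predicted height; ancestry
PCs are deliberately excluded here. Missing data are handled by
complete-case analysis with the analysis n reported — multiple imputation
is out of scope, matching the complete-case sensitivity convention.

Contrasts are reported per 1-SD or per-unit *decrement* (sign-flipped so an
adverse association is negative cm), as a per-quantile trend, or as a
category versus a stated reference. Estimated marginal means are computed
by G-computation — predict every participant at the forced exposure level
and average — with a delta-method CI on the averaged linear predictor; for
a linear model this coincides with `emmeans` under proportional weighting,
which is used as a cross-check in the tests. Sex heterogeneity is tested by
a joint Wald test on exposure-by-sex product terms: with height-GaP as the
outcome, the only coherent product term is exposure × sex. The joint
variance explained by all exposures is the $R^2$ of the joint OLS fit with
a nonparametric bootstrap percentile CI (1000 resamples; the percentile
method was chosen because the sampling distribution of a small $R^2$ is
skewed).

One operating characteristic deserves a note: when the truth is exactly
linear, AIC still picks the 4-df spline whenever the 3-df improvement in
deviance exceeds 6, which happens with probability
$P(\chi^2_3 > 6) \approx 0.11$. "AIC selects linear" is therefore expected
in about 89% of replicates, not 100%.

## Mortality models

The per-1-SD-deficit exposure is $z_i = -\mathrm{GaP}_i /
\sigma_{\mathrm{GaP}}$, so HR > 1 means a deficit is harmful. Cox models
use the Efron tie approximation (the accurate default; the tie method was
not otherwise specified). Model 1 adjusts for age, sex and ancestry PCs;
Model 2 adds genotype-predicted height, giving the model the same linear
span as measured height; a sensitivity set appends adult health factors as
supplied columns. Cause-specific hazards treat other-cause deaths as
censored at the death time — competing-risks subdistribution models are out
of scope. Quartiles are cut within sex at the 25/50/75th percentiles
(ties to the lower quartile, deterministically), Q1 holding the largest
deficits; the headline contrast is Q1 versus Q4 under indicator coding
(an ordinal-trend coding is the untested alternative). Kaplan–Meier
curves per quartile come from the product-limit estimator with
Greenwood-based intervals.

Two numerical facts are worth recording. First, per-SD-deficit and
per-SD-excess fits are exact reciprocals, and reference swaps invert
quartile HRs exactly — both are used as identities in the tests. Second,
the Cox partial likelihood is non-collapsible: adding genotype-predicted
height, even when exactly orthogonal to the deficit exposure and truly
null, perturbs the deficit coefficient by risk-set noise of order
$1/\sqrt{\text{events}}$ (measured ≈ 0.02 in log-HR at 650 events). Exact
Model-1/Model-2 coefficient invariance holds only in linear models, so the
tests assert the shift is unbiased and an order of magnitude below the
effect rather than zero.

## Height-loss sensitivity analysis

Annualized change is the height difference between a participant's first
and last measurement divided by the elapsed years, attributed to the
midpoint age; non-positive intervals are rejected with a log entry. Onset
is estimated per sex as the youngest 1-year age bin whose mean change is
below zero by at least 2 bin standard errors with all older running means
negative — the plain sign rule (recoverable with `z_threshold = 0`) fires
on noise at the youngest bin, since under the null a prefix of bin means
stays negative with appreciable probability. Midpoint attribution smears
the ramp half a measurement interval early, so the estimator is biased
young by up to $\Delta/2$; with 1.5–2-year intervals it recovers a true
onset of 55 to within a year.

Loss percentile curves $q_p(\mathrm{age})$ are linear quantile regressions
of loss ($-\delta$, so loss is positive) on age, one per percentile 1–99
per sex. Quantile regression is implemented in-package (pinball-loss IRLS
with a Nelder–Mead polish; it matches an interior-point reference to ~1e-5
on frozen fixtures). Crossing curves are repaired by monotone
rearrangement across $p$ at each age, and rates are clamped at zero so a
correction never decreases measured height.

Corrections integrate the chosen percentile curve from onset to the
participant's age by a 1-year rectangle rule (the accumulation scheme is a
package choice; any scheme agrees for age-flat curves): the *median*
scenario uses $q_{50}$ for everyone; the *worst-case* scenario assigns each
participant the loss percentile equal to their within-sex height-GaP
deficit percentile — the assumption that whoever lost the most height is
whoever shows the largest deficit. Percentile ranks are matched within sex,
consistent with the sex-specific quartiles elsewhere (matching overall is
the unimplemented alternative). Corrected tables are flagged and a second
correction is rejected. `refit_after_correction()` reports the hazard
ratio before and after correction and their log-HR attenuation ratio.

The worst-case procedure is deliberately an upper bound, and the validation
exposes how sharp its assumptions are. In a designed-confounding scenario —
mortality driven entirely by accumulated loss, baseline heights already
eroded, residual GaP noise small so deficit ranks identify loss ranks — the
correction neutralizes the spurious association (corrected HR ≈ 1).
But in that same scenario a *one-year* error in the onset used for
integration inflates every assigned correction by ~10% in a rank-correlated
way and *reverses* the association rather than nulling it. The
designed-confounding test therefore integrates from the scenario onset
(onset recovery is validated separately), and users applying the worst-case
correction should treat the onset age as a sensitivity parameter, not a
point estimate.

## Problem sizes and reproducibility

Every stochastic routine consumes the ordinary R RNG; `simulate_cohort()`
seeds it from `config$seed` and records the seed in the truth object and
the pipeline manifest, so identical configurations reproduce byte-identical
outputs. The validation suite uses cohorts of 2,000–50,000 (single fits),
500 replicates of n = 2,000 for test size, 100 seeds of n = 5,000 for AIC
operating characteristics, 50 seeds of n = 2,500 for the
designed-confounding study, and n = 100,000 for the extreme-quartile
oracle, chosen so each check's Monte-Carlo error is several times smaller
than the tolerance it asserts. The analysis scripts under `analysis/` run
an 8,000-participant cohort end to end; `scripts/acceptance.R` recomputes
the calibration identity on a fresh 2,000-participant cohort from a
command-line seed.

## Known limitations

Single-cohort synthetic validation; no LD or ancestry structure, so
harmonization and PC adjustment are exercised mechanically rather than
stressed; X-chromosome dosages, multi-allelic sites and genotype imputation
are out of scope; quantile curves are linear in age (adequate for the
generator's age-flat rates; real height loss accelerates); and the
worst-case correction's percentile-matching assumption is extreme by
design — results under it bound, rather than estimate, confounding by
height loss.
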