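---
title: "Methods: reciprocity, factorial trait models, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reciprocity, factorial trait models, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distylr)
```

## The problem

Distylous populations carry two floral morphs whose reproductive organs
are reciprocally placed: the long-styled (L) morph presents a high stigma
and low anthers, the short-styled (S) morph the reverse. Because a
heteromorphic self-incompatibility system makes intermorph pollination
obligatory, the *fit* between one morph's anthers and the other's stigmas
is the quantity of functional interest. Fire is a recurrent disturbance in
savanna systems; this package implements the analysis used to ask whether
a fire event disrupts that fit in a *Palicourea rigida* population split
into a burned and an unburned area, and wraps it around a synthetic data
generator so the whole chain is testable and reusable.

## The inaccuracy statistic

For a pairing of organ summaries at the same level, inaccuracy is

\[ (\bar A - \bar S)^2 + V_A + V_S, \]

the squared difference of the anther and stigma means (*maladaptive
bias*: a systematic departure from optimal reciprocity) plus the sum of
their variances (*imprecision*: scatter around the means). Units are the
squared units of the heights (mm²). Total inaccuracy for one morph pairing
is the sum of the high-organ and low-organ inaccuracies. With two areas
there are exactly four legitimate combinations — within no-fire, within
fire, and the two cross-area pairings — each drawing its high stigma and
low anther from the L member and its high anther and low stigma from the
S member.

Choices made where the analysis left them open:

* **Variance estimator.** The sample variance with the \(n-1\)
  denominator. The source analysis does not state its choice; the unbiased
  estimator is the default a field biometrician would assume.
* **Variance level.** Flower-level variances pooled across individuals
  (not variances of individual means); correspondingly the default
  bootstrap resamples flowers within each area × morph group. A cluster
  bootstrap resampling whole individuals is available via
  `bootstrap_inaccuracy(..., unit = "individual")` for designs where
  between-individual variation dominates.
* **No standardization.** Raw mm² values are reported. A dimensionless
  variant dividing each level's components by the squared mean organ
  height of that level is available behind `standardize = TRUE`; it is an
  extension, not part of the original analysis.
* **Degenerate inputs.** Zero-variance groups are legal and propagate
  exactly (they arise in toy examples and yield degenerate bootstrap
  intervals equal to the point estimate).

Uncertainty is nonparametric-bootstrap percentile intervals (default
B = 1000, 95%), deterministic given a seed. The original analysis reports
point values only; the intervals are this package's addition.

## The factorial trait models

Each trait is modelled as `trait ~ area * morph` with a per-individual
random intercept for all sub-individual sampling units (flowers and
inflorescences); individual-level traits are independent samplings and
carry none. Families follow the trait registry: Gaussian/identity
(inflorescence length, corolla diameter, stigma height, nectar volume and
calories), gamma/log (plant height, stem diameter, corolla length, anther
height, stigma and anther lengths), NB1/log for counts, beta/logit for
nectar concentration. NB1 is the linear-parameterization negative
binomial, \(\mathrm{Var} = \mu(1+\alpha)\), the natural choice when
overdispersion scales with the mean. Deposited pollen counts carry an
intercept-only zero-inflation component.

Fitting is by maximum likelihood through glmmTMB (Laplace approximation
for the random intercepts); type-II Wald chi-square tests come from
`car::Anova`, and marginal means and morph-conditioned contrasts from
emmeans. Decisions worth recording:

* **Dispersion structure.** Where a trait is flagged for a dispersion
  parameter, it is modelled cell-wise (`~ area * morph` on the dispersion
  scale): in a 2 × 2 design, heteroscedasticity is naturally cell-wise,
  and nothing finer is identifiable.
* **Zero inflation** is intercept-only (a constant structural-zero
  probability), with no covariates.
* **Marginal means** average on the link scale over the factor grid and
  then inverse-link, with delta-method SEs — *not*
  observation-weighted averages, so they are unchanged by unbalanced cell
  sizes.
* **Convergence.** A fit failing glmmTMB's convergence checks is retried
  with a larger optimizer budget. If a random-intercept model still fails
  — typical when each individual contributes a single unit, making the
  intercept variance unidentifiable (the nectar layer, with one bagged
  flower per individual, is the canonical case) — the intercept is
  dropped, the reduced model is fitted, and the simplification is flagged
  in the fit object and the pipeline's machine-readable warnings. An
  unconverged fit is always flagged and never silently reported.
* **No multiple-testing correction** is applied across the trait models,
  matching the original univariate analysis.
* **Percent-valued beta responses.** Concentrations in (0, 100) are
  rescaled to proportions for fitting and back-scaled in the marginal
  means.
* **Pollen deposition appears twice** in the source analysis's
  description: as a zero-inflated count model and as proportional
  (binomial) data. Both views are implemented — the count model is in the
  default registry; a presence/absence binomial model is available via
  `model_registry(include_pollen_presence = TRUE)` — and the mapping
  between them is deliberately left to the user.

Percent effect sizes are computed from back-transformed marginal means as
\(100\,(\text{focal}-\text{reference})/\text{reference}\), with the
no-fire group as reference for area effects and the second-named group for
morph effects; this single convention reproduces all nine published
values. Reported to two decimals, matching the published presentation.

## Nectar energetics

Refractometer readings (% w/w sucrose) convert to µg sucrose per µL via
\(10 \cdot C \cdot \rho(C)\) with \(\rho(C)\) the 20 °C density of a C%
w/w aqueous sucrose solution, linearly interpolated from an embedded
standard density table (0–75% in 5% steps); sugar mass converts to energy
at 4 cal/mg. No temperature correction is applied (none is described for
the field protocol). Readings above 75% exceed the table and are rejected
rather than extrapolated.

## What the generator emulates — and what it does not

`population_config()` encodes the study conditions: 17 individuals per
morph × area cell; 80 morphometry flowers, 96 pollen-scored flowers and
10 nectar flowers per cell (drawn from 10 individuals per cell); 22
bud/length inflorescences and 36 fruit-scored inflorescences per cell.
Baseline means are the published back-transformed marginal means
(e.g. stigma heights 16.46/10.42 mm, anther heights 16.51/10.83 mm for
L/S); fire acts multiplicatively on cell means with per-morph overrides,
and the default multipliers are the published effects: inflorescence
length × 0.906, corolla length × 0.953, anther length × 0.941, L-morph
stigma length × 0.665, S-morph fruit count × 1.353, with organ heights
and nectar untouched — the regime in which reciprocity is preserved.

Values the study does not print were fixed once on realism grounds:

* Noise scales were back-derived from printed standard errors where
  possible (inflorescence length SD 4.1 mm from SE 0.62 at ~44
  inflorescences per area; organ-height SD 1.2 mm, giving
  coefficient-of-variation ≈ 7% typical of floral organ morphometry), and
  otherwise set to field-plausible CVs (6.5–25% depending on the organ).
* The fruit-count NB1 dispersion is calibrated to the published
  interaction chi-square: χ² = 9.17 for a × 1.353 morph-specific ratio at
  ~36 inflorescences per cell implies \(1+\alpha \approx 9\), so
  \(\alpha = 8\).
* Individual heterogeneity is a lognormal multiplicative intercept on the
  trait mean, SD 0.05 on the log scale — a ±5% between-plant effect, small
  but enough to give the random-intercept machinery signal.
* Nectar defaults (volume ≈ 14–16 µL at 20% w/w, beta precision 60) are
  chosen so per-flower calories land at the published 12–14 cal range.

Mechanics: Gaussian traits are drawn zero-truncated (at the default CVs
the truncated mass is < 10⁻¹⁰, so the bias is negligible and ignored in
the closed-form moments of `population_inaccuracy()`); gamma traits are
parameterized by mean and CV; NB1 draws use the exact gamma–Poisson
mixture (shape μ/α, scale α), collapsing to Poisson at α = 0; beta draws
use the mean–precision parameterization on the proportion scale.
Concentration intercepts shift on the logit scale so support is
preserved. Generation order is fixed, so one seed reproduces a table
bit-for-bit.

The generator deliberately does **not** simulate pollinator behaviour or
pollen transfer, spatial fire spread, within-flower correlation between
organ traits (traits are conditionally independent given the individual
intercept), temporal phenology, or unbalanced natural cell sizes. Passing
tests therefore show that the *statistical machinery* behaves correctly
under the study's sampling structure and stated distributions — not that
real *P. rigida* data satisfy those distributions.

## Simulation sizes used by the test-suite experiments

These sizes are the package's own design choices for its verification
experiments, stated here for transparency: estimator-consistency runs use
10⁴ flowers per group with individual heterogeneity off (so the
closed-form population inaccuracy is exact); NB1 dispersion and fixed
effects are checked at 500 observations per cell over 20 seeds per family,
and zero inflation at n = 2000; null calibration of the type-II Wald tests
uses 1000 replicates per family at 50 observations per cell — the
asymptotic regime the chi-square reference presumes (at 15 per cell the
Wald test's well-known finite-sample anti-conservatism dominates); the
targeted contrast-recovery experiment injects the S-morph-only fruit
effect at 100 inflorescences per cell over 100 replicates; and
scenario-level checks run the full pipeline at the study's own sample
sizes over 20 seeds, requiring each element of the published significance
pattern to hold in the majority of runs.

## Known limitations

* Random intercepts use glmmTMB's Laplace approximation; for binary
  responses with few clusters this can bias variance components (not a
  regime the default design enters).
* The bootstrap is percentile-based; BCa intervals are not provided.
* The sucrose density table stops at 75% w/w, above any field-plausible
  nectar reading but short of saturated syrups.
* The pipeline's significance gate for post-hoc contrasts (interaction
  p < 0.05) mirrors the original analysis; users wanting contrasts
  regardless can call `conditional_contrasts()` directly.
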