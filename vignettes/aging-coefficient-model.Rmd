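---
title: "The aging-coefficient model: mapping polygenic scores to age-dependent disease risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The aging-coefficient model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lodsim)
```

## The model

lodsim simulates polygenic late-onset diseases (LODs) — conditions such as
Alzheimer's disease, type 2 diabetes, coronary artery disease and the common
cancers, whose liability is spread over many small-effect variants and whose
incidence is concentrated at older ages.  The model has three ingredients:

1. **A multiplicative genetic architecture.**  Each individual carries, for
   every SNP $k$, a detrimental-allele dosage $g_k \in \{0,1,2\}$ drawn under
   Hardy–Weinberg equilibrium at minor allele frequency $p_k$.  The polygenic
   risk score is the lifelong constant
   $G = \exp\big(\sum_k g_k \ln \mathrm{OR}_k\big)$, normalized so the
   population mean is 1.  Two allele-class grids are built in: a
   common-allele/low-effect scenario (MAF 0.073–0.5, OR 1.05–1.15) and a
   rare-allele/medium-effect scenario (MAF 0.0146–0.0998, OR 1.28–2.01), each
   a 5×5 grid of 25 classes over which SNPs are spread evenly.

2. **A proportional hazard with an age-dependent multiplier.**  Conditional
   on being alive and disease-free at age $t$, an individual's yearly
   probability of diagnosis is $h\!\big(A(t)\,G\big)$, where $A(t)$ — the
   *aging coefficient* — aggregates aging and environmental effects, and $h$
   converts the hazard product to a probability (see *Numerical choices*).

3. **Competing mortality from a life table.**  All-cause mortality is
   independent of the risk score and enters only through the survivor
   fraction $S(t)$.

The aging coefficient is not assumed; it is *discovered* by inverting a
clinical yearly incidence curve $I(t)$.  At each age the package solves

$$\frac{\sum_u w_u(t)\, h(A\,G_u)}{\sum_u w_u(t)} = I(t)$$

for $A$, then removes the newly diagnosed mass,
$w_u(t{+}1) = w_u(t)\,\big(1 - h(A(t)G_u)\big)$.  Because high-score
individuals are diagnosed earlier, the mean score of the still-unaffected
pool declines with age (frailty depletion) and $A(t)$ must rise above
$I(t)$ to keep reproducing the clinical curve.  The spread between $A$ and
$I$ therefore grows with the architecture's log-score variance: it is
largest for high-heritability diseases and nearly vanishes for
low-heritability, low-incidence ones, where $A(t) \approx I(t)$.  With a
homogeneous population ($G \equiv 1$) the identity $A = I$ is exact, and the
package guarantees it to the last bit.

Applying the discovered $A(t)$ back to the same population reproduces
$I(t)$ to numerical precision — this round trip is the model's internal
validation, and the test suite enforces it at $10^{-10}$ relative error per
age.

## Projections

From a coefficient, a population (or a fixed hazard ratio) and a life table,
the package reports, per age: the conditional incidence, the incidence
density $D(t)$ — the first-diagnosis mass at age $t$ discounted by the
survivor fraction, $D(t) = m(t)\,S(t)$ — and the cumulative incidence
$C(t) = \sum_{s \le t} D(s)$, whose final value is the **lifetime risk**.
The first-diagnosis mass includes the disease-free fraction, so lifetime
risk is a proper probability of ever being diagnosed and can never exceed 1.
For a fixed hazard ratio the same bookkeeping reads
$\mathrm{LR} = \sum_t p(t)\prod_{s<t}(1-p(s))\,S(t)$ with
$p(t) = h(A(t)\,\mathrm{hr})$.

Two consequences worth knowing:

* **Proportionality at low risk.**  While cumulative risk is small the
  $\prod(1-p)$ factor is close to 1, so lifetime risk is nearly proportional
  to the hazard ratio: a four-fold HR reduction gives close to a four-fold
  risk reduction.  The own-hazard depletion makes the measured ratio fall
  slightly short of exact proportionality — about 2% short at a 3% baseline
  lifetime risk — and the shortfall grows as risk saturates, which the test
  suite asserts on a steep high-plateau fixture.
* **Longevity raises lifetime risk.**  Shifting the mortality curve to
  emulate longer life expectancy adds probability mass at old ages where
  incidence is highest.  Steep late-rising diseases regain a pre-treatment
  baseline within a few years of added life expectancy; low-risk cancers
  stay below baseline beyond 15 added years.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `scenario_name` | `common_low` | allele-class grid (see above) |
| `n_snps` | per disease preset | causal variants; log-score variance grows linearly in it |
| `n_bins` | 10001 | quantile bins of the expectation-mode population |
| `n_individuals` | 100000 | stochastic-mode population size |
| `transform` | `clamp` | hazard-to-probability conversion |
| `makeham_a`, `gompertz_b`, `gompertz_c` | 5e-4, 2.5e-5, 0.095 /yr | synthetic mortality; life expectancy ≈ 80 yr |
| `deltas` | 0, 5, 10, 15 yr | life-expectancy extensions |
| `hrs` | $2^{4}$ … $2^{-4}$ | hazard-ratio grid |
| `or_multiplier` | — | therapy score multiplier in (0, 1] |

The eight disease presets (`lod_presets()`) carry fixed SNP counts
(Alzheimer's 3575 … lung cancer 100) and familial heritabilities; the
mapping from heritability to variant count is shipped as data, not
recomputed.

## The synthetic-data generator

`generate_fixtures()` produces a matched incidence curve, life table and
architecture so that every analysis (and every test) runs without
downloads:

* **Mortality** is Gompertz–Makeham, $q(t) = \min(1, a + b e^{ct})$, with
  defaults chosen so the survivor-curve sum is ≈ 80 years.  Under exponential
  growth $q$ saturates at 1 near age 112, extinguishing the cohort slightly
  earlier than an empirical period table would; ages beyond extinction carry
  no projection weight.
* **Incidence** fixtures are logistic
  $I(t) = a/(1+e^{-k(t-t_{50})})$ in three families anchored to the
  magnitudes of the modelled diseases: *cancer-like* (plateau 0.4%, onset 40,
  lifetime risk ≈ 3%), *t2d-like* (plateau 2.5%, onset 25), and *ad-like*
  (steep rise after 60 toward a 30% plateau at very old age, lifetime risk
  > 0.3).  An exponential-then-linear form with enforced value/slope
  continuity at an explicit switch age is available for the breast-cancer
  pattern.
* **Architectures** pair each family with a heritability-tier SNP count
  (400 / 2125 / 3575).

What the generator does **not** emulate: real diseases' fitted incidence
parameters, sex-specific incidence and mortality, linkage disequilibrium,
dominance or epistasis, gene–environment interaction beyond what $A(t)$
absorbs, and secular mortality trends.  Passing tests demonstrate the
internal consistency and qualitative behaviour of the model — proportional
response, frailty depletion, longevity effects — not calibrated forecasts
for any actual disease.

## Numerical choices

* **Hazard-to-probability transform.**  The default is the direct yearly
  discretization $h(x) = \min(x, 1)$; the alternative
  $h(x) = 1 - e^{-x}$ is available via `transform = "exponential"`.  Both
  round-trip exactly; the clamp keeps $A(t) = I(t)$ in the homogeneous limit
  without approximation, which is why it is the default.
* **Solver.**  The per-age equation is solved in closed form
  ($A = I(t)/\bar G_w$) while no score saturates the clamp; otherwise by
  bisection run until the bracket collapses to machine precision, so the
  round-trip error is dominated by floating-point arithmetic
  ($\sim 10^{-15}$ relative), not solver tolerance.  The left-hand side is
  non-decreasing in $A$, so the solution is unique below full saturation.
* **Expectation vs stochastic populations.**  The default representation is
  a 10001-bin quantile discretization of the matching normal distribution of
  $\ln G$ (justified by the central limit theorem across thousands of
  independent loci).  It is deterministic and removes Monte Carlo noise from
  the inversion.  Stochastic mode samples explicit individuals — drawing
  class-aggregated binomial dosages, which is exactly equivalent to per-SNP
  Hardy–Weinberg sampling — and is used to validate the expectation path and
  for allele-level therapy editing.
* **Degenerate inputs.**  $I(t) = 1$ with bounded scores has no finite
  solution under the clamp and raises an error; sustained extreme incidence
  that exhausts the unaffected pool truncates $A$ with a warning.  Ages
  with $I(t) = 0$ get $A(t) = 0$.
* **Onset-delay reporting.**  Threshold crossings of the cumulative curve
  are linearly interpolated between integer ages, then differences are
  rounded to whole years.
* **Scale pairing.**  A coefficient may be applied to any population on the
  discovery risk scale: freshly normalized (weighted mean 1) or derived from
  such a population with the normalization reference retained (therapy
  rescaling).  Anything else is rejected.

## Design decisions

* **Mortality is excluded from the discovery recursion.**  The incidence
  rate is conditional on being alive and disease-free, and mortality is
  score-independent, so it cancels from the conditional equation; it enters
  only through $S(t)$ in projections.
* **Mortality-curve shifting** translates $q$ along the age axis, holding
  pre-shift ages at the age-0 value.  This is monotone (survivorship never
  decreases), adds close to the nominal number of years for
  adult-mortality-dominated tables (within half a year in the tests), and is
  the simplest rule with those properties.
* **Therapy** defaults to a uniform score multiplier with the normalization
  reference kept, so post-therapy risks are expressed relative to the
  pre-treatment population mean.  Allele-level editing (largest odds ratio
  first, per individual, until the target reduction is met) is provided as a
  realism check and converges to the scalar multiplier at the population
  level; greedy editing needs fewer edits than the class-average conversion
  `n_edits_for_multiplier()`, which for the common-allele grid equates a
  0.25 multiplier with 15 edits.
* **Regain-baseline scan.**  "How long until lifetime risk returns to its
  pre-treatment level under rising life expectancy" is computed as the
  smallest integer mortality shift at which the treated projection meets the
  untreated baseline, scanned to 40 years.
* **Scenario equivalence is a disease-scale property.**  With SNP counts
  calibrated to equal log-score variance, the common-allele and rare-allele
  grids give treated lifetime risks agreeing within ~1% at the
  2125-SNP tier.  At very small architectures (~400 common SNPs ↔ ~58 rare
  SNPs) the rare grid's binomial skewness is no longer negligible and the
  agreement degrades to ~3%; the equivalence check in the test suite is
  therefore run at the disease-scale tier, where the claim belongs.

## Problem sizes

The package's own studies run at desk scale: 10001-bin expectation
populations for all deterministic results, 1e5–2e5 sampled individuals for
stochastic validation and the scenario-equivalence comparison, ages 0–119.
A full discover–project–scenario pipeline on one fixture completes in
seconds; the stochastic comparisons take tens of seconds.

## Known limitations

* The score is constant for life; no age-varying genetic effects.
* One disease at a time: no comorbidity coupling, no cause-deleted life
  tables, no disease-specific mortality feedback.
* The expectation-mode normal approximation understates the skewness of
  very small rare-allele architectures (see above); use stochastic mode
  there.
* Incidence-curve parameters for real diseases must be supplied by the
  user; the shipped fixtures are synthetic families, not fits.
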