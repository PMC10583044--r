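---
title: "Modelling trans-fat elimination with a proportional multistate life table"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trans-fat elimination with a proportional multistate life table}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmslt)
```

## The model

`pmslt` estimates the health and economic consequences of removing
industrially produced trans fatty acids (iTFA) from a national food
supply.  The causal chain is: a mandatory iTFA limit shifts the
population distribution of trans-fat intake; the intake shift lowers
ischaemic heart disease (IHD) incidence through an exposure–response
relative risk; lower incidence reduces IHD prevalence and IHD mortality;
and those reductions propagate into all-cause mortality, morbidity,
healthcare spending and, against the policy's implementation costs, into
cost-effectiveness.

The population is modelled as closed five-year cohorts by sex, entering
at ages 20, 25, …, 95 and simulated in annual cycles until death or age
100.  No new entrants, migration or secular trends in disease rates are
modelled: the reference scenario holds current intake and rates constant,
which is the comparison the policy question poses.

### Exposure and the potential impact fraction

Trans-fat intake (in percent of total energy, %E) in each sex × age-group
stratum is a lognormal distribution, parameterised by moment matching so
the arithmetic mean and SD equal the inputs, and truncated at an upper
bound $m$ with renormalisation.  The exposure–response is log-linear: if
$RR_2$ is the relative risk per 2%E, then $RR(x) = RR_2^{x/2}$, with
intake below the theoretical minimum risk exposure level (TMREL, 0%E in
the primary analysis) contributing $RR = 1$.

The proportional change in incidence from shifting the intake
distribution $P$ to $P'$ is the continuous distribution-shift potential
impact fraction

$$
\mathrm{PIF} \;=\;
\frac{\int_0^m RR(x)\,P(x)\,dx \;-\; \int_0^m RR(x)\,P'(x)\,dx}
     {\int_0^m RR(x)\,P(x)\,dx},
$$

evaluated by adaptive quadrature (`stats::integrate`, relative tolerance
$10^{-10}$, the reported `integration_error` taken from the quadrature's
own error estimate).  In the primary analysis the intervention eliminates
intake entirely, so the PIF reduces to the population attributable
fraction $(\bar{RR}-1)/\bar{RR}$; a sensitivity scenario keeps a residual
intake of 0.10 ± 0.01 %E and uses the general form.  Intervention
incidence is $I' = I\,(1-\mathrm{PIF})$.

The upper bound $m$ has no canonical value; the default is
$\text{mean} + 10\,\text{SD}$ (config-overridable), far enough into the
tail that the truncated mass is negligible at the intake levels involved
(well under $10^{-6}$), while keeping the integrand compactly supported.

### The disease submodel and case fatality

IHD is chronic in the model: remission is fixed at zero, which is
standard proportional multistate life table practice for coronary
disease.  Within each cohort the submodel tracks healthy and diseased
occupancy among the alive with incidence $i$ and case fatality $f$;
background mortality strikes both states equally and therefore cancels in
the prevalence ratio.  Within-cycle rates are constant and the one-year
transition is solved in closed form (including the incidence-then-death
path within the year), so no inner time-stepping is needed.

Case fatality is not published in burden-of-disease outputs.  It is
derived from the stationary illness–death identity: cause-specific
mortality in the whole population equals case fatality times prevalence,
so $f = \mathrm{CSMR}/\mathrm{prevalence}$.  A forward illness–death
simulator (the same closed-form integrator, with background mortality)
serves two roles: as an independent oracle in tests — schedules simulated
forward from known $f$ return that $f$ within 2% wherever prevalence
exceeds $10^{-4}$ — and as the engine of `consistency_report()`, which
re-simulates each sex from the inputs and flags strata whose reproduced
prevalence or CSMR deviates beyond a tolerance (default 10%).

### The life table

Each annual cycle proceeds as: (1) update the IHD submodel under the
scenario's incidence; (2) substitute IHD mortality proportionally in the
main life table,
$m'(a) = m(a) + f(a)\,\bigl(p'(a) - p_{\mathrm{ref}}(a)\bigr)$, where
$p_{\mathrm{ref}}$ and $p'$ are the cycle-average prevalences in the
reference and intervention runs (the correction is computed as a single
difference term so a zero-effect intervention reproduces the reference
life table bit-exactly); (3) survive the cohort with $e^{-m'}$ and accrue
person-years by the trapezoid (average of start- and end-of-cycle
alive); (4) weight person-years into health-adjusted life years with
morbidity $\mathrm{yld}_{\mathrm{all}}(a) + dw(a)\,(p'-p_{\mathrm{ref}})$,
where the IHD disability weight is the IHD YLD rate over prevalence; and
(5) count incident events as $I' \times$ susceptible person-years.  A
negative $m'$ is clamped at zero and counted (`run$clamped`); it cannot
arise from well-formed inputs because CSMR ≤ all-cause mortality is
validated.  IHD-cause deaths are apportioned from total deaths by the
rate share $f\,p'/m'$.

Averted deaths are reported as IHD-cause deaths averted: in a closed
cohort every member eventually dies, so the all-cause difference
necessarily collapses toward zero over the lifetime horizon while the
cause-specific difference measures the deaths the policy actually
shifts to other causes at later ages.

Horizons (5 years, 10 years, lifetime) accumulate calendar years since
policy start across all cohorts.  HALYs and life years are discounted at
the settings rate (3% default; whether the original analyses discounted
health gains is not stated in the sources this model draws on — here they
are discounted by default and the choice is switchable via
`discount_halys`).  Event and death counts are reported undiscounted.

### Economics

Healthcare cost changes have three parts: averted incident events priced
at the sex-specific acute event cost, averted prevalent case-years at the
annual prevalent-case cost, and — because survivors consume healthcare
for everything else — the change in life years at each age priced at the
per-capita non-IHD expenditure.  The last term partially offsets the IHD
savings, which is why total healthcare savings are smaller in magnitude
than IHD-specific savings.  The sex-specific acute event costs are taken
directly as inputs; `pooled_incident_cost()` is provided as an auditable
helper for the component-weighting construction (myocardial infarction /
angina / cardiac arrest), whose published components do not reproduce the
published totals — the aggregation step between them is not documented,
so the totals are trusted as given.

Government costs follow a five-category schedule over years 1–5; after
year 5 only human resources and administration continue, at their year-5
level.  Industry pays a year-1 reformulation lump (cost per product ×
product count × a currency-conversion/inflation multiplier, default 1.79
to carry £25,000 into 2019 US$) and 1% of the lump annually thereafter.
Discounting multiplies year $t$ by $(1+r)^{-(t-1)}$: year 1, the policy
start, is treated as present value.  Net cost is the healthcare change
plus both implementation streams; the ICER divides it by HALYs gained;
the ROI divides (positive) healthcare savings by government spend; and
classification against the WHO thresholds (US$1720 and US$5161 per HALY,
Kenya's 2019 GDP per capita and three times it) is half-open, with
negative net cost classified cost-saving.  Note that implementation
costs are fixed, so only the healthcare-cost component of the ICER is
invariant to population scale.

### Uncertainty

The PSA redraws, per iteration: each stratum's intake *mean* from its
moment-matched lognormal (the SD stays fixed — redrawing the mean is the
natural reading of drawing "from the intake distribution" when the
quantity that varies between iterations is the location of the stratum's
exposure); each age-group relative risk lognormally around its central
value with log-SD from the 95% CI; and normal multipliers (mean 1,
SD 20% of central) for healthcare cost items and each implementation
cost category, truncated at zero with a count of truncations.  Draws are
independent across parameters and iterations — no correlation structure
is asserted by the inputs — and reproducible from `(seed, iteration)`.
Point estimates and 95% uncertainty intervals are the 50th and
2.5th/97.5th percentiles by the nearest-rank rule on the sorted draws
(rank $\lceil pn \rceil$, ties to the lower index).  Failed iterations
are excluded and counted; more than 1% failing aborts the run.

The univariate suite re-runs the deterministic pipeline under named
scenarios: discount 0%/6%, residual post-intervention intake, ±50%
pre-intervention intake, doubled product count, no industry costs, and
50% greater monitoring (human-resources) costs.

## The synthetic data generator

Real inputs of this kind are burden-of-disease extractions that are not
redistributable, so `generate_bundle()` builds a complete bundle with the
same statistical structure, deterministically from a seed.  The defaults
are the study conditions the model is meant to exercise:

* **Population**: 26 million adults aged 20+, half female, declining
  ~4.5%/year of age — the scale and shape of Kenya's 2019 adult
  population.
* **Mortality**: Gompertz, $m(a) = m_0 e^{k(a-20)}$ with
  $m_0 = 0.0016$ (×1.25 male, ×0.85 female) and $k = 0.080$, giving
  plausible adult survival for a lower-middle-income setting.
* **IHD**: incidence rising exponentially (slope 0.072/year from
  1.2·10⁻⁴ at age 20, male excess 1.6 vs 0.7), true case fatality rising
  at 0.035/year from 0.02.  Prevalence and CSMR are *not* sampled — they
  are produced by forward illness–death simulation from those schedules,
  so the generated epidemiology is self-consistent by construction and
  parameter-recovery tests are meaningful.
* **Intake**: stratum means spanning 0.2–0.35 %E across age (the range
  reported for Kenyan adults), SD = mean/2, lognormal.
* **Relative risk**: 1.23 per 2%E at every age (95% CI 1.11–1.37).
* **Costs**: acute event US$6283 (men) / US$6083 (women), US$336 per
  prevalent case-year, non-IHD expenditure rising from US$40 at age 20 by
  US$1.5 per year of age (around Kenya's ~US$80–90 per-capita health
  spending), a five-category government schedule of ~US$1.2M in year 1
  declining to US$0.45M recurrent, and 99 products at £25,000 each.

`generate_null_bundle()` sets RR = 1 everywhere, making every PIF exactly
zero — the fixture for the no-effect identities (zero health gains, net
cost equal to implementation cost, exactly).

What the generator does **not** emulate: sampling uncertainty and
covariance of burden-of-disease estimates, within-band age structure
(inputs are piecewise-constant across five-year bands, matching the I/O
boundary), secular trends, and any correlation between intake and
disease rates.  Tests passing on synthetic bundles therefore demonstrate
the machinery — conservation, monotonicity, oracle agreement,
reproducibility — not agreement with any particular country's published
estimates, which requires transcribing that country's input tables.

## Numerical choices

* Annual cycles with within-cycle constant rates solved in closed form;
  no cycle-length parameter exists to tune.  A brute-force monthly-step
  Markov chain agrees with the engine on deaths averted within 0.5%
  over 10 cycles in the test suite.
* Five-year band inputs are expanded piecewise-constant to single ages
  (counts split uniformly); ages 95+ inherit the last band.  How the
  original banded inputs were interpolated for case-fatality derivation
  is not documented anywhere; piecewise-constant is this package's
  choice.
* Exposure strata run 20–24 through 90–94 (15 bands × 2 sexes = 30
  strata, the published stratification count), with ages 95+ inheriting
  the 90–94 exposure.
* Division guards: disability weight contributes zero where prevalence
  is zero; the IHD share of deaths is zero where $m' = 0$.
* Percentiles are nearest-rank with lower-index tie-breaks, matching a
  sorted-array reference exactly.
* Consistency diagnostics compare at band resolution.  Even so, a bundle
  that has passed through the banded CSV boundary is only approximately
  consistent in the youngest bands: the simulation is anchored at the
  band-mean prevalence at age 20, while the underlying prevalence there
  is still growing fast from zero.  Flags confined to the first bands at
  very low prevalence indicate this discretisation, not defective
  inputs.

## Problem sizes

The test suite runs the full 32-cohort × 80-cycle population at the
26-million scale (a deterministic run takes well under a second), a
2000-iteration PSA (~1 minute), and million-draw Monte Carlo oracles for
the lognormal moment matching and the PIF quadrature.  The acceptance
script repeats the deterministic run and the 2000-iteration PSA from a
fresh seed.

## Known limitations

* Closed population: no cohorts enter after baseline, so long-horizon
  totals understate what an open population would accrue.
* The intervention is immediate and permanent from year 1; no phase-in,
  no compliance dynamics beyond the residual-intake scenario.
* Trans-fat replacement is against the overall diet; systematic
  substitution with saturated fat would attenuate the effect.
* Indirect and productivity costs are excluded by design; the economic
  perspective is the extended health sector (healthcare plus government
  and industry implementation).
* The stationary quotient for case fatality is the leading-order
  identity of a full illness–death fit; inputs that are internally
  inconsistent will show up in `consistency_report()` rather than being
  reconciled.
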