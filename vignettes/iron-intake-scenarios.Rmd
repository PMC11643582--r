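---
title: "Modelling dietary iron intake, adequacy, and biofortification scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dietary iron intake, adequacy, and biofortification scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironintake)
```

## The problem

Cereals are a major source of dietary iron in Mediterranean diets, and
the iron concentration of wheat and rice grain is projected to fall by
roughly 20% by mid-century under elevated atmospheric CO~2~ and
yield-oriented breeding. `ironintake` models what that depletion — and
three candidate corrective actions — would do to the iron intake and
iron adequacy of a population whose diet is observed through a two-day
dietary survey:

* **basic** — climate-change depletion only: wheat and rice iron density
  multiplied by 0.8, everything else unchanged;
* **s1** — 30% iron biofortification of both grains on top of the
  depletion (multiplier 1.3);
* **s2** — a shift of wholegrain wheat consumption *up to* 50% of total
  wheat;
* **s3** — a shift of brown rice consumption up to 100% of total rice;
* **s4** — all corrective actions combined.

Consumed amounts are held fixed in every scenario: only the iron density
of the grain components changes. Consequently energy intake and food
mass are invariant across scenarios, which the test suite asserts.

## The intake model

The unit of observation is an individual with two non-consecutive diary
days (at least 15 days apart). Each diary entry (food code, grams) is
decomposed through a food composition table into wheat-derived,
rice-derived, and other mass, energy, and iron:

* wheat mass = grams x `wheat_fraction` (the recipe-level wheat content
  of composite foods such as bread or biscuits);
* wheat iron = wheat mass x blend(s), where
  blend(s) = s ρ~whole~ + (1 − s) ρ~refined~ is the share-weighted
  component iron density and s is the food's wholegrain share;
* rice analogously with brown/white component densities;
* "other" takes the remainder, so mass, energy, and iron are each
  conserved exactly (a residual iron more negative than rounding noise
  is clamped to zero with a warning).

Energy is attributed to components mass-proportionally (component mass
times the item's energy density); the alternative — separate component
energy densities — would add table columns without affecting any
iron-side result, since scenarios never touch energy.

Per-day quantities are summed over entries and the two days are
arithmetically averaged. Individual intake is therefore the two-day
mean, the same estimator a two-day national survey reports. Group
statistics are mean, sample SD (n − 1), median, and 5th/95th
percentiles with the common type-7 (linear interpolation) rule; the
percentile convention is asserted against a sort-based oracle in the
tests. Individuals with zero energy on both days are retained with a
missing nutrient density rather than dropped.

Ages are completed years. The survey classes are <1, 1–2, 3–9, 10–17,
18–64, and 65–74 years.

## Adequacy

Adequacy is measured as the *gap*: iron intake minus the applicable
population reference intake (PRI), negative meaning inadequate. The PRI
schedule is sex- and age-specific; the reference list states two values
for adolescent females 11–14 ("10/18") and adult females 30–59
("18/10") without giving the switch age, so both switch ages are
explicit arguments of `pri_schedule()`. The defaults — 12 years
(menarche proxy) and 50 years (menopause proxy) — are package
assumptions, not reference values, and changing them only affects
individuals inside those two ranges. Because a survey age class can mix
PRIs (e.g. 3–9 years spans the 8, 11, and 13 mg/day ranges), gaps are
always computed per individual and then summarised.

## Scenario engine

For each individual we keep, from the diary decomposition, the
wheat mass W, its wholegrain part, and effective component densities
ρ~whole~, ρ~refined~ (the actual iron-to-mass ratio of the consumed
component, falling back to the gram-weighted table density when the
individual consumed no wholegrain at all); likewise for rice. A
scenario maps wheat iron to

W x blend(s\*) x depletion x biofortification,

where s\* is the individual's current wholegrain share, lifted to the
target share if a shift is requested and the individual is below it
("shift up to 50%": individuals already above the target are
unchanged). With unchanged shares and unit factors this reproduces the
baseline wheat iron exactly, which makes the identity scenario a strict
no-op — a property the tests assert to 1e-12. Because blend(s) is
linear, the multiplicative factors commute with the share shift; the
declared composition order (shift, then depletion x biofortification)
is presentational, and the commutation is also asserted.

Deltas are taken per individual against the basic scenario and averaged
within (sex, age class). Significance uses the survey's rule: a group
mean increase is significant iff it exceeds the 95% confidence-interval
half-width z·sd/√n of the group's *current* daily iron intake
(z = 1.96, one-sided p < 0.025; z is an argument so a t quantile can be
substituted). The strictness of the inequality ("larger than") is part
of the contract. Infants (<1 year) are excluded from projections, as in
the underlying study design.

The omnibus comparison of wheat/rice variables across age classes and
sexes uses the Kruskal–Wallis test (chi-square approximation, mid-ranks
with the standard tie correction 1 − Σ(t³−t)/(N³−N)); the H statistic is
checked in the tests against a first-principles mid-rank oracle on
small samples, and its type-I error calibration is verified by
simulation.

## The synthetic survey generator

The survey micro-data behind the published group tables are not public,
so the package ships a generator whose defaults *are* the published
study conditions: per (sex, age class) the sample sizes and the
mean/SD of total intake, energy, iron, and the wheat/rice component
quantities of `italian_survey_targets()`. Design choices, in the order
they matter:

* **Right-skewed totals.** Per-person two-day-mean intakes are
  lognormal, moment-matched to the printed group mean/SD. The published
  medians sit below the means in essentially every group, which rules
  out symmetric models; lognormal is the standard choice for intake
  data.
* **Zero-inflated rice.** Rice consumption is a Bernoulli non-consumer
  gate times a lognormal amount whose conditional moments are solved so
  the *unconditional* mean/SD hit the targets. The published 5th
  percentiles are 0 for rice in every group while most medians are
  positive, bracketing the non-consumer fraction between 5% and 50%;
  the default `rice_zero_prob = 0.25` sits in that bracket.
* **Correlated appetites.** Iron, energy, total mass, wheat, and rice
  share a one-factor Gaussian copula (loadings 0.7/0.8/0.8/0.5/0.3), so
  heavy eaters eat more of everything — realistic, and it keeps the
  non-grain iron residual positive in all but rare tail cases.
* **Group-specific foods.** Each group gets its own food codes whose
  component iron densities are derived from the group's published grain
  iron-to-mass ratio (infant foods come out iron-denser per gram of
  grain, as real baby cereals are). The wholegrain:refined component
  density ratio defaults to 2.0 (0.010 vs 0.020 mg/g in refined-wheat
  terms) and brown:white to 3.0 (0.004 vs 0.012 mg/g) — composition-
  database orders of magnitude, exposed as configuration because no
  reference values exist for the specific products behind the survey.
* **Baseline shares.** Baseline wholegrain share of wheat is 0.04 and
  brown share of rice 0.01: Italian consumption studies consistently
  report very low wholegrain intake, and these values make the
  wholegrain-shift scenario produce increments of a few tenths of a
  mg/day with an adolescent-male peak near 0.8 mg/day — the scale the
  published analysis reports. Per-individual shares are Beta-distributed
  around these means (concentration 10).
* **Two days from one mean.** The two diary days are the person's
  latent mean times f and 2 − f with f = 2·Beta(a, a), a chosen so the
  day-level CV is 0.3. The two-day average equals the latent mean
  *exactly*, so the day split adds realism without disturbing the
  calibration.
* **Composite foods.** Wheat reaches the diary through a refined base
  food, a wholegrain base food, and three composites (bread, biscuits,
  breakfast flakes with wheat fractions 0.65/0.55/0.80), rice through
  plain white/brown rice and a composite dish (rice fraction 0.35), so
  the recipe decomposition is exercised non-trivially. Three filler
  foods (mixed plate, beverage, water with trace densities) absorb the
  non-grain residual of iron, energy, and mass, solved per individual
  as a small linear system with priority iron > energy > mass when a
  corner case would require a negative amount.
* **Unused metadata.** Geographic area (uniform over four strata),
  survey-day dates (≥15 days apart), and holiday flags (P = 0.29) are
  generated as metadata but have no effect on computation, mirroring
  the survey design without claiming behavioural structure.

What the generator does *not* emulate: reporting error and under/over-
reporting (excluded from the underlying analysis too), seasonal and
weekday/holiday consumption differences, area effects, supplement
intake, and any within-food-group substitution structure beyond the
wheat/rice split. Tests passing on synthetic cohorts therefore
demonstrate that the *pipeline* is correct and calibrated to the
published group statistics — not that it would reproduce unpublished
individual-level features of the real survey.

## Numerical choices and degenerate inputs

* Validation of composition tables names the offending row and field;
  duplicate food codes are rejected.
* Component-implied iron exceeding an item's total iron density is a
  validation error at load time; at decomposition time a residual more
  negative than 1e-9 (rounding in hand-built tables) is clamped to zero
  with a warning.
* Fully tied Kruskal–Wallis input (all values equal) carries no rank
  information; H is defined as 0 with p = 1.
* `least_significant_delta` requires n ≥ 2; sd = 0 gives half-width 0,
  and the significance inequality stays strict, so a zero delta is
  never significant.
* Lognormal moment matching with SD 0 degenerates to the constant mean.
* Empty diary days are legal and contribute zero to the two-day mean.

## Problem sizes

The default cohort reproduces the published survey layout: 1,969
individuals in 12 (sex x age class) cells, about 42,000 diary records —
a fraction of a second to generate and analyse. The test suite uses
cohorts of 25–600 for structural checks, 100 replicate cohorts of 346
for calibration coverage, one cohort of 3,000 for the Monte-Carlo check
of the biofortification delta, and 2,000 replicates of k = 3, n = 50
for the Kruskal–Wallis type-I calibration; these sizes give sampling
error comfortably below the tolerances being asserted.

## Known limitations

* Iron *bioavailability* (phytate, vitamin C, heme/non-heme absorption)
  is deliberately out of scope: all quantities are intakes, not
  absorbed iron.
* The adequacy metric is the plain gap against the PRI, not an
  EAR-cut-point prevalence estimate.
* Consumption behaviour is frozen: scenarios change grain iron density
  and wholegrain shares only. A global consumption multiplier is
  exposed on `scenario_spec()` for simple sensitivity projections.
* The published 65–74 half-widths are not exactly z·sd/√n of the
  published SD/n (they give 1.12 and 0.64 against printed 1.17 and
  0.67); the package computes the formula and documents the
  discrepancy rather than reproducing those two printed values.

## A worked run

```{r, eval = FALSE}
cfg <- population_config(seed = 1)
sim <- simulate_survey(cfg)
fit <- iron_intake(sim$diaries, sim$composition, sim$individuals)
summary(fit)
proj <- predict(fit)            # five scenarios, basic as baseline
proj
plot(proj, scenario = "s2")     # adequacy: baseline vs wholegrain shift
```

`run_pipeline(run_config(outdir = "out", seed = 1))` writes the same
results as a CSV bundle (per-individual intakes, the four summary
tables, the figure-ready adequacy series) plus a JSON manifest with the
seed and configuration hash that make the run reproducible.
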