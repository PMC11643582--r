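# ironintake

Dietary iron intake estimation, adequacy assessment, and
biofortification scenario projection from two-day food diaries.

## What it does, and for whom

Nutrition and public-health researchers assessing iron adequacy from
dietary surveys face a forward-looking question: elevated atmospheric
CO₂ and yield-oriented breeding are projected to deplete the iron
concentration of wheat and rice grain by about 20% by mid-century. How
much of that loss could biofortification and wholegrain substitution
recover, population group by population group?

`ironintake` implements that analysis as a reusable pipeline:

1. **Intake estimation** — each diary entry is decomposed through a food
   composition table into wheat-derived, rice-derived, and other mass,
   energy, and iron, using recipe-level wheat/rice fractions of
   composite foods; per-day totals are averaged over the two
   non-consecutive survey days.
2. **Adequacy** — per-individual *gaps* `iron − PRI` against a sex- and
   age-specific Population Reference Intake schedule (negative =
   inadequate), summarised by sex × age class.
3. **Scenario projection** — with consumed amounts held fixed, wheat
   iron becomes `W · blend(s*) · d · b`, where `blend(s) = s·ρ_whole +
   (1−s)·ρ_refined` is the share-weighted component iron density, `s*`
   is the (possibly shifted) wholegrain share, `d` the climate
   depletion multiplier (0.8) and `b` the biofortification multiplier
   (1.3); rice analogously with brown/white densities. Five standard
   scenarios: depletion only (`basic`), +30% biofortification (`s1`),
   wholegrain wheat up to 50% (`s2`), brown rice up to 100% (`s3`), all
   combined (`s4`).
4. **Significance** — a group's mean increase over the baseline is
   significant iff it exceeds the group's 95% confidence-interval
   half-width `z·sd/√n` of current daily iron intake (the "least
   significant delta"); wheat/rice variables are compared across groups
   with the tie-corrected Kruskal–Wallis test.
5. **Synthetic survey generator** — the micro-data of the underlying
   national survey are unpublished, so the package ships a calibrated
   generator whose defaults reproduce the published group statistics
   (sample sizes, lognormal right-skewed intakes, zero-inflated rice
   consumption, wheat embedded in composite foods). Every downstream
   stage is fully testable without any external data.

## Worked example

```r
library(ironintake)

sim <- simulate_survey(population_config(seed = 1))
fit <- iron_intake(sim$diaries, sim$composition, sim$individuals)
fit
#> Two-day dietary iron intake estimate
#>   1969 individuals, 12 sex x age-class groups
#>   overall iron intake: mean 9.5 (SD 4.3), median 9.0 (P5-P95 3.6-17.5) mg/day
#>   groups with mean intake below the PRI: 9 of 12

predict(fit)   # scenario projection, basic (depletion-only) baseline
#> Projected iron intake under 5 scenarios (baseline: basic )
#>
#> Cumulative scenario versus baseline:
#>     sex age_class   n delta least_signif_delta significant
#>  female       1-2 160 0.881              0.382        TRUE
#>  female       3-9 171 1.198              0.356        TRUE
#>  female     10-17 138 1.497              0.555        TRUE
#>  female     18-64 380 1.650              0.340        TRUE
#>  female     65-74  91 1.402              0.641        TRUE
#>    male       1-2 162 0.892              0.380        TRUE
#>    male       3-9 168 1.407              0.409        TRUE
#>    male     10-17 138 1.796              0.611        TRUE
#>    male     18-64 346 2.013              0.483        TRUE
#>    male     65-74  65 2.126              1.036        TRUE
```

Reading the projection: adolescent males gain on average 1.80 mg/day of
iron under the cumulative scenario relative to the depleted baseline —
well above that group's 0.61 mg/day significance threshold, so the
recovery is statistically significant; the same holds in every group
(infants are excluded from projections by design). Nine of the twelve
groups still sit below their reference intake at baseline, so the
corrective actions mitigate, but do not eliminate, inadequacy.

Single quantities work standalone:

```r
adequacy_gap(13.1, "male", 30)      # mean adult-male intake vs PRI 10
#> [1] 3.1
least_significant_delta(4.1, 346)   # 95% CI half-width, mg/day
#> [1] 0.432018
```

`run_pipeline(run_config(outdir = "out", seed = 1))` runs the whole
chain and writes the CSV bundle (per-individual intakes, the
intake+adequacy, wheat/rice, cereal-contribution, and significance
tables, a figure-ready adequacy series) plus a JSON manifest with the
seed and config hash. External survey data in the documented CSV
schemas can replace the generator via `mode = "external-csv"`; a
10-person synthetic example lives in `inst/extdata/synthetic_survey_10/`.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "ironintake", load_package = "installed")'
```

The suite checks hand-computed decomposition and scenario closed forms,
brute-force oracles for the intake engine and the Kruskal–Wallis
statistic, percentile and adequacy conventions, generator calibration
coverage across 100 seeds, and type-I error calibration of the rank
test.

## Method vignette

See `vignettes/iron-intake-scenarios.Rmd` for the model, the generator's
design decisions and what it does and does not emulate, numerical
choices, and known limitations.
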