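---
title: "Methods: pediatric body-composition estimation and method agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pediatric body-composition estimation and method agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(bodycomp4c)
```

## The problem

Clinical body composition partitions weight into fat mass (FM) and fat-free
mass (FFM). In children and adolescents no routine method measures fat
directly; each relies on a conversion model with assumptions that are age-
and sex-dependent, because the hydration and mineralisation of fat-free
tissue change across growth. The four-component (4-C) model, which combines
body volume, total body water, bone mineral content and weight, is the
accepted reference because it frees the fat estimate from assumptions about
FFM composition. This package implements the full estimation chain for five
clinical methods and the 4-C reference, the statistical battery used to
judge agreement between them, and a synthetic-cohort generator that allows
the entire pipeline to be exercised and validated without access to
individual-level study data.

## Estimators

**Skinfolds (SF).** Triceps and medial-calf folds are taken with a 0–80 mm
caliper, up to four replicates per site; site means feed the two-site
Slaughter equations, `%FM = 0.735·s + 1.0` (males) and `%FM = 0.610·s +
5.1` (females), where `s` is the triceps+calf sum in mm. Fat mass is the
fraction times weight. The two lines cross at `s = 32.8` mm; below that
sum the female line predicts more fat. Only the two-site forms for
children with sums under 35 mm are implemented.

**Air-displacement plethysmography (ADP).** Two chamber readings of body
volume are taken; if they differ by more than 150 mL a third is required
and the closest agreeing pair is averaged (an exact tie resolves to the
pair containing the earliest reading). Whole-body density `Db = mass /
volume` converts to percent fat through `%FM = (c1/Db − c2)·100`. Thoracic
gas volume is accepted and stored as an input but takes no part in the
arithmetic here: instrument-side volume corrections are treated as internal
to the device, and the supplied readings are taken as the volumes to use.

**DXA.** The scan reports fat mass, lean soft tissue and bone mineral
content separately; FFM is lean soft tissue plus BMC (grams, divided by
1000 at the point of use — every unit conversion in the package is an
explicit operation). DXA fat and fat-free mass need not sum to weight,
and the package does not force them to.

**Deuterium dilution (D2O).** The consumed dose is reconstructed from four
bottle weighings as the weighed isotope times the fraction of bottle
content drunk. Sessions are screened by three rules before use: a bottle
lighter after drinking than empty, more than 1 g of residual dose water, or
a weighed dose deviating more than 15 % (relative) from the 0.05 g/kg
target. Total body water follows the plateau formula
`TBW(kg) = dose·(conc/20)·18.02/ΔAP·10⁻³/1.04`, implemented exactly in that
arrangement (the g→kg factor applied before the 1.04 proton-exchange
correction; the arrangement is a product of scalars, so the order carries no
numerical consequence and is kept as printed for auditability), and
`TBW(L) = TBW(kg)/0.99371` using the density of water at body temperature.
FFM is TBW divided by an age- and sex-specific hydration coefficient.

**MRI.** Only the final arithmetic is in scope: fat mass equals the fat
voxel count times the voxel volume times the adipose-tissue density
(default 0.92 kg/L, configurable). Image acquisition and segmentation are
not modelled.

**4-C reference.**
`FM = 2.7474·BV − 0.7145·TBW + 1.4599·BMC/1000 − 2.0503·weight`, with BV
and TBW in litres and BMC in grams. A configuration switch accepts TBW in
kg for sensitivity checks; litres are the default and the documented
interface. `FFM = weight − FM` everywhere a method reports only fat, so
fat plus fat-free mass conserves weight exactly for those methods.

## Conversion constants as configuration

The child-specific ADP constants and hydration coefficients in routine use
derive from assumed FFM composition, and published tables differ at the
second decimal. They are therefore configuration, not code: a YAML file
(`inst/extdata/constants.yaml`) carries a Lohman-style hydration table in
two-year age bands by sex together with the bone-mineral fraction of FFM.
Unless the file overrides them, the ADP constants per band are derived from
that composition through the identity

```
a  = 0.7145·hc/0.99371 − 1.4599·bmc_frac
c1 = 2.7474/(1 − a),   c2 = (a + 2.0503)/(1 − a)
```

which makes the two-compartment density equation agree exactly with the 4-C
model for a body whose water and mineral fractions match the band's
assumptions. Evaluated on the shipped hydration table the identity
reproduces Lohman's published child constants to roughly 0.03, which is the
expected consistency since those constants were built from the same kind of
assumption. This choice also gives the synthetic cohort an exact zero-error
round trip (below). Every `(sex, age)` query must resolve to exactly one
band; ambiguity or a gap is an error, never a silent nearest match.

## Agreement statistics

Differences are always method minus reference. The battery per method and
group: Pearson correlation with a Fisher-transform interval (SE
`1/√(n−3)`); Lin's concordance correlation coefficient with population
(1/n) moments per Lin's original definition, interval via the Fisher
transform of the CCC with Lin's large-sample variance; ordinary least
squares of the method on the reference (the orientation is fixed and
documented) with t-quantile intervals; the paired t-test; Bland–Altman bias,
SD of differences (n−1) and limits of agreement `bias ± k·SD` with `k = 2`
by default (`1.96` by argument); and the proportional-bias regression of
differences on pair averages with a two-sided t-test on the slope. No
multiple-testing correction is applied anywhere, deliberately. Degenerate
inputs are handled explicitly: identical series give `t = 0, p = 1`; a
constant non-zero difference is flagged and reported at the machine floor
rather than dividing by zero; perfect correlation returns a missing
interval because the transforms are unbounded there. Comparison cells with
fewer than three complete pairs are emitted with an `insufficient-n` flag
rather than dropped, and pairing uses only participants carrying both
values. The `|CCC| ≤ |r|` inequality and agreement of every statistic with
independent direct-summation oracles are enforced by the test suite.

The companion power computation,
`n = ceil(((z_{1−α/2} + z_{1−β})/atanh(ρ))² + 3)`, gives 7 participants per
age-sex stratum at ρ = 0.90, α = 0.05 and power 0.80.

## The synthetic cohort

The generator emulates an age- and sex-stratified pediatric validation
cohort: four strata (63 and 54 children, 92 and 79 adolescents; 288 in
total) with stratum means and SDs for age, weight, height and true 4-C fat
fraction taken from a published demographic table. Weight, height and fat
fraction are drawn from a Gaussian copula with configurable correlations
(defaults 0.5 between size and fatness, 0.8 between weight and height;
neither is derivable from summary tables) and truncated by rejection to
physiologic bounds — weight > 10 kg, height 80–210 cm, fat fraction 0.08 to
0.55. The lower fat bound keeps every draw inside the domain of all five
estimators: the female Slaughter line cannot represent percent fat below
its 5.1 % intercept. Truth then follows deterministically: TBW from the
band hydration coefficient, BMC as the band's configured fraction of FFM (a
simulation convenience, not a physiological claim), and body volume by
inverting the 4-C formula so the forward model returns the generated fat
mass exactly — the linearity of that map also forces the stratum-mean fat
mass to equal the mean of individual fat masses, a pipeline self-check.

Instrument errors are injected per method as
`observed FM = true + bias + slope·true + Normal(0, sd)`, after which the
*raw readings* are back-solved so the estimators themselves — not merely
the statistics — are exercised in every end-to-end test: skinfold sums
invert the Slaughter equations (replicates carry ~4 % zero-mean
multiplicative scatter so site means are exact), volumes invert the density
equation inside the 150 mL agreement window, bottle weights and saliva
enrichments invert the dose and dilution formulas with dosing jitter that
stays inside the outlier rules, DXA partitions the observed FFM around the
true BMC, and MRI rounds to a whole voxel count (1.35 × 10⁻⁵ L voxels; the
half-voxel rounding is the only non-exact back-solve, ~6 × 10⁻⁶ kg). Draws
whose back-solved readings would violate a raw-measurement invariant are
redrawn with a bounded retry budget, then error. With an all-zero error
specification every method's pipeline output equals truth to numerical
precision.

The default error model mirrors a published total-sample Bland–Altman
structure: slopes and residual SDs are taken from that table's rows, and
each constant bias is set to the reported mean difference minus the slope
times the pooled mean fat mass (9.5 kg), so the injected model reproduces
the reported mean differences at the cohort mean. Method errors are
independent across methods by default; their joint distribution is not
reported anywhere and is configurable.

One structural property deserves emphasis: the raw-measurement schema has a
single set of volume and dilution columns, so the 4-C reference shares its
BV and TBW inputs with the ADP and D2O methods, exactly as in a real study.
Errors injected into those two methods therefore propagate (scaled by
`2.7474/c1` and `0.7145·hc/0.99371` respectively) into the reference.
Strict parameter-recovery checks consequently inject into methods that do
not feed the reference (DXA fat mass, skinfolds, MRI). The
proportional-bias power check runs under the full default error model
rather than a single-method injection: a reference artificially stripped of
measurement error attenuates the difference-on-average regression through
the familiar unequal-error-variance artifact, whereas under the full error
structure the recovered skinfold slope centres on the injected −0.1.

## What passing tests do and do not show

The generator produces normal (truncated) marginals, independent method
errors, complete data for every method, and error moments constant within
method. Real cohorts have skewed fat distributions, correlated device
errors, missingness tied to feasibility (MRI especially), and biases that
drift with adiposity in ways a linear model only approximates. Passing
recovery tests therefore validates the estimators and statistics as
computations, and the pipeline's plumbing — not the clinical
interchangeability of the methods, which is precisely the substantive
question such a study answers with real participants.

## Problem sizes and numerical choices

The test suite exercises 288-participant cohorts (the study's size), a
200-seed Monte-Carlo power check, 1000-series oracle comparisons at 1e-10,
and 1e-9 tolerances on all exact identities. Ties in the volume-selection
rule are broken toward the earliest reading; band lookups are half-open
`[min, max)`; reports round to 4 decimals only at the CLI surface while
machine-readable CSV output keeps full precision.

## A worked example

```{r example, eval = FALSE}
sim <- generate_cohort(default_scenario(), seed = 1)
est <- estimate_composition(sim$cohort)
tab <- comparison_table(est, value = "fm_kg", group_by = "total")
tab[, c("method", "n", "ba_bias", "ba_sd", "prop_slope", "prop_p")]
```

## Known limitations

Regional DXA values are stored but unanalysed; thoracic-gas-volume
prediction, DXA calibration and MRI segmentation are out of scope; growth
z-scores require external reference tables and are not computed; the MRI
subsample-selection mechanism of a real study is not simulated (every
synthetic participant carries MRI); and the shipped hydration/density
constants are defaults whose provenance is documented in the YAML file, to
be replaced by study-specific values whenever those are known.
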