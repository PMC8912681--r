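# bodycomp4c

Pediatric body-composition estimation and method agreement against the
four-component reference model.

## What this is for

Clinicians and researchers estimate fat mass (FM) and fat-free mass (FFM)
in children and adolescents with whichever method their setting allows —
skinfolds, air-displacement plethysmography (ADP / BOD POD), DXA, deuterium
dilution, or MRI. Each method leans on age- and sex-dependent conversion
assumptions, and their results are not interchangeable. `bodycomp4c`
implements the complete estimation chain for all five methods plus the
four-component (4-C) reference model, the method-comparison statistics used
in validation studies, and a seeded synthetic-cohort generator so the whole
pipeline can be tested end to end without individual-level study data.

## The models

Each clinical method converts raw readings to percent fat or fat mass:

- Slaughter skinfolds (triceps + calf sum *s*, mm):
  males `%FM = 0.735·s + 1.0`, females `%FM = 0.610·s + 5.1`
- ADP: `Db = mass/volume`, `%FM = (c1/Db − c2)·100` with child-specific
  `(c1, c2)` per sex and age band
- DXA: `FFM = lean soft tissue + BMC/1000`
- Deuterium dilution:
  `TBW(kg) = dose·(conc/20)·18.02/ΔAP·10⁻³/1.04`, `FFM = TBW/hc` with an
  age-sex hydration coefficient `hc`
- MRI: `FM = fat voxels × voxel volume × 0.92 kg/L`

The reference combines them:

```
FM(4-C) = 2.7474·BV − 0.7145·TBW + 1.4599·BMC/1000 − 2.0503·weight
FFM     = weight − FM
```

Agreement per method vs the reference: Pearson *r* and Lin's concordance
correlation coefficient with 95 % CIs, OLS of method on reference, paired
*t*-tests, Bland–Altman bias with ±2 SD limits of agreement, and the
proportional-bias regression of differences on pair averages. Conversion
constants (hydration coefficients, ADP `(c1, c2)`, adipose density) are
configuration in a documented YAML file, not hard-coded.

## Worked example

```r
library(bodycomp4c)

# reference fat mass at adolescent group-mean-like inputs
fm <- fourc_fat_mass(bv_L = 49.1, tbw_L = 26.77, bmc_g = 1900,
                     weight_kg = 51.2)
c(fm = fm, ffm = ffm_from_weight_fm(51.2, fm))
#>       fm      ffm
#> 13.56862 37.63138

# full pipeline on a synthetic 288-participant cohort
sim <- generate_cohort(default_scenario(), seed = 1)
est <- estimate_composition(sim$cohort)
tab <- comparison_table(est, value = "fm_kg", group_by = "total")
tab[, c("method", "n", "ba_bias", "ba_sd", "prop_slope", "prop_p")]
#>   method   n ba_bias ba_sd prop_slope   prop_p
#> 1     SF 288 -0.0845  3.02    -0.0849 6.10e-03
#> 2    ADP 288 -0.8777  1.66    -0.0274 9.15e-02
#> 3    DXA 288  3.0726  2.68     0.0171 5.14e-01
#> 4    D2O 288  0.8533  1.55     0.0782 2.57e-08
#> 5    MRI 288  2.5216  3.24    -0.0623 6.00e-02
```

Reading the table: `ba_bias` is the mean method-minus-reference difference
in kg (DXA overestimates fat by about 3 kg here, ADP underestimates),
`ba_sd` the SD of those differences, and a significant `prop_slope` means
the error grows or shrinks with fatness — the negative skinfold slope says
skinfolds increasingly underestimate fat in fatter participants. These
recovered values reflect the error structure injected by
`default_scenario()`.

A thin command-line wrapper covers the same stages
(`simulate`, `estimate`, `compare`, `run-all`):

```sh
Rscript inst/cli/bodycomp4c run-all --seed 1 --out results/
```

The design-stage power rule is also exposed:
`sample_size_for_correlation(0.90)` returns `7` participants per age-sex
stratum at α = 0.05 and power 0.80.

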