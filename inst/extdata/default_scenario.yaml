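# Default synthetic-cohort scenario: an age- and sex-stratified pediatric
# validation cohort of 288 participants (63 + 54 children, 92 + 79
# adolescents).  Stratum moments (age, weight, height, true fat fraction)
# follow the demographic table of a pediatric body-composition validation
# study; the true fat fraction uses that table's four-component percent-fat
# row.  Within-stratum correlations are not derivable from summary tables
# and default to 0.5 (size vs fatness) and 0.8 (weight vs height).
#
# errors: per-method observed fat mass is
#   true + constant_bias_kg + proportional_slope * true + N(0, residual_sd_kg).
# Slopes and residual SDs mirror the study's total-sample Bland-Altman rows;
# each constant_bias_kg is chosen so that
#   constant_bias + slope * 9.5 kg  (the pooled mean 4-C fat mass)
# reproduces the reported total-sample mean difference for that method.

strata:
  - sex: female
    age_group: children
    "n": 63
    age_mean: 8.1
    age_sd: 1.8
    weight_mean: 26.1
    weight_sd: 8.1
    height_mean: 123.5
    height_sd: 14.7
    fatfrac_mean: 0.194
    fatfrac_sd: 0.087
  - sex: male
    age_group: children
    "n": 54
    age_mean: 8.4
    age_sd: 1.7
    weight_mean: 28.6
    weight_sd: 8.1
    height_mean: 127.9
    height_sd: 11.1
    fatfrac_mean: 0.191
    fatfrac_sd: 0.090
  - sex: female
    age_group: adolescents
    "n": 92
    age_mean: 14.5
    age_sd: 2.1
    weight_mean: 51.2
    weight_sd: 12.0
    height_mean: 155.1
    height_sd: 7.3
    fatfrac_mean: 0.268
    fatfrac_sd: 0.084
  - sex: male
    age_group: adolescents
    "n": 79
    age_mean: 14.8
    age_sd: 2.0
    weight_mean: 53.9
    weight_sd: 11.6
    height_mean: 163.4
    height_sd: 10.3
    fatfrac_mean: 0.174
    fatfrac_sd: 0.089

errors:
  - {method: SF,  constant_bias_kg: 0.61,  proportional_slope: -0.10,  residual_sd_kg: 2.4}
  - {method: DXA, constant_bias_kg: 3.01,  proportional_slope: -0.006, residual_sd_kg: 2.1}
  - {method: ADP, constant_bias_kg: -0.88, proportional_slope: -0.05,  residual_sd_kg: 2.0}
  - {method: D2O, constant_bias_kg: -0.34, proportional_slope: 0.09,   residual_sd_kg: 2.4}
  - {method: MRI, constant_bias_kg: 3.23,  proportional_slope: -0.10,  residual_sd_kg: 2.7}
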