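# Default conversion constants for pediatric body-composition estimation.
#
# hydration: Lohman-style hydration coefficients of fat-free mass (TBW/FFM)
#   for children and adolescents, by sex and half-open age band
#   [age_min, age_max) in years, together with the bone-mineral fraction of
#   FFM (bmc_frac) assumed by the cohort simulator.  Values follow the
#   age-related decline in FFM hydration from ~0.78 in early childhood
#   toward the adult ~0.73, and the rise in FFM mineralisation across
#   puberty.  They are defaults, not measurements: any study using known
#   coefficients should supply its own file.
#
# ADP density constants: no explicit adp: section is given here, so the
#   package derives (c1, c2) for each band from the hydration and mineral
#   fractions above, which keeps the two-compartment density equation exactly
#   consistent with the four-component model under those assumptions (the
#   derived values agree with Lohman's published child constants to ~0.03).
#   An explicit override looks like:
#   adp:
#     - {sex: male, age_min: 4, age_max: 19, c1: 4.95, c2: 4.50}
#
# adipose_density_kg_per_L: density applied to MRI fat-voxel volumes.

hydration:
  - {sex: female, age_min: 4,  age_max: 7,  hydration: 0.780, bmc_frac: 0.042}
  - {sex: female, age_min: 7,  age_max: 9,  hydration: 0.776, bmc_frac: 0.044}
  - {sex: female, age_min: 9,  age_max: 11, hydration: 0.770, bmc_frac: 0.045}
  - {sex: female, age_min: 11, age_max: 13, hydration: 0.770, bmc_frac: 0.047}
  - {sex: female, age_min: 13, age_max: 15, hydration: 0.769, bmc_frac: 0.049}
  - {sex: female, age_min: 15, age_max: 17, hydration: 0.763, bmc_frac: 0.051}
  - {sex: female, age_min: 17, age_max: 19, hydration: 0.758, bmc_frac: 0.052}
  - {sex: male,   age_min: 4,  age_max: 7,  hydration: 0.776, bmc_frac: 0.042}
  - {sex: male,   age_min: 7,  age_max: 9,  hydration: 0.768, bmc_frac: 0.044}
  - {sex: male,   age_min: 9,  age_max: 11, hydration: 0.765, bmc_frac: 0.045}
  - {sex: male,   age_min: 11, age_max: 13, hydration: 0.760, bmc_frac: 0.047}
  - {sex: male,   age_min: 13, age_max: 15, hydration: 0.759, bmc_frac: 0.049}
  - {sex: male,   age_min: 15, age_max: 17, hydration: 0.752, bmc_frac: 0.051}
  - {sex: male,   age_min: 17, age_max: 19, hydration: 0.744, bmc_frac: 0.052}

adipose_density_kg_per_L: 0.92
d2o_concentration_pct: 99.9
d2o_target_dose_g_per_kg: 0.05
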