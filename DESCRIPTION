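Package: bodycomp4c
Title: Pediatric Body Composition Estimation and Agreement with the
    Four-Component Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw clinical measurements into fat mass, fat-free mass
    and percent body fat for five body-composition methods used in children
    and adolescents: triceps+calf skinfolds via the Slaughter equations,
    air-displacement plethysmography via child-specific density constants,
    dual X-ray absorptiometry, deuterium-oxide dilution of total body water,
    and MRI fat-voxel counting.  Combines body volume, total body water,
    bone mineral content and weight into the Fuller four-component reference
    fat mass, and provides the method-comparison battery used in validation
    studies (Pearson and Lin's concordance correlations with confidence
    intervals, simple linear regression, paired t-tests, Bland-Altman limits
    of agreement and proportional-bias regression).  A seeded synthetic-cohort
    generator emulates an age- and sex-stratified pediatric study population
    with configurable per-method measurement-error structure, back-solving
    raw instrument readings so the estimators themselves are exercised in
    every end-to-end test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
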