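Package: resilherd
Title: Lifetime Resilience Scoring and In-Utero Stressor Analysis for Dairy Herds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify associations between stressors experienced by
    dairy cows during gestation and the lifetime resilience of their offspring.
    Implements a lifetime resilience score (LRS) with an additive component
    breakdown (lactation bonus, age at first calving, calving-interval and
    305-d yield deviations from herd average, early-exit penalty), a
    four-parameter nonlinear (MilkBot) lactation model for daily and 305-d
    yields, temperature-humidity index (THI) exposure assessment over
    gestation windows from daily weather-station summaries, a herd-record
    cleaning cascade with pedigree pairing and fuzzy matching of free-text
    treatment records to a product list, hierarchical (farm/dam/cow) linear
    mixed models with forward stepwise selection and leave-one-farm-out
    cross-validation, and a synthetic multi-farm herd generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    lme4,
    minpack.lm,
    geosphere,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
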