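Package: gaitconf
Title: Balance Confidence Classification from Smartphone Gait Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying people with lower limb
    amputation into high and low balance-confidence groups from smartphone
    inertial signals recorded during a six-minute walk test. Includes signal
    conditioning (fixed-rate resampling, zero-lag Butterworth low-pass
    filtering), heuristic foot-strike cleanup (extra-prediction removal,
    gap-rule missed-step insertion with an adaptive locking period), a
    62-feature-per-step gait feature scheme aggregated to 248 trial-level
    features, correlation-based feature selection with best-first search,
    random-forest classification under participant-level leave-one-out
    cross-validation, and a ground-truthed synthetic six-minute-walk signal
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    data.table,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
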