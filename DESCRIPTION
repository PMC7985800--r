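Package: moodstab
Title: Mood-Stability Monitoring from Passive Smartphone and Wearable Data
Version: 0.1.0
Authors@R: person("Maintainer", "Moodstab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for classifying mood stability
    (Steady versus Mood Swing) of patients with major depressive disorder
    from passively collected smartphone and wristband event streams and
    PHQ-9 self reports.  Builds labeled two-period data samples from runs
    of three consecutive PHQ-9 submissions, extracts behavioral features
    (call logs, screen sessions, app usage, sleep architecture, step
    counts, and nightly heart-rate cosinor rhythms), performs L1- and
    tree-based feature selection inside cross-validation folds, and
    benchmarks six classifiers under stratified 10-fold cross-validation.
    Ships a synthetic cohort generator so every stage is testable without
    access to clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    glmnet,
    FNN,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
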