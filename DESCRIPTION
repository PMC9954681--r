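Package: qeegnorm
Title: Age-Stratified Normative Databases and Z-Scoring for Resting-State
    Quantitative EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and validating age-stratified normative
    databases of resting-state EEG absolute band power. Reads 19-channel
    10-20 recordings (EDF or tabular), performs windowed artifact
    rejection with a minimum-clean-data gate, estimates absolute power in
    the delta/theta/alpha/beta/high-beta bands by Welch's method, builds
    per age-group, per-electrode, per-band mean/SD norms from a screened
    healthy cohort, and scores subjects into z and absolute-z tables.
    Includes the statistical procedures used to characterise such cohorts
    (summary t tests, chi-square with adjusted residuals, one-way ANOVA
    with Bonferroni post hoc, Pearson correlation, Cronbach's alpha,
    LOWESS age trends), reliability and validity machinery (leave-one-out
    and independent cross-database validation, Gaussian coverage audits),
    and a synthetic-cohort generator with known ground truth for
    end-to-end checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
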