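Package: kinentropy
Title: Approximate Entropy Analysis of Joint-Angle Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the regularity of quasi-periodic movement signals
    (e.g., joint angles recorded at 100 Hz during dance or gait) with
    delayed-embedding approximate entropy (ApEn), selecting the embedding
    delay from the autocorrelation function. Includes a cohort pipeline that
    aggregates entropy per participant, limb side and dance type, runs
    left-versus-right contrasts with assumption checking (Shapiro-Wilk,
    Brown-Forsythe Levene, Tukey fences) and Welch or Mann-Whitney tests,
    and a synthetic kinematic-cohort generator for validation and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
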