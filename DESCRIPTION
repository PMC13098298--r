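Package: prelever
Title: Trajectory Metrics and Incentive-Salience Phenotyping for Operant
    Self-Administration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn animal pose-estimation tracks and operant
    self-administration event logs into behavioral markers of addiction
    vulnerability. Reads SLEAP-style per-frame pose tables, interpolates
    missing coordinates, calibrates pixels to centimeters, and aligns
    recordings to lever extension; computes locomotion, nose motion,
    lever-zone entrances per meter, first-15-minute intake, progressive-ratio
    breakpoints, and abstinence codes; classifies subjects into
    sensitization/tolerance phenotypes from noncontingent drug challenges and
    into high/low incentive-salience groups by a median split of pre-lever
    activity z-scores; and runs a statistical workflow combining upper-tail
    winsorization, Box-Cox/Yeo-Johnson power transforms, normality-gated
    correlations, and Benjamini-Yekutieli false-discovery-rate adjustment.
    A synthetic-cohort generator with known ground truth makes the whole
    pipeline testable without raw video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    dplyr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
LinkingTo:
    Rcpp
Suggests:
    car,
    glmmTMB,
    jsonlite,
    lme4,
    lmerTest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
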