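Package: cdmtraj
Title: Cognitive Diagnosis Models and Learning-Trajectory Extraction for
    Dichotomous Assessment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Q-matrix based cognitive diagnosis models (DINA, DINO,
    A-CDM, LLM, RRUM and the saturated G-DINA) to dichotomous response data
    by EM marginal maximum likelihood, compares them by information
    criteria, classifies respondents into attribute-mastery patterns
    (EAP/MAP/MLE), and extracts main and secondary learning trajectories
    over the knowledge-state lattice from group-level pattern frequencies.
    Includes a multi-group synthetic-data generator with planted
    trajectories so every pipeline stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
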