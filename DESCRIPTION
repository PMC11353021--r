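Package: cedlar
Title: Cumulative Effective Dose Surveillance and Lifetime Attributable
    Risk for Recurrent CT Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reviewing radiology dose-registry extracts of
    patients undergoing recurrent computed tomography: cumulative
    effective dose (CED) over a sliding multi-year window with
    threshold shortlisting, per-organ cumulative absorbed dose
    accumulation from protocol-level coefficient tables, lifetime
    attributable risk (LAR) of cancer incidence and mortality from the
    BEIR VII age/sex/site coefficient grids with linear age
    interpolation, grouped descriptive cohort statistics, and a
    synthetic registry generator with known ground truth for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
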