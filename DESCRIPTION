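Package: fibrodens
Title: CT Densitometry and Efficacy Statistics for Radiation-Induced
    Pulmonary Fibrosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-lung computed-tomography densitometry for preclinical
    radiation-induced pulmonary fibrosis studies: Hounsfield-unit density
    curves, threshold volume fractions (V_-200) and HU percentiles (HU_50)
    from masked CT volumes; aggregation of trichrome slide grades into the
    12-point per-animal fibrosis score; drug-efficacy normalization against
    matched vehicle controls with pooled-variance t-tests, dual-criterion
    (histology plus CT) fibrosis incidence calls, mortality tabulation and
    baseline-anchored assay timecourses. Includes a synthetic murine
    thoracic-CT phantom generator (two-component Gaussian mixture with
    region-grown patchy consolidation) that emulates the 0 to 20 week
    fibrosis trajectory, so every stage of the pipeline is testable without
    animal data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
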