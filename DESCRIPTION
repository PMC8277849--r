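Package: nasoair
Title: Nasal Airway Morphometry and Airflow Post-Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Characterizes nasal airway anatomy and airflow from triangulated
    lumen surfaces and sampled flow fields. Extracts an airway centerline with
    normalized anatomical landmarks, slices cross-sections to profile area,
    perimeter and hydraulic diameter, and computes surface area, cavity volume
    and their ratio (SAVR) for whole cavities and anatomical regions. Flow
    post-processing yields plane mass flow, surface-averaged total pressure,
    incremental and cumulative trans-nasal resistance, perimeter-based Reynolds
    numbers, bilateral mass-flow-weighted summaries, and the partitioning of
    flow and wall shear stress between superior, middle and inferior cavity.
    Includes a parametric two-passage phantom generator with matched analytic
    laminar flow fields and paired normal/decongested cohort simulation, plus
    exact Wilcoxon signed-rank comparison of paired cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    withr,
    yaml,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
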