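Package: vrsquant
Title: Automated Quantification of Virchow-Robin Spaces from T2-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and automated quantification of visible Virchow-Robin
    (perivascular) spaces on axial T2-weighted MRI, together with the cohort
    statistics used to relate perivascular-space burden to simple febrile
    seizure duration in young children. Provides T2-like digital phantoms with
    embedded tubular and circular perivascular structures and Rician noise,
    brain extraction and three-class tissue segmentation, a supraventricular
    white-matter region of interest, multi-scale two-dimensional Frangi
    vesselness filtering, connected-component counting and volumetry, a
    correlated synthetic cohort generator, Mann-Whitney group comparisons with
    Bonferroni-adjusted significance, Pearson correlation panels, and
    LOESS-based detection of a seizure-duration cutoff.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    EBImage,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
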