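Package: vagusmap
Title: Spatial Mapping of Fascicles and Selective-Stimulation Responses in
    the Cervical Vagus Nerve
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Co-registers microCT-traced fascicle maps and back-projected
    spatially-selective vagus nerve stimulation (sVNS) responses onto a
    common circular template, averages rotation-aligned maps into
    cross-animal atlases, and quantifies the spatial organization of
    laryngeal, pulmonary, cardiac efferent and cardiac afferent regions
    with angular centre-of-mass statistics, ANOVA with multiple-comparison
    correction, and area/overlap matrices. Includes a synthetic cohort
    generator emulating porcine cervical vagus composition and
    multi-electrode cuff stimulation sessions so the full pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
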