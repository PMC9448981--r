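Package: vdthand
Title: Virtual Driving Test Telemetry Screening for HIV-Associated
    Neurocognitive Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for relating virtual driving test (VDT) telemetry to
    HIV-associated neurocognitive disorder (HAND) status in small,
    high-dimensional cohorts. Implements global deficit score (GDS)
    classification from neuropsychological T-scores, summary-statistic
    featurization of 10 Hz multichannel replay files over global and zonal
    scopes, a composite error score, stratified split-consensus
    Kruskal-Wallis variable screening with elbow-guided choice of list
    length, top-k list stability diagnostics (Jaccard similarity and
    normalized Kendall distance with a penalty parameter), and
    domain-association statistics. Includes a synthetic cohort generator
    with planted group effects so the full pipeline can be exercised and
    validated without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
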