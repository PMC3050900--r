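Package: butolscreen
Title: Genomic Library Enrichment Screening for n-Butanol Tolerance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pooled genomic-library enrichment screens of solvent
    tolerance in bacteria. Implements two-channel array-CGH log-ratio
    normalization (LOWESS), per-gene enrichment profiling across serial
    challenge steps, differential enrichment calling with control-arm
    subtraction, CAST (Cluster Affinity Search Technique) clustering of
    enrichment profiles, GO term enrichment with log odds-ratios, and
    growth-kinetics scoring of candidate genes via maximum specific growth
    rates and the IIE and RSGR tolerance statistics. A synthetic-data module
    simulates clone libraries under multiplicative selection, two-channel
    array scans with intensity-dependent dye bias, and lagged logistic
    growth curves with known ground truth, so that every stage of the screen
    can be exercised and calibrated offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    S4Vectors,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
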