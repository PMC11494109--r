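Package: thromboprofiler
Title: Thrombus Profiling, Effect Barcodes, and Platelet Adhesion Kinetics
    for Microfluidic Stenosis Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microfluidic stenosis-assay thrombus
    profiling: converts multi-channel fluorescence time courses into
    seven-dimension thrombus profiles (size plus six platelet-normalized
    biomarker enrichments), derives effect barcodes and personal thrombus
    barcodes with a sign-saturating addition rule and mean +/- 2 s.d.
    reference ranges, fits Hill dose-response curves to extract IC50s,
    analyzes biomembrane-force-probe adhesion-frequency kinetics and
    lifetime-versus-force catch/slip bond curves, estimates wall shear
    stress in stenotic rectangular microchannels by lubrication theory,
    and provides cohort discrimination statistics. Includes a seeded
    synthetic-data generator emulating the study design (four cohorts,
    inhibitor panels, Bernoulli touch cycles, exponential bond lifetimes,
    and ratiometric calcium traces) so that every stage is testable
    without access to protected human blood-sample data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    rlang
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
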