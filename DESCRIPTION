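Package: spermhts
Title: High-Throughput Sperm Motility and Acrosome-Reaction Screening Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis pipeline for plate-based phenotypic screening
    of human sperm. Detects sperm heads in brightfield time-lapse image stacks
    and links them into tracks (Crocker-Grier-style band-pass detection plus
    frame-to-frame assignment), computes standard CASA kinematic parameters
    (VCL, VSL, VAP, STR, LIN) and WHO motility classes per track, aggregates
    wells and normalises median curvilinear velocity to DMSO vehicle controls,
    computes Z'-factor plate QC and calls motility hits at a 15% reduction
    cut-off, gates flow-cytometry events into propidium-iodide/PNA-lectin
    quadrants to score acrosome reaction with event-count QC and
    fluorescence-interference triage, and confirms hits with four-parameter
    logistic dose-response fits. A ground-truthed synthetic-data generator
    simulates swimming tracks, rendered image stacks, flow-event clouds and
    whole 384-well plates for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    grDevices,
    graphics,
    minpack.lm,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
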