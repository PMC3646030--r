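Package: msiseq
Title: Microsatellite Instability Scoring from Transcriptome Indel Calls
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Catalogues perfect microsatellite tracts (repeat units of 1-6 bp)
    in transcript sequences, ingests indel calls from VCF with
    left-normalization and known-variant filtering, intersects indels with the
    microsatellite catalogue and transcript regions (5'UTR/CDS/3'UTR/ncRNA),
    and computes the PI/PD ratio (the proportion of insertions falling in
    microsatellites over the proportion of deletions falling in
    microsatellites) to classify samples as microsatellite instable (MSI) or
    stable (MSS). Includes Kolmogorov-Smirnov comparisons of microsatellite
    indel-length distributions against a control cohort, a seeded synthetic
    cohort simulator with known ground truth, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
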