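Package: tcrfingerprint
Title: TCR Fingerprinting and Cross-Reactive Antigen Prediction from
    Replacement-Scan Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds position weight matrices ("TCR fingerprints") from
    single-substitution replacement-scan measurements of T-cell receptor
    binding, activation and killing assays, scores candidate peptides
    against the fingerprint with anchor positions excluded, screens MHC
    class I binding 9-mer peptides enumerated from a proteome for
    potential off-target antigens, and selects a cross-reactivity score
    cutoff by maximum-sensitivity ROC analysis. Includes a fully seeded
    synthetic-data generator (planted recognition kernels, replicate
    assay noise, decoy proteomes, synthetic binding affinities and tissue
    expression) so the entire pipeline can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
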