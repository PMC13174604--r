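Package: iresMPRA
Title: Quantification of IRES and Cap-Dependent Translation from Massively
    Parallel Reporter Assays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end quantification of internal ribosome entry site (IRES)
    and cap-dependent initiation (CDI) activity from pooled mRNA reporter
    assays read out by paired-end sequencing. Reporter libraries carry each
    candidate 5' UTR on both an m7G-capped (G-cap, CDI) and an A-capped
    (A-cap, IRES-only) mRNA; nascently translating mRNAs are affinity
    purified and translation efficiency is estimated per construct and cap
    class as the log2 ratio of immunoprecipitated to input reads per million
    of unique molecular identifiers (UMIs). The package provides variant
    library design (scanning mutagenesis, helix disruption/rescue, rRNA
    complement tiles), a synthetic paired-end read simulator with ground
    truth, read merging, cap-class demultiplexing, UMI/stagger handling and
    unique-UMI counting, replicate combination and quality control, input
    filtering and pseudocounted RPM/TE computation, spike-in anchored
    normalization for stress comparisons, activity classification against a
    positive-control threshold, mutagenesis fold-change profiles, and
    strong-pair (G-C) secondary-structure statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Transcriptomics, Sequencing, Normalization, QualityControl
RoxygenNote: 7.3.3
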