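Package: foldscan
Title: Sliding-Window Thermodynamic Scanning and Consensus Structure Modeling for mRNA
Version: 0.9.0
Authors@R:
    person("Foldscan", "Developers", email = "foldscan@example.org", role = c("aut", "cre"))
Description: Scans transcript sequences with a sliding thermodynamic folding window to
    compute minimum free energy, shuffle-based z-scores, p-values and ensemble diversity;
    builds z-score-weighted consensus base pairing across overlapping windows, resolves
    pairing competition, and extracts unusually stable structural motifs. Includes
    per-transcript and regional (5'UTR/CDS/3'UTR) aggregation, ROC comparison of structure
    models against DMS/SHAPE chemical probing reactivities, covariation-power binning, a
    synthetic-data generator with planted hairpins for validation, and a command-line
    interface. A reduced nearest-neighbor folding engine (MFE plus partition function)
    is built in; an external RNAfold backend can be selected when available.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
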