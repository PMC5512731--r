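Package: clonekinetics
Title: Clonal Barcode Quantification and Stochastic Niche-Competition
    Simulation for Leukemia Transplantation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cellular-barcoding studies of clonal competition in
    oncogene-driven leukemia. Generates synthetic barcode libraries,
    transduced clone populations, in vitro culture trajectories and
    error-bearing amplicon reads; quantifies barcodes from FASTQ data with
    Phred-score filtering, flank-anchored extraction and greedy
    Hamming-distance error correction; computes clonal statistics (richness,
    abundances, Shannon diversity, dominance classification, delta-delta-Ct
    fold changes); and runs a single-cell agent-based model of hematopoietic
    niche competition to simulate transplantation cohorts, including graft
    sampling, class-specific engraftment, leukemia outcome classification
    and calibration of free parameters against observed incidences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
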