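Package: mfps
Title: Taxonomy-Aware Probe Set Design for Microbial Community Fingerprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Designs small sets of 10-mer DNA probes that fingerprint
    microbial 16S rRNA genes into taxonomically faithful groups.  Implements
    a training-data preparation pipeline for pre-aligned rRNA sequences
    (hypervariable-region masking, primer-anchored truncation, quality
    filtering, per-genus clustering into operational taxonomic units at 99%
    similarity), candidate probe enumeration with conservation-based
    filtering, and probe set selection by simulated annealing under either
    the Maximum Fidelity Probe Set (MFPS) cost, which penalises binary
    hybridization fingerprints shared across taxonomic groups at up to three
    levels, or the earlier Maximum Distinguishing Probe Set (MDPS) cost.
    Includes evaluation metrics (High Fidelity Ratio, low-fidelity distance
    histograms), cross-validation and phylum-holdout harnesses, and a
    deterministic generator of taxonomically structured synthetic alignments
    for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
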