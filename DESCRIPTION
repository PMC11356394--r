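Package: mthapnet
Title: Haplotype Diversity, Demography and Median-Joining Networks for
    mtDNA Control-Region Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for population analysis of aligned mitochondrial
    control-region sequences: alignment harmonization (window trimming in
    reference coordinates, indel-column removal, variable-site summaries),
    haplotype collapsing and motif-based haplogroup classification,
    haplotype and nucleotide diversity, mismatch distributions with
    sudden-expansion model fitting (tau, theta0, SSD, raggedness,
    parametric bootstrap), Fu's Fs via the Ewens sampling formula,
    hierarchical AMOVA with Phi-statistics and permutation tests, weighted
    median-joining haplotype networks with regional projections, and
    clade-aware mitogenome consensus calling with boxplot-whisker quality
    thresholds. Includes a coalescent-based synthetic-data generator that
    emulates a two-haplogroup population with star-like within-haplogroup
    expansions, and a reproducible end-to-end pipeline driven by a single
    configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
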