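Package: mitocr
Title: Mitochondrial Genome Organization and Control-Region Dissection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis toolkit for insect mitochondrial genomes,
    centred on the dissection of the A+T-rich control region. Provides
    genome-organization statistics from annotation tables (overlaps, spacers,
    junction gaps), nucleotide composition and AT/GC skew, codon usage under
    the invertebrate mitochondrial code, Nei-Gojobori (1986) Ka/Ks estimation,
    a from-scratch tandem-repeat decomposer with repeat-unit typing and
    adjacency analysis, motif scanners (homopolymers, microsatellites,
    content blocks, stem-loops), a stochastic simulator of tandem-array
    evolution by slipped-strand mispairing, tRNA-family conservation
    profiling, and seeded synthetic-data generators that emulate the
    architecture of a sequenced seed-bug mitogenome so every analysis stage
    runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
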