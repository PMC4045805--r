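Package: amiRtrace
Title: Processing Fidelity of Artificial microRNA Precursors from Small RNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess how faithfully an artificial microRNA (amiRNA)
    precursor built on a miR319-family backbone is processed in planta.
    Implements read preprocessing and collapsing for small RNA libraries,
    exact and mismatch-tolerant mapping onto hairpin precursors and target
    transcripts, block-wise classification of precursor-derived small RNAs
    with the 15-nt-overlap/6-nt-extension membership rule, decomposition of
    3'-tailed variants into a genome-matched component and a non-templated
    tail, 5'-RACE cleavage-site mapping against the position-10/11 slicer
    rule, nearest-neighbor duplex free-energy scoring with amiRNA design and
    target-selection criteria, and a seeded simulator of loop-to-base hairpin
    processing for end-to-end validation without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
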