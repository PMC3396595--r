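Package: percal
Title: Discovery and Statistics of the PERCAL Calcium-Binding Motif
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering and characterising short calcium-binding
    sequence insertions in bacterial animal-peroxidase-like (ANP-like)
    domains, centred on the PERCAL motif G-x-D-G-x-x-[GN]-[TN]-x-D-D. The
    package parses PROSITE-syntax patterns and scans protein sequences for
    them, classifies motif occurrences as intra- or extra-domain against
    user-supplied domain interval tables, extracts flanked insert records and
    derives consensus patterns and per-column information content, estimates
    expected random motif counts under an i.i.d. residue-composition
    background (with a Monte-Carlo cross-check) to form observed/expected
    enrichment ratios, and builds neighbor-joining trees with bootstrap
    consensus supports from domain alignments. A seeded synthetic-data
    module generates background proteomes, planted motif insertions with
    ground truth, and alignments evolved along known trees, so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
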