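Package: trypsearch
Title: Mass-Indexed Peptide Databases and SEQUEST-Style Spectral Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale shotgun-proteomics and metaproteomics database
    searching. Builds a three-collection peptide index (protein records,
    distinct peptide sequences with parent mappings, and peptides grouped
    by discretized monoisotopic mass) from a decoy-augmented FASTA by
    in-silico tryptic digestion; scores tandem mass spectra (MS2/MGF)
    against mass-window candidate streams with SEQUEST-style XCorr,
    DeltaCN and candidate Z-scores; and controls protein-level false
    discovery rate by target-decoy counting with a two-peptide rule.
    Includes a synthetic proteome and MS/MS run generator with ground
    truth so the whole build-search-filter loop is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    stringi,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
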