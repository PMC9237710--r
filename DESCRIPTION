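Package: bedcert
Title: Conformance Testing for the BED Genomic Interval Format
Version: 0.1.0
Authors@R: person("Hoffman Lab", "Reimplementation", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A conformance suite for the Browser Extensible Data (BED)
    plain-text genomic interval format. Provides a strict validator for the
    GA4GH BED v1 rules, a deterministic generator of an expected-pass and
    expected-fail test corpus across the BED3 to BED12 variants, a harness
    that runs external command-line tools on the corpus and scores
    per-variant correctness from exit status and captured output, a
    grammar-based fuzzer with a meta-grammar for differential testing of two
    BED consumers, and SVG badge and summary-table reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    processx,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
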