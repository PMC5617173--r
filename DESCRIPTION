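Package: excelsafe
Title: Escape Tab-Delimited Text to Prevent Spreadsheet Auto-Conversion
Version: 0.1.0
Authors@R:
    person("Moffitt", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spreadsheet programs silently reinterpret imported text: gene
    symbols such as SEPT7 become dates, RIKEN-style accessions such as
    2610100E13 become scientific notation, leading zeroes are dropped, and
    long numeric barcodes lose digits beyond the 15th.  excelsafe rewrites
    tab-delimited files so that vulnerable fields are wrapped as
    formula-quoted strings (="SEPT7") that survive import verbatim.  It also
    ships a conversion oracle that predicts what a spreadsheet would do to
    each raw field, so whole tables can be audited for silent corruption, a
    line-ending normalizer for legacy CR-only files, a command-line front
    end, and a deterministic generator of validation tables and synthetic
    gene lists for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
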