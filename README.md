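# excelsafe

Escape tab-delimited text so spreadsheet import cannot silently corrupt
it — and predict/audit the corruption that unescaped import would cause.

## The problem

Opening a tab-delimited file in a spreadsheet auto-converts text on
import, silently and irreversibly:

| in the file | after import |
|---|---|
| `00123456` | `123456` |
| `1234567890123456789` | `1234567890123450000` |
| `2610100E13` | `26101000000000000000` |
| `SEPT7` | `7-Sep` |
| `1/3` | `3-Jan` |
| `1 A` | `1:00 AM` |
| `++ stain intensity` | `#NAME?` |

Gene symbols, RIKEN clone accessions, zero-padded database keys,
plate-well identifiers (`11E9` → 1.1×10¹⁰) and long numeric barcodes are
all affected; numeric cells keep only 15 significant digits. excelsafe
prevents this by rewriting each vulnerable field `x` as the one-string
formula `="x"`, which imports as exactly the original text. Everything
else passes through byte-for-byte, so the output is still ordinary TSV
for `cut`, `paste`, `awk` and friends.

## Worked example

```r
library(excelsafe)

tf <- tempfile(fileext = ".tsv")
writeLines(c("symbol\tid\tscore",
             "SEPT7\t00123456\t1.82",
             "TP53\t2610100E13\t-0.40",
             "MARCH1\t11E9\t2.10"), tf)

out <- tempfile(fileext = ".tsv")
stats <- escape_file(tf, out)
writeLines(readLines(out))
#> symbol	id	score
#> ="SEPT7"	="00123456"	1.82
#> TP53	="2610100E13"	-0.40
#> ="MARCH1"	="11E9"	2.10
print(stats)
#> lines: 4  fields: 12  escaped: 5
#>   leading_zero: 1
#>   sci_mantissa: 2
#>   date_like: 2
```

Five fields were protected: two date-like gene symbols (`SEPT7`,
`MARCH1`), one zero-padded identifier, and two fields that parse as
wide-mantissa scientific notation (`2610100E13`, `11E9`). `TP53` and
the plain numbers are untouched. Re-running `escape_file` on its own
output changes nothing.

The conversion oracle shows what an unescaped import would have done:

```r
audit_file(tf)
#> audit: 7 of 12 fields would be corrupted on import
#>   number: 5
#>   date: 2
#>   row column      input   kind          stored_text
#> 1   2      1      SEPT7   date                7-Sep
#> 2   2      2   00123456 number               123456
#> 3   3      2 2610100E13 number 26101000000000000000
#> 4   3      3      -0.40 number                 -0.4
#> 5   4      1     MARCH1   date                1-Mar
#> 6   4      2       11E9 number          11000000000
#> 7   4      3       2.10 number                  2.1
```

Note `-0.40` → `-0.4`: the audit reports every field whose stored
*text* changes, including pure respelling of genuine numbers. The
escaper deliberately leaves those alone — the stored value is the
intended value — just as it leaves the deprecated aliases `2E4`, `2E6`,
`2E12`, `3E2`, `3e46` unescaped because they are more likely to be real
numbers than identifiers.

Per-field entry points:

```r
predict_conversion(c("SEPT7", "00123456", "1234567890123456789"))
#>                 field   kind         stored_text lossy
#> 1               SEPT7   date               7-Sep  TRUE
#> 2            00123456 number              123456  TRUE
#> 3 1234567890123456789 number 1234567890123450000  TRUE
process_field("SEPT7")
#> [1] "=\"SEPT7\""
```

## Command line

```sh
Rscript inst/exec/excelsafe escape [--no-dates] [--no-sci] [--no-zeroes] \
        [--paranoid] [--eol lf|crlf] [IN [OUT]]
Rscript inst/exec/excelsafe audit [IN [REPORT]]
Rscript inst/exec/excelsafe eol --to lf|crlf [IN [OUT]]
```

`IN`/`OUT` default to stdin/stdout; statistics go to stderr. Unknown
options (including `--help`) print a usage summary and exit non-zero.
Legacy CR-only (classic Mac) line endings are accepted everywhere and
can be normalized standalone with the `eol` subcommand.

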