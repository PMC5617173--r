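---
title: "Escaping tab-delimited text against spreadsheet auto-conversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Escaping tab-delimited text against spreadsheet auto-conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excelsafe)
```

## The problem

Spreadsheet programs reinterpret imported text silently. A tab-delimited
gene list opened by double-click arrives with `SEPT7` turned into the
date `7-Sep`, the RIKEN-style clone accession `2610100E13` turned into
the number `26101000000000000000`, the zero-padded database key
`00123456` turned into `123456`, and the 32-digit microarray barcode
truncated to 15 significant digits with the rest zeroed forever. Surveys
of published supplementary material suggest roughly a fifth of papers
with gene lists carry such corruption, because the conversion happens on
*import*, before anyone can intervene, and is irreversible afterwards.

excelsafe takes the prevention approach: rewrite the text file *before*
import so that nothing is left for the spreadsheet to convert. A
vulnerable cell `x` is replaced by the one-string formula `="x"`. The
leading `=` makes the import path treat the cell as an equation; the
quoted string makes the equation evaluate to exactly the original text.
Every other cell is passed through byte-for-byte.

## The procedure

Each field of each line goes through three stages.

**1. Cleaning** (`clean_field()`). Import artifacts are stripped
iteratively until a fixpoint: a leading UTF-8 byte-order mark, one layer
of pre-existing `="…"` escaping (with doubled interior quotes
collapsed), enclosing or leading double quotes, and leading/trailing
spaces — in that order, repeated while anything changes. Every rule
strictly shortens the string, so at most `nchar(field)` passes run.
The fixed rule order matters in one corner: a trailing space can hide an
enclosing quote pair (`"a" `), and stripping spaces first would let the
enclosing-pair rule fire where the fixed order applies the weaker
leading-quote rule. Within the class of orderings that strip quotes
before padding, the fixpoint is order-independent; the test suite
verifies this exhaustively over a trigger-character alphabet.

**2. Decision** (`decide_escape()`). A cleaned field is first tested
against a strict numeric grammar (optional sign, digits with one
optional decimal point, optional `e`/`E` exponent). Numbers are escaped
when

* the integer part has a leading zero and more than one digit
  (`00123456` — import drops the padding), flag `zeroes`;
* an exponent is present and the mantissa has ≥ 2 digits before the
  point (`11E9`, a plate-11/row-E/column-9 well identifier, which import
  loads as 1.1×10¹⁰), flag `sci`;
* there are more than 11 digits before the point (import renders ≥ 12
  digit whole numbers in scientific notation and zeroes digits past the
  15th), also flag `sci`.

Everything else is text. Under `paranoid` every non-empty text field is
escaped. Otherwise a leading `'`, a leading `=`, a leading run of
`+`/`-` followed by anything else, and (flag `dates`) anything matching
the date/time grammar triggers escaping. A field of pure signs (`++`)
is left alone — import does not touch it.

**3. Wrapping** (`wrap_field()`). Escaped cells become
`="body"` with interior `"` doubled, which is the only quoting the
formula-string syntax needs. Cleaning knows how to undo exactly this,
which gives the central invariant: processing a document twice is
byte-identical to processing it once.

## The date/time grammar, and why it is deliberately broad

The grammar a spreadsheet actually uses is locale- and version-
dependent and not published. Over-escaping costs nothing (the cell
imports as its own text either way), while under-escaping corrupts
data, so the grammar here is a documented superset of the common
behaviour: a month token is any case-insensitive prefix of ≥ 3 letters
of an English month name, combined with a 1–2 digit day (1–31) adjacent
or separated by space, hyphen, slash or period, in either order, with
an optional 2- or 4-digit year; numeric dates are `m/d`, `d/m`, `m-d`,
`d-m` and three-component forms whose components fit day/month/year
ranges; times are `H:MM(:SS)` with an optional AM/PM marker, plus the
bare `1 A` pattern (from sample series such as `1 A`, `1 B`, `1 C`,
which import reads as 1:00 AM). This
reproduces the `SEPT7`/`MARCH1`/`DEC1` class of corruption while
leaving the renamed symbols (`SEPTIN7`, `MARCHF8`) alone, because
`septi`/`marchf` are not month prefixes.

The same grammar drives both the escape rules and the conversion
oracle, so the two can only disagree where we decide they should.

## The conversion oracle

`predict_conversion()` models the import path: `="…"` imports as its
body; a leading `'` is consumed; numbers are stored as numeric cells —
leading zeroes dropped, exponents multiplied out by exact digit
shifting (no floating point until necessary), and whole numbers of
≥ 12 digits put through `fifteen_digit_store()`; leading-`=` and
leading-sign text becomes the `#NAME?` formula error unless the body is
a pure number; dates render as `D-Mmm` (the import attaches the current
year internally, so predictions are deliberately year-free); times as
`H:MM AM/PM`. `audit_table()` aggregates the predictions over a table
into a corruption report.

The 15-digit model is the one place floating point semantics are
unavoidable, and the details matter: the stored value is the nearest
binary double, and the rendered digits are the double's exact decimal
expansion *truncated* — not rounded — at the 15th significant digit,
then zero-filled. Truncation is what reproduces the published behaviour
for `1234567890123456789` (stored `1234567890123450000`, even though
decimal rounding would give `…460000`), while the nearest-double step
is what turns 18 nines into `1000000000000000000`. The implementation
is checked against an independent arbitrary-precision oracle (Python
`float`/`Decimal`) on 10⁴ random 1–25 digit integers.

## Deliberate non-escapes

Single-digit-mantissa scientific notation — `2E4`, `2E6`, `2E12`,
`3E2`, `3e46`, all of them deprecated gene aliases — is left unescaped
although import converts it, because such strings are far more likely
to be genuine numbers in scientific data. The oracle still predicts the
conversion, and the acceptance suite asserts that these five strings
are *exactly* the set on which the escaper and the oracle diverge over
the bundled validation table. For the same reason `1.50`, `.5` and
`1E05` are passed through: they are numbers, their stored value is the
intended value, and only their textual spelling changes.

A subtle consequence: a 12–15 digit whole number is escaped (the
display corruption is real) but predicted *not* lossy (the stored value
survives). The oracle's `lossy` means "stored text differs", not
"display differs".

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `dates` | `TRUE` | escape date/time-like fields |
| `sci` | `TRUE` | escape ≥ 2-digit-mantissa exponents and > 11-digit integers |
| `zeroes` | `TRUE` | escape leading-zero numbers |
| `paranoid` | `FALSE` | escape every non-number |
| `eol` | `"lf"` | output line terminator (`"crlf"` available) |

Turning a flag off is monotone: it can only reduce the set of escaped
fields. `paranoid` can only enlarge it.

## What the synthetic data does and does not establish

`synth_gene_table()` emulates a supplementary gene list: one symbol per
row plus a numeric score. A seeded fraction (`corruption_rate`; the
tests use 5–10%, far above the ~0.05% rate in real current symbol
lists, to get non-trivial counts at n = 1000–2000) is drawn from
families known to convert: `SEPT1–14`, `MARCH1–11`, `DEC1–2`,
RIKEN-style `dddddddEdd`, zero-padded identifiers and 20–30 digit
barcodes. ~2% of the remaining rows mimic the deprecated `2E4`-class
aliases and are labelled `excluded`; the rest come from a curated list
of symbols verified safe under the rules. Green tests establish that
the escaper has 100% recall on the constructed vulnerable families and
zero false positives on the curated safe set. They do not establish
anything about symbols outside those families, about non-English
locales, or about the published census counts (34/59726 human,
29/68260 mouse), which require the original GenBank symbol workbook
that cannot be redistributed here; `audit_table()` reproduces that
census when pointed at the workbook's symbol columns.

## Numerical and degenerate-input choices

* Only U+0020 is padding; tabs are delimiters and other Unicode spaces
  are data.
* An empty field is never escaped, in paranoid mode included: `=""`
  would turn a visually empty cell into a formula for no benefit.
* Sign-prefixed numbers (`-1`) are numbers, not leading-sign text; the
  number branch is checked first.
* Thousands separators are not part of the number grammar: `1,234` is
  text, has no trigger, and is left alone.
* Ragged tables pass through field-wise with a message; the tool's
  contract is per-field, not per-schema.
* A final line without a terminator keeps none; the EOL filter
  preserves terminator counts exactly and holds back a carriage return
  at a chunk boundary so `CRLF` pairs are never split.

## Known limitations

The real import grammar varies by locale and version; the bundled
validation table is the contract, not a proof of equivalence. Formula
evaluation is not modelled beyond "pure number after the signs" —
everything else maps to `#NAME?`. Date predictions carry no year, and
the 1900/1904 serial-number systems are out of scope. Comma-separated
input and multi-line quoted cells are out of scope by design: the tool
reads and writes tab-delimited text only, because that is the format
the downstream row/column Unix toolchain and the import path both
understand.
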