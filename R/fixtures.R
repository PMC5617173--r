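# Bundled validation data, generated in code: a table of should-escape /
# must-not-escape strings with their expected decisions and predicted
# import outcomes, plus a seeded synthetic gene-list generator.  Every
# other module is testable against these without any download.

#' The bundled validation table
#'
#' A deterministic table of strings with, for each: the escape-rule tag
#' expected under the default [rule_config()], whether the field is
#' escaped, and the conversion oracle's expected prediction (kind and
#' stored text).  It covers every printed corruption example verbatim
#' (zero-padded identifiers, the 19-digit integer, the RIKEN-style
#' accession, `SEPT7`, `1/3`, `1 A`, `++ stain intensity`), at least five
#' strings per rule tag, and the five deprecated gene aliases (`2E4`,
#' `2E6`, `2E12`, `3E2`, `3e46`) that are deliberately *not* escaped even
#' though import would convert them — those rows carry `excluded = TRUE`.
#' The plain-text rows double as paranoid-mode cases: under
#' `rule_config(paranoid = TRUE)` every `none`-tagged non-number row is
#' escaped with tag `paranoid`.
#'
#' `lossy` is `stored != field`: exactly the rows whose direct import
#' would silently change the cell.
#'
#' @return a data frame with columns `field`, `tag`, `escape`, `kind`,
#'   `stored`, `lossy`, `excluded`.
#' @examples
#' head(validation_table())
#' @export
validation_table <- function() {
  row <- function(field, tag, kind, stored, excluded = FALSE) {
    data.frame(field = field, tag = tag, escape = tag != "none",
               kind = kind, stored = stored, excluded = excluded,
               stringsAsFactors = FALSE)
  }
  tbl <- rbind(
    # printed corruption examples, verbatim
    row("00123456", "leading_zero", "number", "123456"),
    row("1234567890123456789", "long_integer", "number",
        "1234567890123450000"),
    row("2610100E13", "sci_mantissa", "number", "26101000000000000000"),
    row("SEPT7", "date_like", "date", "7-Sep"),
    row("1/3", "date_like", "date", "3-Jan"),
    row("1 A", "time_like", "time", "1:00 AM"),
    row("++ stain intensity", "leading_plusminus", "formula", "#NAME?"),
    # zero-padded identifiers
    row("001234", "leading_zero", "number", "1234"),
    row("007", "leading_zero", "number", "7"),
    row("010", "leading_zero", "number", "10"),
    row("0001.5", "leading_zero", "number", "1.5"),
    row("00.5", "leading_zero", "number", "0.5"),
    # plate/well identifiers: wide-mantissa scientific notation
    row("11E9", "sci_mantissa", "number", "11000000000"),
    row("12E3", "sci_mantissa", "number", "12000"),
    row("12e3", "sci_mantissa", "number", "12000"),
    row("99E2", "sci_mantissa", "number", "9900"),
    row("26E5", "sci_mantissa", "number", "2600000"),
    # long whole-number barcodes (12+ digits; >15 lose digits for good)
    row("123456789012", "long_integer", "number", "123456789012"),
    row("1234567890123456", "long_integer", "number", "1234567890123450"),
    row("999999999999999999", "long_integer", "number",
        "1000000000000000000"),
    row("52070900777217100409406332354780", "long_integer", "number",
        "52070900777217000000000000000000"),
    # leading single quotes (consumed by import)
    row("'TP53", "leading_quote", "quote_stripped", "TP53"),
    row("'0012", "leading_quote", "quote_stripped", "0012"),
    row("'=x", "leading_quote", "quote_stripped", "=x"),
    row("'hello world", "leading_quote", "quote_stripped", "hello world"),
    row("''", "leading_quote", "quote_stripped", "'"),
    # leading equals signs (evaluated as formulas)
    row("=SUM(A1)", "leading_equals", "formula", "#NAME?"),
    row("=A1", "leading_equals", "formula", "#NAME?"),
    row("=x", "leading_equals", "formula", "#NAME?"),
    row("=5", "leading_equals", "number", "5"),
    row("=TP53", "leading_equals", "formula", "#NAME?"),
    # leading +/- runs followed by text
    row("+positive", "leading_plusminus", "formula", "#NAME?"),
    row("-negative", "leading_plusminus", "formula", "#NAME?"),
    row("--x", "leading_plusminus", "formula", "#NAME?"),
    row("+/- ratio", "leading_plusminus", "formula", "#NAME?"),
    # date-like gene symbols and numeric dates
    row("MARCH1", "date_like", "date", "1-Mar"),
    row("DEC1", "date_like", "date", "1-Dec"),
    row("OCT4", "date_like", "date", "4-Oct"),
    row("SEP2", "date_like", "date", "2-Sep"),
    row("jan-5", "date_like", "date", "5-Jan"),
    row("APR-1", "date_like", "date", "1-Apr"),
    row("2/14", "date_like", "date", "14-Feb"),
    row("12-25", "date_like", "date", "25-Dec"),
    # time-like fields
    row("2 P", "time_like", "time", "2:00 PM"),
    row("9:05", "time_like", "time", "9:05 AM"),
    row("12:30", "time_like", "time", "12:30 PM"),
    row("23:59", "time_like", "time", "11:59 PM"),
    row("3:15:30", "time_like", "time", "3:15:30 AM"),
    # deprecated aliases: deliberately unescaped although import converts
    row("2E4", "none", "number", "20000", excluded = TRUE),
    row("2E6", "none", "number", "2000000", excluded = TRUE),
    row("2E12", "none", "number", "2000000000000", excluded = TRUE),
    row("3E2", "none", "number", "300", excluded = TRUE),
    row("3e46", "none", "number", paste0("3", strrep("0", 46)),
        excluded = TRUE),
    # safe strings: import leaves these alone
    row("TP53", "none", "unchanged", "TP53"),
    row("SEPTIN7", "none", "unchanged", "SEPTIN7"),
    row("MARCHF8", "none", "unchanged", "MARCHF8"),
    row("BRCA1", "none", "unchanged", "BRCA1"),
    row("GAPDH", "none", "unchanged", "GAPDH"),
    row("ACTB", "none", "unchanged", "ACTB"),
    row("abc def", "none", "unchanged", "abc def"),
    row("ab\"c", "none", "unchanged", "ab\"c"),
    row("", "none", "unchanged", ""),
    row("123456", "none", "number", "123456"),
    row("1.5", "none", "number", "1.5"),
    row("-1", "none", "number", "-1"),
    row("3.14", "none", "number", "3.14"),
    row("++", "none", "unchanged", "++"),
    row("1,234", "none", "unchanged", "1,234"),
    row("11A9", "none", "unchanged", "11A9")
  )
  tbl$lossy <- tbl$stored != tbl$field
  tbl[c("field", "tag", "escape", "kind", "stored", "lossy", "excluded")]
}

# run code with a private, seeded RNG stream, restoring any prior state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# symbols verified safe under the default rules: no month-prefix + day
# pattern, not numeric, no leading trigger characters
.safe_symbols <- c(
  "TP53", "BRCA1", "BRCA2", "EGFR", "KRAS", "MYC", "SEPTIN7", "MARCHF8",
  "CDKN2A", "PTEN", "PIK3CA", "AKT1", "STAT3", "NFKB1", "GAPDH", "ACTB",
  "VEGFA", "TNF", "IL6", "CXCL8", "FOXP3", "GATA3", "RUNX1", "SOX2",
  "POU5F1", "NANOG", "KLF4", "ALDH1A1", "CD44", "EPCAM", "VIM", "CDH1",
  "CDH2", "SNAI1", "TWIST1", "ZEB1", "MKI67", "PCNA", "TOP2A", "AURKA",
  "PLK1", "CCNB1", "CDK1", "RB1", "MDM2", "ATM", "ATR", "CHEK1", "CHEK2",
  "PALB2", "RAD51", "XRCC1", "ERCC1", "MSH2", "MLH1", "PMS2", "BRAF",
  "NRAS", "HRAS", "MAP2K1", "MAPK1", "MAPK3", "MTOR", "TSC1", "TSC2",
  "STK11", "SMAD4", "TGFBR2", "NOTCH1", "CTNNB1", "APC", "AXIN1", "GSK3B",
  "WNT5A", "FZD7", "LRP6", "HDAC1", "EZH2", "KMT2D", "ARID1A", "SMARCA4"
)

# one vulnerable identifier from a named family
.vulnerable_field <- function(family) {
  switch(family,
    septin = paste0("SEPT", sample(1:14, 1L)),
    march = paste0("MARCH", sample(1:11, 1L)),
    dec = paste0("DEC", sample(1:2, 1L)),
    riken = sprintf("%07.0fE%02d",
                    floor(stats::runif(1, 1e6, 1e7)), sample(0:99, 1L)),
    zeropad = paste0(strrep("0", sample(1:3, 1L)),
                     sprintf("%.0f", floor(stats::runif(1, 1e5, 1e7)))),
    barcode = paste0(sample(1:9, 1L),
                     paste(sample(0:9, sample(19:29, 1L), replace = TRUE),
                           collapse = "")),
    stop("unknown family: ", family)
  )
}

#' Generate a synthetic gene-list document with truth labels
#'
#' Emulates the kind of supplementary gene table the escaper is meant to
#' protect: one symbol per row plus a numeric score column.  A seeded
#' fraction `corruption_rate` of the symbols is drawn from families known
#' to be auto-converted on import (septin/march/dec-style date symbols,
#' RIKEN-style `dddddddEdd` accessions, zero-padded identifiers, long
#' digit barcodes) and labelled `vulnerable`; a small fraction of the
#' remaining rows is drawn from the deliberately-unescaped
#' single-digit-mantissa scientific-notation family and labelled
#' `excluded`; the rest are symbols verified safe and labelled `safe`.
#' By construction the escaper must escape every `vulnerable` row (100%
#' recall) and must leave every `excluded` and `safe` row alone.
#'
#' @param n_rows number of rows.
#' @param corruption_rate fraction of rows drawn from vulnerable
#'   families, in `[0, 1]`.
#' @param seed integer seed; generation is deterministic given the seed
#'   and does not disturb the caller's RNG state.
#' @param path optional path: write the document (columns `symbol`,
#'   `score`) as TSV.
#' @param labels_path optional path: write the truth labels (`symbol`,
#'   `label`, `family`) as a sidecar TSV.
#' @return a data frame with columns `symbol`, `score`, `label`,
#'   `family`.
#' @examples
#' head(synth_gene_table(10, 0.5, seed = 1))
#' @export
synth_gene_table <- function(n_rows, corruption_rate, seed,
                             path = NULL, labels_path = NULL) {
  if (!is.numeric(corruption_rate) || length(corruption_rate) != 1L ||
      is.na(corruption_rate) || corruption_rate < 0 || corruption_rate > 1) {
    stop("corruption_rate must be a single value in [0, 1]", call. = FALSE)
  }
  stopifnot(is.numeric(n_rows), n_rows >= 0)
  n_rows <- as.integer(n_rows)
  families <- c("septin", "march", "dec", "riken", "zeropad", "barcode")
  tbl <- .with_seed(seed, {
    u <- stats::runif(n_rows)
    vulnerable <- u < corruption_rate
    # ~2% of the non-vulnerable rows mimic the deprecated 2E4-class aliases
    excluded <- !vulnerable & stats::runif(n_rows) < 0.02
    label <- ifelse(vulnerable, "vulnerable",
                    ifelse(excluded, "excluded", "safe"))
    family <- rep("none", n_rows)
    symbol <- character(n_rows)
    for (i in seq_len(n_rows)) {
      if (vulnerable[i]) {
        family[i] <- sample(families, 1L)
        symbol[i] <- .vulnerable_field(family[i])
      } else if (excluded[i]) {
        family[i] <- "exclusion"
        symbol[i] <- paste0(sample(1:9, 1L), sample(c("E", "e"), 1L),
                            sample(1:99, 1L))
      } else {
        symbol[i] <- sample(.safe_symbols, 1L)
      }
    }
    data.frame(symbol = symbol,
               score = round(stats::runif(n_rows, -5, 5), 3L),
               label = label, family = family, stringsAsFactors = FALSE)
  })
  if (!is.null(path)) {
    lines <- c("symbol\tscore",
               paste(tbl$symbol, format(tbl$score, trim = TRUE), sep = "\t"))
    writeLines(lines, path)
  }
  if (!is.null(labels_path)) {
    lines <- c("symbol\tlabel\tfamily",
               paste(tbl$symbol, tbl$label, tbl$family, sep = "\t"))
    writeLines(lines, labels_path)
  }
  tbl
}
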