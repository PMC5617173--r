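# Conversion oracle: a model of what spreadsheet text import does to a
# raw field.  It is the testing ground truth for the escaper — every
# escaped output must be predicted to import verbatim — and the engine
# for auditing whole tables for would-be corruption.

#' Model 15-significant-digit numeric storage
#'
#' Spreadsheet cells hold binary double-precision floats and render at
#' most 15 significant decimal digits; digits past the 15th are
#' irrecoverably zeroed.  This helper reproduces that exactly: the digit
#' string is converted to the nearest double, the double's exact decimal
#' expansion is taken, and everything past the 15th significant digit is
#' replaced by zeroes (the rendering truncates rather than rounds, which
#' is why a 19-digit identifier ending in `...56789` is stored as
#' `...450000`).
#'
#' @param int_text character vector of unsigned digit strings (1-25
#'   digits or more; anything `as.numeric` can hold).
#' @return character vector of zero-filled digit strings.
#' @examples
#' fifteen_digit_store("1234567890123456789")  # "1234567890123450000"
#' @export
fifteen_digit_store <- function(int_text) {
  if (!all(grepl("^[0-9]+$", int_text))) {
    stop("fifteen_digit_store expects unsigned digit strings", call. = FALSE)
  }
  vapply(int_text, function(s) {
    s <- sub("^0+([0-9])", "\\1", s)
    d <- sprintf("%.0f", as.numeric(s))   # exact decimal digits of the double
    if (nchar(d) > 15L) {
      d <- paste0(substr(d, 1L, 15L), strrep("0", nchar(d) - 15L))
    }
    d
  }, "", USE.NAMES = FALSE)
}

# Expand sign/int/frac/exponent parts to a canonical decimal string the
# way a numeric cell stores them: leading zeroes dropped, exponent
# multiplied out (arbitrary precision, by digit shifting), trailing
# fractional zeroes dropped, and 15-digit storage applied to whole
# numbers of 12+ digits.  Returns the stored text.
.store_number <- function(sign, int, frac, exp) {
  digits <- paste0(int, frac)
  p <- nchar(int) + exp                       # digits before the point
  len <- nchar(digits)
  if (p >= len) {
    int_part <- paste0(digits, strrep("0", p - len))
    frac_part <- ""
  } else if (p <= 0L) {
    int_part <- "0"
    frac_part <- paste0(strrep("0", -p), digits)
  } else {
    int_part <- substr(digits, 1L, p)
    frac_part <- substr(digits, p + 1L, len)
  }
  int_part <- sub("^0+([0-9])", "\\1", int_part)
  frac_part <- sub("0+$", "", frac_part)
  if (frac_part == "" && nchar(int_part) >= 12L) {
    int_part <- fifteen_digit_store(int_part)
  } else if (frac_part != "" && nchar(int_part) >= 12L) {
    # mixed case: the double keeps at most 15 significant digits overall
    keep <- max(0L, 15L - nchar(int_part))
    v <- as.numeric(paste0(int_part, ".", frac_part))
    txt <- sprintf("%.*f", keep, v)
    int_part <- sub("[.].*$", "", txt)
    frac_part <- sub("0+$", "", sub("^[^.]*[.]?", "", txt))
  }
  body <- if (frac_part == "") int_part else paste0(int_part, ".", frac_part)
  if (sign == "-" && grepl("[1-9]", body)) {
    body <- paste0("-", body)
  }
  body
}

.render_date <- function(month, day) {
  paste0(day, "-", .month_abb[month])
}

.render_time <- function(hour, min, sec, ampm) {
  if (ampm == "") {
    suffix <- if (hour < 12L) "AM" else "PM"
    h12 <- hour %% 12L
    if (h12 == 0L) h12 <- 12L
  } else {
    suffix <- if (toupper(substr(ampm, 1L, 1L)) == "A") "AM" else "PM"
    h12 <- hour
  }
  core <- sprintf("%d:%02d", h12, min)
  if (!is.na(sec)) {
    core <- sprintf("%s:%02d", core, sec)
  }
  paste(core, suffix)
}

# scalar prediction
.predict_1 <- function(x) {
  if (is.na(x)) {
    return(list(kind = "unchanged", stored_text = NA_character_, lossy = FALSE))
  }
  # already-escaped formula string: imports as the literal body
  if (grepl('^="(.*)"$', x)) {
    body <- gsub('""', '"', sub('^="(.*)"$', "\\1", x), fixed = TRUE)
    return(list(kind = "unchanged", stored_text = body, lossy = FALSE))
  }
  # manual-escape convention: a leading single quote is consumed
  if (substr(x, 1L, 1L) == "'") {
    return(list(kind = "quote_stripped", stored_text = substring(x, 2L),
                lossy = TRUE))
  }
  # numbers (sign included in the grammar) are stored as numeric cells
  p <- parse_number(x)
  if (p$is_number) {
    exp <- if (p$exp_digits == "" || is.na(p$exp_digits)) 0L else {
      as.integer(p$exp_digits) * (if (identical(p$exp_sign, "-")) -1L else 1L)
    }
    stored <- .store_number(p$sign, p$int_digits, p$frac_digits, exp)
    return(list(kind = "number", stored_text = stored, lossy = stored != x))
  }
  # leading '=' or a leading +/- run followed by text: treated as a formula
  if (substr(x, 1L, 1L) == "=" || grepl("^[+-]+[^+-]", x)) {
    body <- sub("^[=+-]+", "", x)
    bp <- parse_number(body)
    if (bp$is_number) {
      exp <- if (bp$exp_digits == "" || is.na(bp$exp_digits)) 0L else {
        as.integer(bp$exp_digits) * (if (identical(bp$exp_sign, "-")) -1L else 1L)
      }
      stored <- .store_number(bp$sign, bp$int_digits, bp$frac_digits, exp)
      return(list(kind = "number", stored_text = stored, lossy = TRUE))
    }
    return(list(kind = "formula", stored_text = "#NAME?", lossy = TRUE))
  }
  # dates and times (shared grammar with the escape rules)
  if (.datetime_candidate(x)) {
    d <- .parse_date_1(x)
    if (!is.null(d)) {
      stored <- .render_date(d$month, d$day)
      return(list(kind = "date", stored_text = stored, lossy = stored != x))
    }
    t <- .parse_time_1(x)
    if (!is.null(t)) {
      stored <- .render_time(t$hour, t$min, t$sec, t$ampm)
      return(list(kind = "time", stored_text = stored, lossy = stored != x))
    }
  }
  list(kind = "unchanged", stored_text = x, lossy = FALSE)
}

#' Predict what spreadsheet import does to a raw field
#'
#' Models, in order: formula-quoted strings (`="..."` imports as the
#' literal body, unchanged); a leading single quote (consumed by import);
#' numeric fields (stored as numbers: leading zeroes dropped, exponents
#' expanded, 15-significant-digit storage for whole numbers of 12 or more
#' digits); fields with a leading `=` or a leading `+`/`-` run followed by
#' text (evaluated as formulas — stored as the `#NAME?` error unless the
#' body is a pure number); date-like fields (rendered `D-Mmm`, no year);
#' time-like fields (rendered `H:MM AM/PM`); everything else unchanged.
#' Formula evaluation is not modelled beyond the number case.
#'
#' @param field character vector of raw fields.
#' @return a data frame with columns `field`, `kind` (one of `unchanged`,
#'   `number`, `date`, `time`, `formula`, `quote_stripped`), `stored_text`
#'   (the post-import cell content as text) and `lossy` (`TRUE` when the
#'   stored text differs from the input).
#' @examples
#' predict_conversion(c("SEPT7", "00123456", "2610100E13", "TP53"))
#' @export
predict_conversion <- function(field) {
  field <- as.character(field)
  res <- lapply(field, .predict_1)
  data.frame(
    field = field,
    kind = vapply(res, `[[`, "", "kind"),
    stored_text = vapply(res, `[[`, "", "stored_text"),
    lossy = vapply(res, `[[`, NA, "lossy"),
    stringsAsFactors = FALSE
  )
}

#' Audit a table for would-be import corruption
#'
#' Runs [predict_conversion()] over every (selected) cell of a table and
#' aggregates the fields whose stored text would differ from the input —
#' the silent corruption a direct spreadsheet import would cause.
#'
#' @param x a character vector, matrix or data frame of raw fields.
#' @param columns optional column selector (indices or names) restricting
#'   the audit to some columns of a matrix/data frame.
#' @return an object of class `audit_report`: a list with `total`,
#'   `corrupted`, `by_kind` (counts of lossy fields per prediction kind)
#'   and `details` (a data frame of row, column, input and stored text for
#'   every lossy field).
#' @examples
#' audit_table(c("SEPT7", "TP53"))
#' @export
audit_table <- function(x, columns = NULL) {
  if (is.data.frame(x)) {
    x <- as.matrix(x)
  }
  if (is.matrix(x)) {
    if (!is.null(columns)) {
      x <- x[, columns, drop = FALSE]
    }
    cells <- as.character(x)
    row_idx <- rep(seq_len(nrow(x)), times = ncol(x))
    col_lab <- colnames(x)
    if (is.null(col_lab)) col_lab <- as.character(seq_len(ncol(x)))
    col_idx <- rep(col_lab, each = nrow(x))
  } else {
    cells <- as.character(x)
    row_idx <- seq_along(cells)
    col_idx <- rep("1", length(cells))
  }
  pred <- predict_conversion(cells)
  lossy <- which(!is.na(pred$lossy) & pred$lossy)
  by_kind <- table(factor(pred$kind[lossy],
                          levels = c("number", "date", "time", "formula",
                                     "quote_stripped")))
  structure(
    list(
      total = length(cells),
      corrupted = length(lossy),
      by_kind = by_kind,
      details = data.frame(
        row = row_idx[lossy],
        column = col_idx[lossy],
        input = cells[lossy],
        kind = pred$kind[lossy],
        stored_text = pred$stored_text[lossy],
        stringsAsFactors = FALSE
      )
    ),
    class = "audit_report"
  )
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("audit: %d of %d fields would be corrupted on import\n",
              x$corrupted, x$total))
  nz <- x$by_kind[x$by_kind > 0L]
  if (length(nz)) {
    cat(paste0("  ", names(nz), ": ", as.integer(nz), collapse = "\n"),
        "\n", sep = "")
  }
  if (nrow(x$details)) {
    print(utils::head(x$details, 10L))
    if (nrow(x$details) > 10L) {
      cat("  ... and", nrow(x$details) - 10L, "more\n")
    }
  }
  invisible(x)
}

#' Audit a tab-delimited file
#'
#' File-level wrapper around [audit_table()]: reads a tab-delimited UTF-8
#' file (any line-ending convention) and, optionally, writes the lossy
#' fields as a tab-delimited report (`row`, `column`, `input`, `kind`,
#' `stored_text`).
#'
#' @param input path or connection to the tab-delimited file.
#' @param output optional path or connection for the report.
#' @param columns optional column selector (indices).
#' @return the `audit_report`, invisibly if `output` is given.
#' @export
audit_file <- function(input, output = NULL, columns = NULL) {
  bytes <- normalize_eol(.read_bytes(input), "lf")
  dec <- .decode_lines(bytes)
  fields <- .split_fields(dec$lines)
  nf <- lengths(fields)
  flat <- unlist(fields, use.names = FALSE)
  rows <- rep.int(seq_along(fields), nf)
  cols <- sequence(nf)
  if (!is.null(columns)) {
    keep <- cols %in% columns
    flat <- flat[keep]
    rows <- rows[keep]
    cols <- cols[keep]
  }
  pred <- predict_conversion(flat)
  lossy <- which(!is.na(pred$lossy) & pred$lossy)
  by_kind <- table(factor(pred$kind[lossy],
                          levels = c("number", "date", "time", "formula",
                                     "quote_stripped")))
  rep_obj <- structure(
    list(
      total = length(flat),
      corrupted = length(lossy),
      by_kind = by_kind,
      details = data.frame(
        row = rows[lossy],
        column = as.character(cols[lossy]),
        input = flat[lossy],
        kind = pred$kind[lossy],
        stored_text = pred$stored_text[lossy],
        stringsAsFactors = FALSE
      )
    ),
    class = "audit_report"
  )
  if (!is.null(output)) {
    lines <- c(paste(c("row", "column", "input", "kind", "stored_text"),
                     collapse = "\t"),
               do.call(paste, c(rep_obj$details, sep = "\t")))
    .write_bytes(charToRaw(enc2utf8(paste0(paste(lines, collapse = "\n"),
                                           "\n"))), output)
    return(invisible(rep_obj))
  }
  rep_obj
}
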