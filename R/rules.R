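# Escape-decision rules.  A clean field is either a number (judged by the
# numeric rules: leading zeroes, scientific-notation mantissa width, long
# integers) or text (judged by leading trigger characters and the shared
# date/time grammar).  The grammar here is deliberately a little broader
# than any single spreadsheet locale: over-escaping is harmless,
# under-escaping silently corrupts identifiers.

# ---------------------------------------------------------------------------
# configuration

#' Escape-rule configuration
#'
#' Bundles the four behaviour flags of the escaper plus the output
#' line-terminator policy.  All three pattern classes default to on;
#' paranoid mode (escape every non-number) defaults to off.
#'
#' @param dates escape fields that look like dates or times of day.
#' @param sci escape scientific notation with a mantissa of two or more
#'   integer digits (plate identifiers such as `11E9`) and whole numbers
#'   with more than 11 digits before the decimal point (long barcodes).
#' @param zeroes escape numbers whose integer part has a leading zero
#'   (zero-padded database identifiers such as `00123456`).
#' @param paranoid escape every field that is not a number, regardless of
#'   the pattern rules.
#' @param eol line terminator used when writing escaped output.
#' @return an object of class `rule_config`.
#' @examples
#' rule_config()
#' rule_config(dates = FALSE, paranoid = TRUE)
#' @export
rule_config <- function(dates = TRUE, sci = TRUE, zeroes = TRUE,
                        paranoid = FALSE, eol = c("lf", "crlf")) {
  eol <- match.arg(eol)
  for (flag in list(dates, sci, zeroes, paranoid)) {
    if (!is.logical(flag) || length(flag) != 1L || is.na(flag)) {
      stop("rule flags must be single TRUE/FALSE values", call. = FALSE)
    }
  }
  structure(
    list(dates = dates, sci = sci, zeroes = zeroes,
         paranoid = paranoid, eol = eol),
    class = "rule_config"
  )
}

#' @export
print.rule_config <- function(x, ...) {
  cat("<rule_config> dates:", x$dates, " sci:", x$sci,
      " zeroes:", x$zeroes, " paranoid:", x$paranoid,
      " eol:", x$eol, "\n")
  invisible(x)
}

# rule tags, in reporting order
.rule_tags <- c("none", "leading_zero", "sci_mantissa", "long_integer",
                "leading_quote", "leading_equals", "leading_plusminus",
                "date_like", "time_like", "paranoid")

# ---------------------------------------------------------------------------
# number grammar

# optional sign; digits with an optional single decimal point (digits on at
# least one side); optional e/E exponent with optional sign and >= 1 digit
.number_re <- "^([+-]?)(([0-9]+)([.]([0-9]*))?|[.]([0-9]+))([eE]([+-]?)([0-9]+))?$"

#' Parse a clean field as a number
#'
#' Splits a field into its numeric parts: sign, integer digits, fraction
#' digits and exponent.  Fields not matching the grammar (anything with
#' spaces, commas, letters other than a single exponent marker, multiple
#' points, ...) are flagged `is_number = FALSE` and their part columns are
#' `NA`.  Reassembling the parts of a recognized number reproduces the
#' original text exactly.
#'
#' @param field character vector of clean fields.
#' @return a data frame with one row per field and columns `field`,
#'   `is_number`, `sign`, `int_digits`, `has_point`, `frac_digits`,
#'   `exp_char`, `exp_sign`, `exp_digits` and `mantissa_int_len` (number of
#'   digits before the decimal point).
#' @examples
#' parse_number(c("2610100E13", "2E4", "1 A"))
#' @export
parse_number <- function(field) {
  field <- as.character(field)
  n <- length(field)
  out <- data.frame(
    field = field,
    is_number = !is.na(field) & grepl(.number_re, field),
    sign = NA_character_, int_digits = NA_character_,
    has_point = NA, frac_digits = NA_character_,
    exp_char = NA_character_, exp_sign = NA_character_,
    exp_digits = NA_character_, mantissa_int_len = NA_integer_,
    stringsAsFactors = FALSE
  )
  hit <- which(out$is_number)
  if (length(hit)) {
    m <- regmatches(field[hit], regexec(.number_re, field[hit]))
    g <- function(i) vapply(m, `[`, "", i + 1L)  # group i (1 = whole match)
    int_led <- g(3)            # digits before point ("" for ".5" style)
    point_led_frac <- g(6)     # digits of a point-led mantissa
    dot_part <- g(4)           # ".frac" when int-led mantissa has a point
    out$sign[hit] <- g(1)
    out$int_digits[hit] <- int_led
    out$has_point[hit] <- dot_part != "" | point_led_frac != ""
    out$frac_digits[hit] <- ifelse(point_led_frac != "", point_led_frac, g(5))
    exp_whole <- g(7)
    out$exp_char[hit] <- ifelse(exp_whole == "", "", substr(exp_whole, 1L, 1L))
    out$exp_sign[hit] <- g(8)
    out$exp_digits[hit] <- g(9)
    out$mantissa_int_len[hit] <- nchar(int_led)
  }
  out
}

#' Decide whether a parsed number needs escaping
#'
#' Three numeric rules, checked in order (first match wins):
#' * `leading_zero` — the integer part has more than one digit and starts
#'   with `0` (import would drop the padding);
#' * `sci_mantissa` — an exponent is present and the mantissa has at least
#'   2 digits before the decimal point (plate identifiers such as `11E9`);
#' * `long_integer` — more than 11 digits before the decimal point
#'   (import renders these in scientific notation and zeroes digits past
#'   the 15th).
#'
#' Single-digit-mantissa scientific notation (`2E4`, `3e46`) is deliberately
#' left alone: such strings are more likely to be genuine numbers than
#' identifiers.  Leading zeroes in the *exponent* (`1E05`) do not trigger
#' `leading_zero`; the rule reads only the integer part of the mantissa.
#'
#' @param parts a data frame from [parse_number()].
#' @param config a [rule_config()].
#' @return a data frame with columns `escape` (logical) and `rule` (tag);
#'   rows whose input was not a number get `NA`/`"none"`.
#' @export
number_needs_escape <- function(parts, config = rule_config()) {
  stopifnot(inherits(config, "rule_config"))
  int <- parts$int_digits
  rule <- rep("none", nrow(parts))
  lead0 <- config$zeroes & !is.na(int) & nchar(int) > 1L &
    substr(int, 1L, 1L) == "0"
  sci <- config$sci & !is.na(parts$exp_char) & parts$exp_char != "" &
    parts$mantissa_int_len >= 2L
  long <- config$sci & !is.na(parts$mantissa_int_len) &
    parts$mantissa_int_len > 11L
  rule[which(long)] <- "long_integer"
  rule[which(sci)] <- "sci_mantissa"
  rule[which(lead0)] <- "leading_zero"
  rule[!parts$is_number] <- "none"
  data.frame(escape = rule != "none", rule = rule, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# date / time grammar (shared between the escape rules and the conversion
# oracle, so "what we escape" and "what the oracle predicts" can only
# diverge where we deliberately document it)

.month_names <- c("january", "february", "march", "april", "may", "june",
                  "july", "august", "september", "october", "november",
                  "december")
.month_abb <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

# every case-insensitive prefix of length >= 3 of an English month name,
# longest first so the regex alternation prefers the longest token
.month_prefixes <- unlist(lapply(.month_names, function(m) {
  substring(m, 1L, 3L:nchar(m))
}))
.month_re <- paste(.month_prefixes[order(-nchar(.month_prefixes))],
                   collapse = "|")

.date_sep <- "[ /.-]"
.re_month_day <- paste0("^(", .month_re, ")", .date_sep,
                        "?([0-9]{1,2})(", .date_sep,
                        "?([0-9]{2}|[0-9]{4}))?$")
.re_day_month <- paste0("^([0-9]{1,2})", .date_sep,
                        "?(", .month_re, ")(", .date_sep,
                        "?([0-9]{2}|[0-9]{4}))?$")
.re_num_2 <- "^([0-9]{1,2})([/-])([0-9]{1,2})$"
.re_num_3 <- "^([0-9]{1,4})([/-])([0-9]{1,2})\\2([0-9]{1,4})$"
.re_time_colon <- "^([0-9]{1,2}):([0-9]{2})(:([0-9]{2}))?( ?([apAP])[mM]?)?$"
.re_time_ap <- "^([0-9]{1,2}) ?([apAP])[mM]?$"

.month_index <- function(token) {
  match(tolower(substr(token, 1L, 3L)), substr(.month_names, 1L, 3L))
}

# scalar: parse a clean field as a date; NULL if it is not date-like
.parse_date_1 <- function(x) {
  m <- regmatches(x, regexec(.re_month_day, x, ignore.case = TRUE))[[1]]
  if (length(m)) {
    day <- as.integer(m[3])
    if (day >= 1L && day <= 31L) {
      return(list(month = .month_index(m[2]), day = day))
    }
  }
  m <- regmatches(x, regexec(.re_day_month, x, ignore.case = TRUE))[[1]]
  if (length(m)) {
    day <- as.integer(m[2])
    if (day >= 1L && day <= 31L) {
      return(list(month = .month_index(m[3]), day = day))
    }
  }
  m <- regmatches(x, regexec(.re_num_2, x))[[1]]
  if (length(m)) {
    a <- as.integer(m[2])
    b <- as.integer(m[4])
    # month/day preferred (US-style import), else day/month
    if (a >= 1L && a <= 12L && b >= 1L && b <= 31L) {
      return(list(month = a, day = b))
    }
    if (b >= 1L && b <= 12L && a >= 1L && a <= 31L) {
      return(list(month = b, day = a))
    }
    return(NULL)
  }
  m <- regmatches(x, regexec(.re_num_3, x, perl = TRUE))[[1]]
  if (length(m)) {
    a <- as.integer(m[2])
    b <- as.integer(m[4])
    c3 <- as.integer(m[5])
    na <- nchar(m[2])
    nc <- nchar(m[5])
    if (na <= 2L && a >= 1L && a <= 12L && b >= 1L && b <= 31L &&
        nc %in% c(2L, 4L)) {
      return(list(month = a, day = b))                       # m/d/y
    }
    if (na <= 2L && a >= 1L && a <= 31L && b >= 1L && b <= 12L &&
        nc %in% c(2L, 4L)) {
      return(list(month = b, day = a))                       # d/m/y
    }
    if (na == 4L && b >= 1L && b <= 12L && c3 >= 1L && c3 <= 31L) {
      return(list(month = b, day = c3))                      # y/m/d
    }
  }
  NULL
}

# scalar: parse a clean field as a time of day; NULL if it is not time-like
.parse_time_1 <- function(x) {
  m <- regmatches(x, regexec(.re_time_colon, x))[[1]]
  if (length(m)) {
    h <- as.integer(m[2])
    mi <- as.integer(m[3])
    se <- if (m[5] == "") NA_integer_ else as.integer(m[5])
    ap <- toupper(m[7])
    ok <- mi <= 59L && (is.na(se) || se <= 59L) &&
      (if (ap == "") h <= 23L else (h >= 1L && h <= 12L))
    if (ok) {
      return(list(hour = h, min = mi, sec = se, ampm = ap))
    }
  }
  m <- regmatches(x, regexec(.re_time_ap, x))[[1]]
  if (length(m)) {
    h <- as.integer(m[2])
    if (h >= 1L && h <= 12L) {
      return(list(hour = h, min = 0L, sec = NA_integer_,
                  ampm = toupper(m[3])))
    }
  }
  NULL
}

# cheap vectorized prefilter so property tests over 10^4 strings stay fast
.datetime_candidate <- function(field) {
  has_month <- grepl(.month_re, field, ignore.case = TRUE)
  numericish <- grepl("^[0-9]", field)
  !is.na(field) & (has_month | numericish)
}

#' Classify a field as date-like, time-like, or neither
#'
#' The grammar recognizes month-token dates (a case-insensitive prefix of
#' at least three letters of an English month name, with a 1-2 digit day
#' adjacent or separated by space, hyphen, slash or period, in either
#' order, optionally followed by a 2- or 4-digit year), numeric dates
#' (`m/d`, `d/m`, `m-d`, `d-m` and three-component forms whose components
#' fit day/month/year ranges), colon times (`H:MM`, `H:MM:SS`, optionally
#' with an AM/PM marker) and bare number-plus-A/P fields such as `1 A`.
#'
#' `SEPT7` is date-like; the renamed symbol `SEPTIN7` is not (`septi` is
#' not a month prefix).  Callers are expected to have ruled out numbers
#' first: a pure number never reaches this check in [decide_escape()].
#'
#' @param field character vector of clean fields.
#' @return character vector of tags: `"date_like"`, `"time_like"` or
#'   `"none"`.
#' @examples
#' looks_like_date_or_time(c("SEPT7", "1/3", "1 A", "SEPTIN7"))
#' @export
looks_like_date_or_time <- function(field) {
  field <- as.character(field)
  out <- rep("none", length(field))
  cand <- which(.datetime_candidate(field))
  for (i in cand) {
    if (!is.null(.parse_date_1(field[i]))) {
      out[i] <- "date_like"
    } else if (!is.null(.parse_time_1(field[i]))) {
      out[i] <- "time_like"
    }
  }
  out
}

# ---------------------------------------------------------------------------
# the full decision

#' Decide whether clean fields must be escaped
#'
#' Implements the full branch structure: numbers are judged by
#' [number_needs_escape()]; under `paranoid` every non-empty non-number is
#' escaped; otherwise a leading single quote, a leading equals sign, a
#' leading run of `+`/`-` followed by at least one other character, and
#' (when `dates` is on) date/time-likeness each trigger escaping.  Within
#' the text branch the first matching rule is reported
#' (quote > equals > plus/minus > date/time); the escaped output is the
#' same whichever tag is reported.  An empty field always passes.
#'
#' Sign-prefixed numbers (`-1`, `+1.5`) take the number branch and are not
#' `leading_plusminus` candidates; a field of only signs (`++`) passes,
#' since import leaves it alone.
#'
#' @param field character vector of clean fields.
#' @param config a [rule_config()].
#' @return a data frame with columns `field`, `escape` (logical) and
#'   `rule` (tag; `"none"` iff `escape` is `FALSE`).
#' @examples
#' decide_escape(c("SEPT7", "00123456", "TP53", "++ stain intensity"))
#' @export
decide_escape <- function(field, config = rule_config()) {
  stopifnot(inherits(config, "rule_config"))
  field <- as.character(field)
  parts <- parse_number(field)
  rule <- rep("none", length(field))

  num <- parts$is_number
  if (any(num)) {
    rule[num] <- number_needs_escape(parts[num, , drop = FALSE], config)$rule
  }

  txt <- which(!num & !is.na(field) & field != "")
  if (length(txt)) {
    f <- field[txt]
    if (config$paranoid) {
      rule[txt] <- "paranoid"
    } else {
      r <- rep("none", length(f))
      r[grepl("^[+-]+[^+-]", f)] <- "leading_plusminus"
      r[substr(f, 1L, 1L) == "="] <- "leading_equals"
      r[substr(f, 1L, 1L) == "'"] <- "leading_quote"
      if (config$dates) {
        open <- r == "none"
        r[open] <- looks_like_date_or_time(f[open])
      }
      rule[txt] <- r
    }
  }

  data.frame(field = field, escape = rule != "none", rule = rule,
             stringsAsFactors = FALSE)
}
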