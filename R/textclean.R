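# Field cleaning: iteratively strip import artifacts (byte-order marks,
# prior escaping, quotes, padding) until nothing changes.  Every rule
# strictly shortens the string, so the fixpoint loop terminates in at most
# nchar(field) passes.

#' Strip a single leading byte-order mark from each field
#'
#' Some exporters (notably database dump tools) prepend a UTF-8 byte-order
#' mark (U+FEFF) to files or individual fields.  Downstream tools that are
#' unaware of BOMs treat them as literal characters, which breaks both
#' pattern matching and exact-string database joins, so they are removed.
#' Only a single *leading* mark is stripped per call; interior marks are
#' left untouched.
#'
#' @param field character vector of raw fields (no tabs, no line
#'   terminators).
#' @return character vector of the same length.
#' @examples
#' strip_bom("\uFEFFSEPT7")
#' @export
strip_bom <- function(field) {
  sub("^\uFEFF", "", field)
}

#' Remove one layer of pre-existing formula-quote escaping
#'
#' A field exactly of the form `="<body>"` (the escaped form this package
#' itself emits) is unwrapped to `<body>`, with doubled interior quotes
#' (`""`) collapsed back to single quotes, so that re-running the escaper
#' over already-escaped output is a no-op rather than double-wrapping.
#' Anything not in that exact form is returned unchanged.  One layer is
#' removed per call; [clean_field()]'s fixpoint loop peels nested layers.
#'
#' @inheritParams strip_bom
#' @return character vector of the same length.
#' @examples
#' strip_prior_escape('="SEPT7"')
#' @export
strip_prior_escape <- function(field) {
  hit <- !is.na(field) & grepl('^="(.*)"$', field)
  if (any(hit)) {
    body <- sub('^="(.*)"$', "\\1", field[hit])
    field[hit] <- gsub('""', '"', body, fixed = TRUE)
  }
  field
}

#' Remove enclosing or leading double quotes
#'
#' A field enclosed in a matching pair of double quotes loses both;
#' otherwise a single leading double quote is removed.  A field consisting
#' of one bare `"` counts as a leading quote and becomes empty.  Interior
#' quotes are never touched.
#'
#' @inheritParams strip_bom
#' @return character vector of the same length.
#' @examples
#' strip_quotes('"00123456"')
#' @export
strip_quotes <- function(field) {
  enclosed <- !is.na(field) & nchar(field) >= 2L & grepl('^".*"$', field)
  field[enclosed] <- sub('^"(.*)"$', "\\1", field[enclosed])
  field[!enclosed] <- sub('^"', "", field[!enclosed])
  field
}

#' Remove leading and trailing spaces
#'
#' Only U+0020 is treated as a space: tabs are field delimiters and never
#' appear inside a field, and other Unicode space characters are left
#' alone (the cleaning rules are deliberately byte-conservative).
#'
#' @inheritParams strip_bom
#' @return character vector of the same length.
#' @export
strip_pad <- function(field) {
  sub("[ ]+$", "", sub("^[ ]+", "", field))
}

#' Clean raw fields to their canonical form
#'
#' Applies [strip_bom()], [strip_prior_escape()], [strip_quotes()] and
#' [strip_pad()] in that order, repeatedly, until no rule changes the
#' field.  The result is the canonical content that a spreadsheet should
#' ultimately display: no leading BOM, no prior escaping, no enclosing or
#' leading double quote, no leading/trailing spaces, and re-cleaning it is
#' a no-op.  The empty string is a valid clean field.
#'
#' Because every individual rule strictly shortens the string, the loop
#' terminates, and the fixpoint does not depend on the order in which the
#' rules are applied.
#'
#' @inheritParams strip_bom
#' @return character vector of clean fields, same length as the input.
#' @examples
#' clean_field(' "="SEPT7"" ')   # -> "SEPT7"
#' @export
clean_field <- function(field) {
  out <- as.character(field)
  repeat {
    prev <- out
    out <- strip_pad(strip_quotes(strip_prior_escape(strip_bom(out))))
    if (identical(out, prev)) {
      break
    }
  }
  out
}
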