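# Streaming escaper: clean each field, decide, and wrap the vulnerable
# ones as formula-quoted strings.  Row count, column structure and field
# order are preserved exactly; the only change a downstream parser can see
# is that some cells now read ="...".

#' Wrap a clean field as a formula-quoted string
#'
#' Produces `="<body>"`, with every interior double quote doubled
#' (spreadsheet formula-string syntax), so import displays the body
#' verbatim instead of auto-converting it.
#'
#' @param field character vector of clean fields.
#' @return character vector of wrapped fields.
#' @examples
#' wrap_field("SEPT1")           # ="SEPT1"
#' wrap_field('he said "hi"')    # ="he said ""hi"""
#' @export
wrap_field <- function(field) {
  paste0('="', gsub('"', '""', field, fixed = TRUE), '"')
}

#' Unwrap a formula-quoted field
#'
#' Inverse of [wrap_field()]: a field exactly of the form `="<body>"`
#' loses the wrapper and has doubled quotes collapsed; anything else is
#' returned unchanged.
#'
#' @param field character vector.
#' @return character vector.
#' @export
unwrap_field <- function(field) {
  strip_prior_escape(field)
}

#' Clean and escape a single raw field
#'
#' The composition the whole tool is built from: [clean_field()], then
#' [decide_escape()], then [wrap_field()] when the decision says escape,
#' otherwise the clean field verbatim.  Running the result through
#' `process_field` again returns it unchanged (prior escaping is removed
#' by the cleaning loop before the decision is re-taken).
#'
#' @param field character vector of raw fields.
#' @param config a [rule_config()].
#' @return character vector of escaped-or-clean fields.
#' @examples
#' process_field(c("SEPT7", "123456", "00123456"))
#' @export
process_field <- function(field, config = rule_config()) {
  cf <- clean_field(field)
  d <- decide_escape(cf, config)
  ifelse(d$escape, wrap_field(cf), cf)
}

# split lines on tabs, keeping trailing empty fields (strsplit drops them)
.split_fields <- function(lines) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  want <- nchar(lines) - nchar(gsub("\t", "", lines, fixed = TRUE)) + 1L
  short <- which(lengths(fields) < want)
  if (length(short)) {
    fields[short] <- Map(function(f, k) c(f, character(k)),
                         fields[short], want[short] - lengths(fields[short]))
  }
  fields
}

.empty_stats <- function() {
  by_rule <- integer(length(.rule_tags) - 1L)
  names(by_rule) <- .rule_tags[-1L]
  structure(
    list(lines = 0L, fields = 0L, escaped = 0L, by_rule = by_rule),
    class = "process_stats"
  )
}

#' @export
print.process_stats <- function(x, ...) {
  cat(sprintf("lines: %d  fields: %d  escaped: %d\n",
              x$lines, x$fields, x$escaped))
  nz <- x$by_rule[x$by_rule > 0L]
  if (length(nz)) {
    cat(paste0("  ", names(nz), ": ", nz, collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}

#' Escape every field of a tab-delimited document
#'
#' Splits each line on tabs, runs [process_field()] on every cell, and
#' joins the line back together.  Line count, per-line field count and
#' field order are preserved exactly; ragged tables (varying field counts)
#' pass through unchanged apart from escaping, with an informational
#' message.
#'
#' @param lines character vector of lines (already terminator-free; see
#'   [normalize_eol()] / [escape_file()] for byte-level input).
#' @param config a [rule_config()].
#' @param warn_ragged emit a message when lines have differing field
#'   counts.
#' @return a list with `lines` (the escaped lines) and `stats` (a
#'   `process_stats` object: line, field and per-rule escape counts).
#' @examples
#' process_lines("SEPT7\t123456")$lines
#' @export
process_lines <- function(lines, config = rule_config(),
                          warn_ragged = TRUE) {
  stats <- .empty_stats()
  stats$lines <- length(lines)
  if (!length(lines)) {
    return(list(lines = character(0), stats = stats))
  }
  fields <- .split_fields(lines)
  nf <- lengths(fields)
  if (warn_ragged && length(unique(nf)) > 1L) {
    message("ragged table: lines have between ", min(nf), " and ",
            max(nf), " fields; structure preserved as-is")
  }
  flat <- unlist(fields, use.names = FALSE)
  cf <- clean_field(flat)
  d <- decide_escape(cf, config)
  out_flat <- ifelse(d$escape, wrap_field(cf), cf)

  stats$fields <- length(flat)
  stats$escaped <- sum(d$escape)
  tab <- table(factor(d$rule[d$escape], levels = names(stats$by_rule)))
  stats$by_rule <- stats$by_rule + as.integer(tab)

  out <- vapply(split(out_flat, rep.int(seq_along(fields), nf)),
                paste, "", collapse = "\t")
  names(out) <- NULL
  list(lines = out, stats = stats)
}

# read a whole file (or connection) as raw bytes
.read_bytes <- function(input) {
  if (inherits(input, "connection")) {
    if (!isOpen(input)) {
      open(input, "rb")
      on.exit(close(input))
    }
    chunks <- list()
    repeat {
      b <- readBin(input, "raw", n = 1048576L)
      if (!length(b)) break
      chunks[[length(chunks) + 1L]] <- b
    }
    return(do.call(c, c(chunks, list(raw(0)))))
  }
  if (!file.exists(input)) {
    stop("cannot read input: ", input, call. = FALSE)
  }
  readBin(input, "raw", n = file.size(input))
}

.write_bytes <- function(bytes, output) {
  if (inherits(output, "connection")) {
    if (!isOpen(output)) {
      open(output, "wb")
      on.exit(close(output))
    }
    writeBin(bytes, output)
  } else {
    con <- file(output, "wb")
    on.exit(close(con))
    writeBin(bytes, con)
  }
  invisible(NULL)
}

# decode normalized (LF-terminated) bytes into lines; errors name the
# first undecodable line.  Returns list(lines, trailing_newline).
.decode_lines <- function(bytes) {
  # strip a file-level UTF-8 BOM before tokenizing
  if (length(bytes) >= 3L && identical(bytes[1:3], as.raw(c(0xef, 0xbb, 0xbf)))) {
    bytes <- bytes[-(1:3)]
  }
  if (!length(bytes)) {
    return(list(lines = character(0), trailing_newline = FALSE))
  }
  if (any(bytes == as.raw(0L))) {
    stop("input contains NUL bytes; not a text file", call. = FALSE)
  }
  txt <- rawToChar(bytes)
  trailing <- bytes[length(bytes)] == as.raw(10L)
  lines <- strsplit(txt, "\n", fixed = TRUE, useBytes = TRUE)[[1]]
  if (!trailing && !length(lines)) {
    lines <- ""
  }
  bad <- which(!validUTF8(lines))
  if (length(bad)) {
    stop("line ", bad[1], ": invalid UTF-8 byte sequence", call. = FALSE)
  }
  Encoding(lines) <- "UTF-8"
  list(lines = lines, trailing_newline = trailing)
}

#' Escape a tab-delimited file
#'
#' Reads a tab-delimited UTF-8 file (byte-order mark allowed; CRLF, LF or
#' legacy CR-only line endings all accepted), escapes every vulnerable
#' field, and writes the result with the configured line terminator
#' (UTF-8, no BOM).  A final line without a terminator stays
#' terminator-free.  Undecodable bytes abort with an error naming the
#' offending line.
#'
#' @param input path or connection to read from.
#' @param output path or connection to write to.
#' @param config a [rule_config()]; `config$eol` selects the output
#'   terminator.
#' @param warn_ragged see [process_lines()].
#' @return the `process_stats` object, invisibly.
#' @export
escape_file <- function(input, output, config = rule_config(),
                        warn_ragged = TRUE) {
  bytes <- normalize_eol(.read_bytes(input), "lf")
  dec <- .decode_lines(bytes)
  res <- process_lines(dec$lines, config, warn_ragged = warn_ragged)
  eol <- if (config$eol == "crlf") "\r\n" else "\n"
  txt <- paste(res$lines, collapse = eol)
  if (dec$trailing_newline && length(res$lines)) {
    txt <- paste0(txt, eol)
  }
  .write_bytes(charToRaw(enc2utf8(txt)), output)
  invisible(res$stats)
}
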