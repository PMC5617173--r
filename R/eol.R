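# Line-terminator normalization.  Legacy Mac-style exports (still the
# default of some spreadsheet "save as text" paths) terminate lines with a
# bare carriage return, which many line readers cannot tokenize; this
# rewrites CRLF, LF and CR-only terminators to one convention before any
# parsing happens.

#' Normalize line terminators in a byte stream
#'
#' Rewrites every CRLF, LF and lone-CR terminator to the target
#' convention.  The number of line terminators is preserved and no other
#' byte is altered; a final line without a terminator keeps none.
#' Normalizing twice is the same as once, and LF -> CRLF -> LF is the
#' identity.
#'
#' @param bytes a raw vector (or a character scalar, converted with
#'   [charToRaw()]).
#' @param target output convention, `"lf"` or `"crlf"`.
#' @return a raw vector.
#' @examples
#' rawToChar(normalize_eol(charToRaw("a\rb\r"), "lf"))
#' @export
normalize_eol <- function(bytes, target = c("lf", "crlf")) {
  target <- match.arg(target)
  if (is.character(bytes)) {
    bytes <- charToRaw(bytes)
  }
  stopifnot(is.raw(bytes))
  n <- length(bytes)
  if (n == 0L) {
    return(bytes)
  }
  cr <- bytes == as.raw(13L)
  lf <- bytes == as.raw(10L)
  # drop the LF of each CRLF pair, then turn every CR into LF
  drop <- c(FALSE, cr[-n]) & lf
  b <- bytes[!drop]
  b[b == as.raw(13L)] <- as.raw(10L)
  if (target == "crlf") {
    is_lf <- b == as.raw(10L)
    pos <- seq_along(b) + cumsum(is_lf)       # one CR inserted before each LF
    out <- raw(length(b) + sum(is_lf))
    out[pos] <- b
    out[pos[is_lf] - 1L] <- as.raw(13L)
    b <- out
  }
  b
}

#' Normalize line terminators of a file, streaming
#'
#' Chunked version of [normalize_eol()] usable as a pipe filter on files
#' of any size.  A carriage return at a chunk boundary is held back until
#' the next chunk so CRLF pairs are never split.
#'
#' @param input path or connection to read from.
#' @param output path or connection to write to.
#' @param target output convention, `"lf"` or `"crlf"`.
#' @param chunk_size bytes per read (exposed for testing boundary
#'   handling).
#' @return number of bytes written, invisibly.
#' @export
normalize_eol_file <- function(input, output, target = c("lf", "crlf"),
                               chunk_size = 65536L) {
  target <- match.arg(target)
  stopifnot(chunk_size >= 2L)
  in_con <- if (inherits(input, "connection")) input else file(input, "rb")
  if (!isOpen(in_con)) open(in_con, "rb")
  out_con <- if (inherits(output, "connection")) output else file(output, "wb")
  if (!isOpen(out_con)) open(out_con, "wb")
  on.exit({
    if (!inherits(input, "connection")) close(in_con)
    if (!inherits(output, "connection")) close(out_con)
  })
  written <- 0L
  held <- raw(0)                # a trailing CR awaiting its possible LF
  repeat {
    chunk <- readBin(in_con, "raw", n = chunk_size)
    eof <- length(chunk) < chunk_size
    chunk <- c(held, chunk)
    held <- raw(0)
    if (!eof && length(chunk) && chunk[length(chunk)] == as.raw(13L)) {
      held <- chunk[length(chunk)]
      chunk <- chunk[-length(chunk)]
    }
    if (length(chunk)) {
      out <- normalize_eol(chunk, target)
      writeBin(out, out_con)
      written <- written + length(out)
    }
    if (eof) {
      if (length(held)) {       # file ended in a bare CR
        out <- normalize_eol(held, target)
        writeBin(out, out_con)
        written <- written + length(out)
      }
      break
    }
  }
  invisible(written)
}
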