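# Wrapping, per-field processing, and whole-document streaming.

test_that("wrap_field emits valid formula strings", {
  expect_equal(wrap_field("SEPT1"), '="SEPT1"')
  expect_equal(wrap_field(""), '=""')
  expect_equal(wrap_field('he said "hi"'), '="he said ""hi"""')
  # unwrap inverts wrap for arbitrary clean bodies
  set.seed(5)
  bodies <- clean_field(random_strings(500))
  expect_identical(unwrap_field(wrap_field(bodies)), bodies)
})

test_that("process_field cleans, decides and wraps", {
  expect_equal(process_field("SEPT7"), '="SEPT7"')
  expect_equal(process_field("123456"), "123456")
  expect_equal(process_field('="00123456"'), '="00123456"')
  # double application equals single application
  set.seed(17)
  x <- c(validation_table()$field, random_strings(500))
  once <- process_field(x)
  expect_identical(process_field(once), once)
  # and under every flag combination
  for (cfg in list(rule_config(paranoid = TRUE), rule_config(dates = FALSE),
                   rule_config(sci = FALSE, zeroes = FALSE))) {
    once <- process_field(x, cfg)
    expect_identical(process_field(once, cfg), once)
  }
})

test_that("process_lines preserves document structure exactly", {
  res <- process_lines("SEPT7\t123456", warn_ragged = FALSE)
  expect_equal(res$lines, '="SEPT7"\t123456')
  expect_equal(res$stats$escaped, 1L)

  empty <- process_lines(character(0))
  expect_equal(empty$lines, character(0))
  expect_equal(empty$stats$fields, 0L)

  expect_message(process_lines(c("a\tb\tc", "d\te")), "ragged")

  set.seed(29)
  lines <- random_tsv_lines(300)
  out <- process_lines(lines, warn_ragged = FALSE)$lines
  expect_equal(length(out), length(lines))
  ntab <- function(v) nchar(v) - nchar(gsub("\t", "", v, fixed = TRUE))
  expect_equal(ntab(out), ntab(lines))
  # trailing empty fields survive
  res2 <- process_lines(c("a\t\t", "\tb"), warn_ragged = FALSE)
  expect_equal(res2$lines, c("a\t\t", "\tb"))
  expect_equal(res2$stats$fields, 5L)
})

test_that("stats are consistent with the decisions", {
  set.seed(37)
  lines <- random_tsv_lines(200)
  res <- process_lines(lines, warn_ragged = FALSE)
  s <- res$stats
  expect_equal(s$escaped, sum(s$by_rule))
  expect_lte(s$escaped, s$fields)
  expect_equal(s$lines, length(lines))
  wrapped <- sum(grepl('^="', unlist(strsplit(res$lines, "\t", fixed = TRUE))))
  expect_equal(wrapped, s$escaped)
})

test_that("unwrapping the output recovers the cleaned input", {
  set.seed(41)
  lines <- c(random_tsv_lines(200),
             paste(validation_table()$field, collapse = "\t"))
  out <- process_lines(lines, warn_ragged = FALSE)$lines
  in_fields <- unlist(strsplit(paste0(lines, "\ta"), "\t", fixed = TRUE))
  out_fields <- unlist(strsplit(paste0(out, "\ta"), "\t", fixed = TRUE))
  expect_identical(unwrap_field(out_fields), clean_field(in_fields))
})

test_that("escape_file handles BOM, CR-only endings and round-trips", {
  tf_in <- tempfile()
  tf_out <- tempfile()
  tf_out2 <- tempfile()
  on.exit(unlink(c(tf_in, tf_out, tf_out2)))
  writeBin(charToRaw("\xef\xbb\xbfSEPT7\t123456\r00123456\tTP53\r"), tf_in)
  stats <- escape_file(tf_in, tf_out)
  expect_equal(readLines(tf_out),
               c('="SEPT7"\t123456', '="00123456"\tTP53'))
  expect_equal(stats$escaped, 2L)
  expect_equal(unname(stats$by_rule[c("leading_zero", "date_like")]),
               c(1L, 1L))
  # byte-identical on the second pass
  escape_file(tf_out, tf_out2)
  expect_identical(readBin(tf_out, "raw", 1000), readBin(tf_out2, "raw", 1000))

  # no trailing terminator in -> none out; crlf option honoured
  writeBin(charToRaw("SEPT7\tx"), tf_in)
  escape_file(tf_in, tf_out, rule_config(eol = "crlf"))
  expect_identical(rawToChar(readBin(tf_out, "raw", 100)), '="SEPT7"\tx')

  # undecodable bytes name the line
  writeBin(c(charToRaw("ok\n"), as.raw(c(0xff, 0xfe)), charToRaw("x\n")), tf_in)
  expect_error(escape_file(tf_in, tf_out), "line 2")
})
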