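# Escape-decision rules: the number grammar, the numeric rules, the
# date/time grammar, and the full branch structure.

test_that("parse_number recognizes the numeric grammar", {
  p <- parse_number(c("2610100E13", "2E4", "1 A", "-1.5e-3", ".5", "1.",
                      "1,234", "+7", "1E05", "", "abc", "1.2.3"))
  expect_equal(p$is_number,
               c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                 FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(p$int_digits[1], "2610100")
  expect_equal(p$exp_digits[1], "13")
  expect_equal(p$mantissa_int_len[1], 7L)
  expect_equal(p$mantissa_int_len[2], 1L)
  expect_equal(p$mantissa_int_len[5], 0L)   # ".5"
  expect_equal(p$sign[4], "-")
  expect_equal(p$exp_sign[4], "-")
})

test_that("parsed number parts reassemble to the original text", {
  reassemble <- function(p) {
    paste0(p$sign, p$int_digits,
           ifelse(p$has_point, ".", ""), p$frac_digits,
           p$exp_char, p$exp_sign, p$exp_digits)
  }
  set.seed(11)
  fixed <- c("2610100E13", "-1.5e-3", ".5", "1.", "+0.00", "1E05",
             "007", "3e46", "12E3", "0")
  rand <- random_strings(2000, max_len = 10L,
                         alphabet = c(0:9, ".", "e", "E", "+", "-"))
  x <- c(fixed, rand)
  p <- parse_number(x)
  num <- p$is_number
  expect_true(any(num))
  expect_identical(reassemble(p[num, ]), x[num])
})

test_that("numeric rules fire in the documented order", {
  cases <- data.frame(
    field = c("00123456", "11E9", "3e46", "2E4",
              "52070900777217100409406332354780", "123456789012",
              "1E05", "0.5", "00E13", "123456789012.5", "123456"),
    rule = c("leading_zero", "sci_mantissa", "none", "none",
             "long_integer", "long_integer",
             "none",          # exponent zeroes are not integer-part zeroes
             "none",          # single leading zero before the point
             "leading_zero",  # precedence: leading zero beats sci notation
             "long_integer",  # >11 digits before the decimal, point or not
             "none"),
    stringsAsFactors = FALSE
  )
  d <- number_needs_escape(parse_number(cases$field))
  expect_equal(d$rule, cases$rule)
  expect_equal(d$escape, cases$rule != "none")
})

test_that("flags disable their rule class", {
  no_zero <- rule_config(zeroes = FALSE)
  expect_false(decide_escape("00123456", no_zero)$escape)
  no_sci <- rule_config(sci = FALSE)
  expect_false(decide_escape("11E9", no_sci)$escape)
  expect_false(decide_escape("1234567890123456789", no_sci)$escape)
  no_dates <- rule_config(dates = FALSE)
  expect_false(decide_escape("SEPT7", no_dates)$escape)
  expect_false(decide_escape("1 A", no_dates)$escape)
  # unrelated rules unaffected
  expect_true(decide_escape("SEPT7", no_sci)$escape)
  expect_true(decide_escape("00123456", no_dates)$escape)
})

test_that("date/time grammar matches the documented cases", {
  expect_equal(
    looks_like_date_or_time(c("SEPT7", "1/3", "1 A", "SEPTIN7",
                              "MARCH1", "DEC1", "OCT4", "7SEP",
                              "sep-7-2017", "1/3/17", "2017/1/3",
                              "12:30", "23:59", "3:15:30", "1 P", "11 am",
                              "13/25", "32/1", "MARCHF8", "13 A",
                              "24:00", "12:60", "MAY", "TP53")),
    c("date_like", "date_like", "time_like", "none",
      "date_like", "date_like", "date_like", "date_like",
      "date_like", "date_like", "date_like",
      "time_like", "time_like", "time_like", "time_like", "time_like",
      "none", "none", "none", "none",
      "none", "none", "none", "none")
  )
})

test_that("decide_escape implements the full branch structure", {
  d <- decide_escape(c("++ stain intensity", "TP53", "++", "-1", "+1.5",
                       "'note", "=SUM(A1)", ""))
  expect_equal(d$rule, c("leading_plusminus", "none", "none", "none",
                         "none", "leading_quote", "leading_equals", "none"))
  expect_equal(d$escape, d$rule != "none")

  p <- rule_config(paranoid = TRUE)
  # paranoid is an else-branch: every non-empty non-number, dates included
  dp <- decide_escape(c("TP53", "123456", "SEPT7", "", "++"), p)
  expect_equal(dp$rule, c("paranoid", "none", "paranoid", "none",
                          "paranoid"))
})

test_that("the validation table decisions all match", {
  tbl <- validation_table()
  d <- decide_escape(tbl$field)
  expect_equal(d$rule, tbl$tag)
  expect_equal(d$escape, tbl$escape)
  # under paranoid every non-number none-row is escaped as paranoid
  dp <- decide_escape(tbl$field, rule_config(paranoid = TRUE))
  nonnum_none <- tbl$tag == "none" & tbl$field != "" &
    !parse_number(tbl$field)$is_number
  expect_true(all(dp$rule[nonnum_none] == "paranoid"))
  expect_gte(sum(nonnum_none), 5L)
})

test_that("turning flags off is monotone; paranoid only adds escapes", {
  set.seed(23)
  x <- c(validation_table()$field, random_strings(500))
  base <- decide_escape(x)
  for (cfg in list(rule_config(dates = FALSE), rule_config(sci = FALSE),
                   rule_config(zeroes = FALSE))) {
    relaxed <- decide_escape(x, cfg)
    # switching a class off never escapes a field the default passed
    expect_false(any(relaxed$escape & !base$escape))
  }
  par <- decide_escape(x, rule_config(paranoid = TRUE))
  expect_false(any(base$escape & !par$escape))
})

test_that("numbers never reach the date/time branch", {
  set.seed(31)
  x <- c(validation_table()$field, random_strings(500))
  d <- decide_escape(x)
  num <- parse_number(x)$is_number
  expect_false(any(d$rule[num] %in% c("date_like", "time_like")))
})
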