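test_that("split_fields follows the dialect's delimiter semantics", {
  expect_equal(split_fields("chr1\t250000\t250100"),
               c("chr1", "250000", "250100"))
  # first line of the published fuzzer-generated file: 4 fields
  expect_length(split_fields(table1_file2_lines()[1]), 4L)

  expect_equal(split_fields("a b\tc", bed_dialect("tabs")), c("a b", "c"))
  expect_equal(split_fields("a b\tc", bed_dialect("flexible")),
               c("a", "b", "c"))
  # tabs-only preserves empty fields; flexible collapses runs
  expect_equal(split_fields("a\t\tb", bed_dialect("tabs")), c("a", "", "b"))
  expect_equal(split_fields("a\t\tb", bed_dialect("flexible")), c("a", "b"))
  expect_length(split_fields("", bed_dialect("tabs")), 0L)
})

valid5 <- c("chr1", "250000", "250100", "feat", "500")

test_that("validate_line applies the closed rule table", {
  cases <- list(
    # fields, n, expected error codes (empty = clean line)
    list(c("chr1", "250000", "250100"), 3, character(0)),
    list(c("chr1", "-1", "250100"), 3, "NEGATIVE_COORD"),
    list(c("chr1", "25O000", "250100"), 3, "COORD_FORMAT"),
    list(c("chr1", "250200", "250100"), 3, "COORD_ORDER"),
    list(c("chr1", "250100", "250100"), 3, character(0)),  # zero-length
    list(c("chr;1", "250000", "250100"), 3, "CHROM_FORMAT"),
    list(c(valid5[1:3], strrep("N", 256), "500"), 5, "NAME_FORMAT"),
    list(replace(valid5, 5, "1001"), 5, "SCORE_RANGE"),
    list(replace(valid5, 5, "-1"), 5, "SCORE_RANGE"),
    list(replace(valid5, 5, "0.5"), 5, "SCORE_FORMAT"),
    list(c(valid5, "."), 6, character(0)),
    list(c(valid5, "*"), 6, "STRAND_SYMBOL"),
    list(c(valid5, "+", "249000"), 7, "THICK_OUT_OF_BOUNDS"),
    list(c(valid5, "+", "250000", "250200"), 8, "THICK_OUT_OF_BOUNDS"),
    list(c(valid5, "+", "250000", "250100", "0"), 9, character(0)),
    list(c(valid5, "+", "250000", "250100", "255,0,0"), 9, character(0)),
    list(c(valid5, "+", "250000", "250100", "256,0,0"), 9, "RGB_FORMAT"),
    list(c(valid5, "+", "250000", "250100", "0,0"), 9, "RGB_FORMAT"),
    list(c(valid5, "+", "250000", "250100", "0", "0", "100", "0"), 12,
         "BLOCK_COUNT"),
    list(c(valid5, "+", "250000", "250100", "0", "1", "100,50", "0"), 12,
         "BLOCK_LIST_LENGTH"),
    list(c(valid5, "+", "250000", "250100", "0", "1", "0", "0"), 12,
         "BLOCK_LIST_FORMAT"),
    list(c(valid5, "+", "250000", "250100", "0", "1", "50", "0"), 12,
         "BLOCK_STRUCTURE"),  # last block must end at chromEnd - chromStart
    list(c(valid5, "+", "250000", "250100", "0", "1", "100", "10"), 12,
         "BLOCK_STRUCTURE"),  # first block must start at 0
    list(c(valid5, "+", "250000", "250100", "0", "2", "50,50", "0,40"), 12,
         "BLOCK_STRUCTURE"),  # overlap
    list(c(valid5, "+", "250000", "250100", "0", "2", "50,50", "0,50"), 12,
         character(0)),
    list(c(valid5, "+", "250000", "250100", "0", "1", "100,", "0,"), 12,
         character(0))  # one trailing comma tolerated
  )
  for (case in cases) {
    issues <- validate_line(case[[1]], bed_variant(case[[2]]))
    errs <- issues$code[issues$severity == "error"]
    label <- paste(case[[1]], collapse = "|")
    if (length(case[[3]]) == 0L) {
      expect_length(errs, 0L)
    } else {
      expect_true(all(case[[3]] %in% errs),
                  label = sprintf("%s -> %s (got %s)", label,
                                  paste(case[[3]], collapse = ","),
                                  paste(errs, collapse = ",")))
    }
  }
})

test_that("score validity agrees with the brute-force range oracle", {
  for (s in -5:1005) {
    issues <- validate_line(replace(valid5, 5, as.character(s)),
                            bed_variant(5))
    oracle_valid <- (s >= 0 && s <= 1000)
    expect_equal(nrow(issues) == 0L, oracle_valid,
                 label = sprintf("score %d", s))
  }
})

test_that("coordinate comparisons stay exact beyond double precision", {
  big <- "9223372036854775807"  # 2^63 - 1
  expect_equal(nrow(validate_line(c("chr1", big, big), bed_variant(3))), 0L)
  # one less must order below, which doubles cannot distinguish
  issues <- validate_line(c("chr1", big, "9223372036854775806"),
                          bed_variant(3))
  expect_true("COORD_ORDER" %in% issues$code)
})

test_that("validate_file fixes the variant and handles blanks and encodings", {
  ok <- write_bed(c("chr1\t250000\t250100", "", "chr2\t250000\t250100"))
  rep <- validate_file(ok)
  expect_true(rep$valid)
  expect_equal(rep$n_records, 2L)
  expect_equal(rep$n_blank, 1L)
  expect_equal(format(rep$variant), "BED3")

  # a fully space-delimited file is valid under the flexible dialect
  sp <- write_bed(c("chr1 250000 250100", "chr2 250000 250100"))
  expect_true(validate_file(sp, bed_dialect("flexible"))$valid)
  expect_false(validate_file(sp, bed_dialect("tabs"))$valid)

  # empty file: vacuously valid, zero records
  empty <- write_bed(character(0))
  rep <- validate_file(empty)
  expect_true(rep$valid)
  expect_equal(rep$n_records, 0L)

  # ten fields in strict mode
  ten <- write_bed(paste(c("chr1", "250000", "250100", "x", "500", "+",
                           "250000", "250100", "0", "1"), collapse = "\t"))
  rep <- validate_file(ten)
  expect_false(rep$valid)
  expect_true("PROHIBITED_VARIANT" %in% rep$issues$code)
  # ...but the same file is fine as a declared custom BED9+1
  expect_true(validate_file(ten, mode = "custom", declared_n = 9)$valid)

  # mixed field counts within one file
  mixed <- write_bed(c("chr1\t250000\t250100", "chr1\t250000\t250100\tx"))
  rep <- validate_file(mixed)
  expect_false(rep$valid)
  expect_true("MIXED_FIELD_COUNT" %in% rep$issues$code)

  # undecodable bytes
  enc <- write_bed(paste0("chr", rawToChar(as.raw(0xFF)), "\t250000\t250100"))
  rep <- validate_file(enc)
  expect_false(rep$valid)
  expect_true("ENCODING" %in% rep$issues$code)

  # carriage returns warn but do not invalidate
  crlf <- write_bed("chr1\t250000\t250100\r")
  rep <- validate_file(crlf)
  expect_true(rep$valid)
  expect_true("CRLF" %in% rep$issues$code)

  expect_equal(error_code(validate_file(tempfile())), "IO_ERROR")
})

test_that("comment handling is explicit dialect state", {
  lines <- c("#I", "chr12\t632184\t753365\tVx6")
  expect_false(validate_text(lines)$valid)  # '#I' is a malformed data line
  skip_dialect <- bed_dialect(skip_comments = TRUE)
  expect_true(validate_text(lines, skip_dialect)$valid)
})

test_that("failing rules are inherited by every wider variant", {
  # monotone rule inheritance: a base case failing on field k keeps failing
  # after expansion, because filler only appends later fields
  bases <- list(
    bed_test_case("neg", 3, "fail", "chr7\t-250000\t250150"),
    bed_test_case("score", 5, "fail", "chr7\t250000\t250150\tx\t2000"),
    bed_test_case("strand", 6, "fail", "chr7\t250000\t250150\tx\t500\t*")
  )
  for (base in bases) {
    for (n in seq(base$n, 12)) {
      expanded <- expand_case(base, n)
      expect_false(validate_text(expanded$content)$valid,
                   label = sprintf("%s at BED%d", base$id, n))
    }
  }
})

test_that("the validator CLI mirrors the report and sets exit status", {
  good <- write_bed("chr1\t250000\t250100")
  bad <- write_bed("chr1\t-5\t250100")
  expect_equal(suppressMessages(bedcert_main(c("validate", good))), 0L)
  expect_equal(suppressMessages(bedcert_main(c("validate", bad))), 1L)
  expect_equal(suppressMessages(bedcert_main(c("validate", tempfile()))), 2L)
  msgs <- capture.output(bedcert_main(c("validate", bad)), type = "message")
  expect_true(any(grepl("NEGATIVE_COORD", msgs)))
  json <- capture.output(suppressMessages(
    bedcert_main(c("validate", good, "--json"))))
  parsed <- jsonlite::fromJSON(paste(json, collapse = ""))
  expect_true(parsed$valid)
  expect_equal(parsed$variant, "BED3")
})
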