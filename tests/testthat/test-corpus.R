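test_that("the corpus has 92 uniquely named cases with the stated layout", {
  dir <- cached_corpus_dir()
  manifest <- read_manifest(dir)
  expect_equal(nrow(manifest), 92L)
  expect_false(anyDuplicated(manifest$id) > 0)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  expect_true(all(grepl("^bed\\d+/expected_(pass|fail)/", manifest$file)))

  smry <- corpus_summary(manifest)
  expect_equal(sum(smry$total), 92L)
  expect_setequal(smry$variant, 3:12)
  # the named cases the corpus must contain
  expect_true(all(c("bed3/02-negative-start",
                    "bed3/other-fully_space_delimited",
                    "bed3/other-space_between_lines") %in% manifest$id))
})

test_that("BED10 and BED11 have zero expected-pass cases", {
  manifest <- read_manifest(cached_corpus_dir())
  for (n in c(10, 11)) {
    sub <- manifest[manifest$variant == n, ]
    expect_gt(nrow(sub), 0)
    expect_true(all(sub$expectation == "fail"))
  }
})

test_that("all corpus coordinates lie within the stated interval range", {
  dir <- cached_corpus_dir()
  manifest <- read_manifest(dir)
  coord_cols <- c(2, 3, 7, 8)
  for (i in seq_len(nrow(manifest))) {
    for (line in readLines(file.path(dir, manifest$file[i]), warn = FALSE)) {
      if (!validUTF8(line) || grepl("^[ \t]*$", line)) next
      fields <- split_fields(line, bed_dialect("flexible"))
      toks <- fields[coord_cols[coord_cols <= length(fields)]]
      vals <- suppressWarnings(as.numeric(toks))
      vals <- vals[!is.na(vals)]
      expect_true(all(vals <= 260000),
                  label = sprintf("%s: %s", manifest$id[i], line))
      if (manifest$expectation[i] == "pass") {
        expect_true(all(vals >= 250000), label = manifest$id[i])
      }
    }
  }
})

test_that("generation is deterministic: two runs are byte-identical", {
  d1 <- file.path(tempdir(), "corpus-det-1")
  d2 <- file.path(tempdir(), "corpus-det-2")
  generate_corpus(d1)
  generate_corpus(d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("every case behaves as labelled under the in-process validator", {
  dir <- cached_corpus_dir()
  manifest <- read_manifest(dir)
  for (i in seq_len(nrow(manifest))) {
    dialect <- bed_dialect(
      if (manifest$dialect[i] == "tabs") "tabs" else "flexible")
    rep <- validate_file(file.path(dir, manifest$file[i]), dialect)
    expect_equal(rep$valid, manifest$expectation[i] == "pass",
                 label = manifest$id[i])
  }
})

test_that("the expected-fail cases cover every validator rule code", {
  dir <- cached_corpus_dir()
  manifest <- read_manifest(dir)
  seen <- character(0)
  for (i in which(manifest$expectation == "fail")) {
    dialect <- bed_dialect(
      if (manifest$dialect[i] == "tabs") "tabs" else "flexible")
    rep <- validate_file(file.path(dir, manifest$file[i]), dialect)
    seen <- union(seen, rep$issues$code[rep$issues$severity == "error"])
  }
  missed <- setdiff(setdiff(rule_codes(), "BLANK_LINE"), seen)
  expect_length(missed, 0L)
})

test_that("expand_case inherits expectations and flips BED10/11 to fail", {
  cases <- corpus_cases()
  base_fail <- cases[["bed5/06-score-too-large"]]
  expect_equal(expand_case(base_fail, 12)$expectation, "fail")

  base_pass <- cases[["bed3/01-valid"]]
  expect_equal(expand_case(base_pass, 9)$expectation, "pass")
  expect_equal(expand_case(base_pass, 11)$expectation, "fail")
  # identity expansion
  expect_identical(expand_case(base_pass, 3), base_pass)
  # downward expansion is a contract violation
  expect_equal(error_code(expand_case(base_fail, 4)), "INVALID_EXPANSION")
  # expanded pass content is itself valid
  expect_true(validate_text(expand_case(base_pass, 12)$content)$valid)
})

test_that("minimal fixtures are deterministic and span the corpus range", {
  d1 <- file.path(tempdir(), "fix-1")
  d2 <- file.path(tempdir(), "fix-2")
  f1 <- make_minimal_fixtures(d1)
  f2 <- make_minimal_fixtures(d2)
  expect_identical(readBin(f1[["fasta"]], "raw", 5e6),
                   readBin(f2[["fasta"]], "raw", 5e6))

  fasta <- readLines(f1[["fasta"]], warn = FALSE)
  headers <- grep("^>", fasta, value = TRUE)
  sizes <- read.table(f1[["sizes"]], sep = "\t",
                      col.names = c("chrom", "size"))
  expect_equal(length(headers), nrow(sizes))
  expect_true(all(sizes$size >= 260000))
  # sequence lengths match the sizes file
  lens <- tapply(nchar(fasta[!grepl("^>", fasta)]),
                 cumsum(grepl("^>", fasta))[!grepl("^>", fasta)], sum)
  expect_equal(unname(as.numeric(lens)), sizes$size)
  # every chromosome used by the corpus is covered
  manifest <- read_manifest(cached_corpus_dir())
  pass <- manifest[manifest$expectation == "pass", ]
  chroms <- unique(unlist(lapply(file.path(cached_corpus_dir(), pass$file),
    function(p) {
      vapply(readLines(p, warn = FALSE), function(l) {
        if (grepl("^[ \t]*$", l)) NA_character_
        else split_fields(l, bed_dialect("flexible"))[1]
      }, character(1))
    })))
  expect_true(all(stats::na.omit(chroms) %in% sizes$chrom))
  unlink(c(d1, d2), recursive = TRUE)
})
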