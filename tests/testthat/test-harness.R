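write_config <- function(lines) {
  path <- tempfile(fileext = ".yaml")
  writeLines(lines, path)
  path
}

test_that("load_config parses the three-section schema and substitutes settings", {
  path <- write_config(c(
    "settings:",
    "  GENOME: /data/mock.fa",
    "tools:",
    "  toolA: mytool --in FILE",
    "  toolB: other -g GENOME FILE",
    "conda-environment:",
    "  toolA: envA"))
  cfg <- load_config(path)
  expect_length(cfg$tools, 2L)
  expect_equal(cfg$tools$toolA$template, "mytool --in FILE")
  expect_equal(cfg$tools$toolB$template, "other -g /data/mock.fa FILE")
  expect_equal(cfg$tools$toolA$environment, "envA")
  expect_null(cfg$tools$toolB$environment)
})

test_that("config errors are coded", {
  no_tools <- write_config(c("settings:", "  A: b"))
  expect_equal(error_code(load_config(no_tools)), "CONFIG_ERROR")
  no_file <- write_config(c("tools:", "  t: mytool --version"))
  expect_equal(error_code(load_config(no_file)), "CONFIG_ERROR")
  two_files <- write_config(c("tools:", "  t: cmp FILE FILE"))
  expect_equal(error_code(load_config(two_files)), "CONFIG_ERROR")
  expect_equal(error_code(load_config(tempfile())), "IO_ERROR")
})

test_that("classification is a pure function of the captured outcome", {
  oc <- function(status, stdout = "", stderr = "", timed_out = FALSE) {
    structure(list(status = status, stdout = stdout, stderr = stderr,
                   timed_out = timed_out), class = "bed_tool_outcome")
  }
  expect_equal(classify_outcome(oc(0L)), "pass")
  expect_equal(classify_outcome(oc(1L)), "fail")
  expect_equal(
    classify_outcome(oc(1L, stderr = paste(
      "Error: line number 1 of file 2.bed has 4 fields, but 0 were",
      "expected"))),
    "fail")
  # a warning on a zero exit status still counts as a failure
  expect_equal(classify_outcome(oc(0L, stderr = "Warning: skipped line 3")),
               "fail")
  expect_equal(classify_outcome(oc(0L, stdout = "WARNING in caps")), "fail")
  expect_equal(classify_outcome(oc(0L, timed_out = TRUE)), "fail")
  # patterns are configuration: with none, output text is ignored
  expect_equal(classify_outcome(oc(0L, stderr = "Error!"), character(0)),
               "pass")
  # purity: identical tuples classify identically
  expect_equal(classify_outcome(oc(0L, "x", "y")),
               classify_outcome(oc(0L, "x", "y")))
})

test_that("run_tool_on_case captures status and streams separately", {
  bed <- write_bed("chr1\t250000\t250100")
  pass <- run_tool_on_case(mock_tool("always-pass"), bed)
  expect_equal(pass$status, 0L)
  expect_equal(pass$stdout, "")
  expect_equal(pass$stderr, "")
  expect_equal(pass$classified, "pass")

  fail <- run_tool_on_case(mock_tool("always-fail"), bed)
  expect_equal(fail$status, 1L)
  expect_match(fail$stderr, "^Error")
  expect_equal(fail$classified, "fail")

  warn <- run_tool_on_case(mock_tool("warn"), bed)
  expect_equal(warn$status, 0L)
  expect_equal(warn$classified, "fail")

  silent <- run_tool_on_case(mock_tool("silent-fail"), bed)
  expect_equal(silent$classified, "fail")
})

test_that("a run past the timeout is classified fail", {
  bed <- write_bed("chr1\t250000\t250100")
  sleepy <- mock_tool("sleepy", sleep = 30)
  t0 <- Sys.time()
  out <- run_tool_on_case(sleepy, bed, timeout = 1)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 10)
  expect_true(out$timed_out)
  expect_equal(out$classified, "fail")
})

test_that("a missing executable is a coded, recoverable error", {
  tool <- tool_spec("ghost", "definitely-not-a-real-tool-xyz FILE")
  bed <- write_bed("chr1\t250000\t250100")
  # sh reports the missing command on stderr with non-zero status
  out <- run_tool_on_case(tool, bed)
  expect_equal(out$classified, "fail")
})

test_that("mock tools score exactly the expected-pass/fail fractions", {
  dir <- cached_corpus_dir()
  manifest <- read_manifest(dir)
  smry <- corpus_summary(manifest)

  res_pass <- evaluate_tool(mock_tool("always-pass"), dir, manifest)
  expect_equal(res_pass$behaved_as_expected,
               manifest$expectation == "pass")
  sc <- score_by_variant(res_pass)
  expect_equal(sc$proportion, smry$n_pass / smry$total)

  res_fail <- evaluate_tool(mock_tool("always-fail"), dir, manifest)
  expect_equal(res_fail$behaved_as_expected,
               manifest$expectation == "fail")
  sc <- score_by_variant(res_fail)
  expect_equal(sc$proportion, smry$n_fail / smry$total)

  # scores are permutation-invariant over case order
  shuffled <- res_pass[sample(nrow(res_pass)), ]
  expect_equal(score_by_variant(shuffled), score_by_variant(res_pass))
})
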