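# Run external command-line tools over the corpus and score how often they
# behave as expected: accept expected-pass files silently (zero exit, no
# error or warning output) and reject expected-fail files (non-zero exit or
# an error/warning message).

DEFAULT_PATTERNS <- c("error", "warning", "exception", "traceback")

#' Describe one tool under test
#'
#' @param name tool label.
#' @param template shell command template containing the literal placeholder
#'   `FILE` exactly once; it is replaced by the path of each test file. A
#'   template may also contain `DIALECT`, replaced by the case's dialect
#'   (`flexible` or `tabs`) from the corpus manifest -- used by the
#'   package's own validator CLI.
#' @param environment optional isolated-runtime label (e.g. a conda
#'   environment name). If a `conda` executable is on the path the command
#'   is run under `conda run -n <label>`; otherwise the label is ignored
#'   with a notice.
#' @param patterns character vector of case-insensitive regular expressions
#'   scanned against captured output; any match classifies the run as a
#'   failure even on exit status 0.
#' @return object of class `bed_tool_spec`.
#'   Errors: `CONFIG_ERROR` unless `template` contains `FILE` exactly once.
#' @export
tool_spec <- function(name, template, environment = NULL,
                      patterns = DEFAULT_PATTERNS) {
  n_file <- lengths(regmatches(template, gregexpr("FILE", template, fixed = TRUE)))
  if (n_file != 1L) {
    bedcert_stop("CONFIG_ERROR",
                 sprintf("tool '%s': template must contain FILE exactly once (found %d)",
                         name, n_file))
  }
  structure(list(name = name, template = template,
                 environment = environment, patterns = patterns),
            class = "bed_tool_spec")
}

#' @export
print.bed_tool_spec <- function(x, ...) {
  cat(sprintf("<tool %s> %s\n", x$name, x$template))
  invisible(x)
}

#' Load a harness configuration file
#'
#' The YAML file has three sections: `settings` (named locations inserted
#' into command lines), `tools` (map of tool name to invocation template
#' containing `FILE`) and `conda-environment` (map of tool name to
#' environment label). An optional `patterns` section overrides the default
#' error/warning patterns per tool. Every uppercase settings key is
#' substituted into the templates, so a template may reference e.g. `GENOME`
#' when settings defines `GENOME: /path/to.fa`.
#'
#' @param path path to the YAML configuration.
#' @return list with elements `tools` (list of [tool_spec()]) and `settings`
#'   (named list).
#'   Errors: `CONFIG_ERROR` for a missing `tools` section or a template
#'   without `FILE`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    bedcert_stop("IO_ERROR", sprintf("cannot read config '%s'", path))
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$tools) || length(cfg$tools) == 0L) {
    bedcert_stop("CONFIG_ERROR", "config has no 'tools' section")
  }
  settings <- cfg$settings %||% list()
  envs <- cfg[["conda-environment"]] %||% list()
  patterns <- cfg$patterns %||% list()

  tools <- lapply(names(cfg$tools), function(nm) {
    template <- cfg$tools[[nm]]
    for (key in names(settings)) {
      template <- gsub(key, as.character(settings[[key]]), template,
                       fixed = TRUE)
    }
    tool_spec(nm, template,
              environment = envs[[nm]],
              patterns = if (!is.null(patterns[[nm]]))
                as.character(patterns[[nm]]) else DEFAULT_PATTERNS)
  })
  names(tools) <- names(cfg$tools)
  list(tools = tools, settings = settings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

activation_prefix <- function(environment) {
  if (is.null(environment) || !nzchar(environment)) return("")
  if (nzchar(Sys.which("conda"))) {
    sprintf("conda run -n %s ", environment)
  } else {
    message(sprintf("no environment manager found; ignoring environment '%s'",
                    environment))
    ""
  }
}

#' Run one tool on one test file
#'
#' The command is the tool's template with `FILE` replaced by the file path
#' (and `DIALECT` by `dialect`, when present), run through `sh -c` with
#' standard output and error captured separately.
#'
#' @param tool a [tool_spec()].
#' @param file path to the BED test file.
#' @param dialect dialect string substituted for a `DIALECT` placeholder.
#' @param timeout seconds before the child is killed; a timed-out run
#'   classifies as fail.
#' @return object of class `bed_tool_outcome`: list with `file`, `status`,
#'   `stdout`, `stderr`, `timed_out`, `classified` (`"pass"` or `"fail"`).
#'   Errors: `TOOL_MISSING` when the command cannot be spawned at all.
#' @export
run_tool_on_case <- function(tool, file, dialect = "flexible", timeout = 60) {
  stopifnot(inherits(tool, "bed_tool_spec"))
  cmd <- gsub("FILE", file, tool$template, fixed = TRUE)
  cmd <- gsub("DIALECT", dialect, cmd, fixed = TRUE)
  cmd <- paste0(activation_prefix(tool$environment), cmd)
  res <- tryCatch(
    processx::run("sh", c("-c", cmd), error_on_status = FALSE,
                  timeout = timeout),
    error = function(e) {
      bedcert_stop("TOOL_MISSING",
                   sprintf("tool '%s' could not be run: %s", tool$name,
                           conditionMessage(e)))
    }
  )
  outcome <- structure(
    list(file = file, status = res$status, stdout = res$stdout,
         stderr = res$stderr, timed_out = isTRUE(res$timeout),
         classified = NA_character_),
    class = "bed_tool_outcome")
  outcome$classified <- classify_outcome(outcome, tool$patterns)
  outcome
}

#' Classify a captured tool run as pass or fail
#'
#' A run passes iff the exit status is 0, it did not time out, and none of
#' the patterns match the captured standard output or error
#' (case-insensitively, as substrings/regular expressions). A warning
#' message therefore counts as a failure even with a zero exit status.
#'
#' @param outcome a `bed_tool_outcome` (the `classified` field is ignored).
#' @param patterns character vector of case-insensitive patterns.
#' @return `"pass"` or `"fail"`.
#' @examples
#' o <- structure(list(status = 0L, stdout = "", stderr = "",
#'                     timed_out = FALSE), class = "bed_tool_outcome")
#' classify_outcome(o)  # "pass"
#' @export
classify_outcome <- function(outcome, patterns = DEFAULT_PATTERNS) {
  if (isTRUE(outcome$timed_out)) return("fail")
  if (is.na(outcome$status) || outcome$status != 0L) return("fail")
  text <- c(outcome$stdout, outcome$stderr)
  for (p in patterns) {
    if (any(grepl(p, text, ignore.case = TRUE))) return("fail")
  }
  "pass"
}

#' Run one tool over the whole corpus
#'
#' Visits every manifest case, runs the tool, classifies the outcome and
#' records whether the tool behaved as expected: classified pass on an
#' expected-pass case or classified fail on an expected-fail case.
#'
#' @param tool a [tool_spec()].
#' @param corpus_dir directory written by [generate_corpus()].
#' @param manifest corpus manifest; read from `corpus_dir` by default.
#' @param timeout per-case timeout in seconds.
#' @return data frame with one row per case: `tool`, `case`, `variant`,
#'   `expectation`, `classified`, `behaved_as_expected`.
#' @export
evaluate_tool <- function(tool, corpus_dir, manifest = NULL, timeout = 60) {
  if (is.null(manifest)) manifest <- read_manifest(corpus_dir)
  dialect <- if ("dialect" %in% names(manifest)) manifest$dialect
             else rep("flexible", nrow(manifest))
  classified <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    outcome <- run_tool_on_case(tool, file.path(corpus_dir, manifest$file[i]),
                                dialect = dialect[i], timeout = timeout)
    classified[i] <- outcome$classified
  }
  data.frame(tool = tool$name, case = manifest$id,
             variant = manifest$variant, expectation = manifest$expectation,
             classified = classified,
             behaved_as_expected = classified == manifest$expectation,
             stringsAsFactors = FALSE)
}

#' Per-variant scores for one tool
#'
#' The score for a variant is the number of tests that behaved as expected
#' divided by the number of tests for that variant.
#'
#' @param results data frame from [evaluate_tool()].
#' @return data frame with `variant`, `expected_count`, `total_count`,
#'   `proportion`, ordered by variant. Variants with no cases are skipped.
#' @export
score_by_variant <- function(results) {
  sp <- split(results$behaved_as_expected, results$variant)
  out <- data.frame(variant = as.integer(names(sp)),
                    expected_count = vapply(sp, sum, 0L),
                    total_count = lengths(sp), row.names = NULL)
  out$proportion <- out$expected_count / out$total_count
  out[order(out$variant), ]
}

#' Tool spec for the package's own validator CLI
#'
#' Lets the harness exercise the repository's validator as an ordinary
#' external tool (self-conformance): the command invokes the installed
#' `exec/bedcert` script through `Rscript`, with the per-case `DIALECT`
#' placeholder so corpus cases that are delimiter-sensitive are judged
#' under their declared dialect.
#'
#' @return a [tool_spec()] named `"bedcert"`.
#' @export
validator_tool_spec <- function() {
  cli <- file.path(system.file(package = "bedcert"), "exec", "bedcert")
  if (!file.exists(cli)) {
    bedcert_stop("TOOL_MISSING", "installed bedcert CLI not found")
  }
  rscript <- file.path(R.home("bin"), "Rscript")
  tool_spec("bedcert",
            paste(shQuote(rscript), "--vanilla", shQuote(cli),
                  "validate --dialect DIALECT FILE"))
}

#' Write a small mock tool for harness testing
#'
#' Mock tools stand in for external BED consumers so the harness and the
#' differential fuzzer can be tested hermetically.
#'
#' @param behavior one of `"always-pass"` (consumes the file, exits 0
#'   silently), `"always-fail"` (prints an error, exits 1), `"silent-fail"`
#'   (exits non-zero without output), `"warn"` (exits 0 but prints a
#'   warning), `"sleepy"` (sleeps `sleep` seconds, for timeout tests) and
#'   `"reject-4-fields"` (errors iff some line has exactly 4
#'   whitespace-delimited fields).
#' @param dir directory for the script.
#' @param sleep seconds the `"sleepy"` tool sleeps.
#' @return a [tool_spec()] invoking the script.
#' @export
mock_tool <- function(behavior = c("always-pass", "always-fail",
                                   "silent-fail", "warn", "sleepy",
                                   "reject-4-fields"),
                      dir = tempdir(), sleep = 5) {
  behavior <- match.arg(behavior)
  body <- switch(behavior,
    "always-pass" = 'cat "$1" > /dev/null 2>&1\nexit 0',
    "always-fail" = 'echo "Error: rejected $1" >&2\nexit 1',
    "silent-fail" = 'exit 3',
    "warn" = 'echo "Warning: skipped line 3" >&2\nexit 0',
    "sleepy" = sprintf('sleep %s\nexit 0', sleep),
    "reject-4-fields" = paste(
      'set -f',  # no glob expansion when word-splitting fields
      'while IFS= read -r line || [ -n "$line" ]; do',
      '  set -- $line',
      '  if [ "$#" -eq 4 ]; then',
      '    echo "Error: a line has 4 fields, but 0 were expected" >&2',
      '    exit 1',
      '  fi',
      'done < "$1"',
      'exit 0', sep = "\n")
  )
  path <- file.path(dir, paste0("mock-", behavior, ".sh"))
  writeLines(c("#!/bin/sh", body), path)
  Sys.chmod(path, "0755")
  tool_spec(paste0("mock-", behavior), paste("sh", shQuote(path), "FILE"))
}
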