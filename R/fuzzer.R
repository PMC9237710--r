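# Grammar-based fuzzing. A meta-grammar samples a concrete BED grammar
# (dialect choices plus per-field value generators); the grammar then
# generates whole files. Strictly-valid grammars only produce content the
# strict validator accepts under the matching dialect; possibly-invalid
# grammars differ from the specification in exactly one rule, so a
# discordance between two tools is attributable to that rule.

# run expr under a private RNG stream, restoring the caller's stream
local_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  expr
}

FUZZ_MUTATIONS <- c("score-range", "negative-start", "start-after-end",
                    "strand-symbol", "prohibited-variant")

#' Sample a concrete BED grammar from the meta-grammar
#'
#' The meta-grammar varies the dialect (tabs only versus tabs and spaces;
#' blank lines; `#` comment lines) and the file's variant. A
#' `strictly-valid` instance keeps every field generator inside the
#' specification; a `possibly-invalid` instance additionally mutates
#' exactly one rule away from the specification (recorded in `$mutation`).
#'
#' @param seed integer seed; the instance is deterministic in it.
#' @param validity `"strictly-valid"` or `"possibly-invalid"`.
#' @return object of class `bed_grammar`: list with `delimiter` (`"tab"` or
#'   `"both"`), `allow_blank`, `allow_comments`, `n` (variant),
#'   `coord_max`, `validity`, `mutation` (`NA` for strictly-valid) and
#'   `dialect` (the matching [bed_dialect()]).
#' @examples
#' g <- instantiate_grammar(1)
#' identical(g, instantiate_grammar(1))  # TRUE
#' @export
instantiate_grammar <- function(seed,
                                validity = c("strictly-valid",
                                             "possibly-invalid")) {
  validity <- match.arg(validity)
  local_seed(seed, {
    delimiter <- sample(c("tab", "both"), 1L)
    allow_blank <- sample(c(TRUE, FALSE), 1L)
    allow_comments <- sample(c(TRUE, FALSE), 1L)
    n <- sample(STANDARD_N, 1L)
    mutation <- NA_character_
    if (validity == "possibly-invalid") {
      mutation <- sample(FUZZ_MUTATIONS, 1L)
      if (mutation == "prohibited-variant") n <- sample(c(10L, 11L), 1L)
    }
    structure(
      list(delimiter = delimiter, allow_blank = allow_blank,
           allow_comments = allow_comments, n = n,
           coord_max = sample(c(10000L, 100000L, 1000000L), 1L),
           validity = validity, mutation = mutation,
           dialect = bed_dialect(
             whitespace = if (delimiter == "both") "flexible" else "tabs",
             allow_blank = TRUE, skip_comments = allow_comments)),
      class = "bed_grammar")
  })
}

#' @export
print.bed_grammar <- function(x, ...) {
  cat(sprintf("<bed_grammar BED%d %s%s delim=%s blank=%s comments=%s>\n",
              x$n, x$validity,
              if (is.na(x$mutation)) "" else paste0(" [", x$mutation, "]"),
              x$delimiter, x$allow_blank, x$allow_comments))
  invisible(x)
}

rand_name <- function() {
  paste(sample(c(letters, LETTERS, 0:9), sample(2:10, 1L), replace = TRUE),
        collapse = "")
}

# one record's tokens under the grammar (and its single mutation, if any)
fuzz_record <- function(g) {
  mut <- g$mutation
  chrom <- sample(c(paste0("chr", c(1:22, "X", "Y")), "chrUn_KI270752v1"), 1L)
  start <- sample.int(g$coord_max, 1L) - 1L

  # block structure first so chromEnd closes the last block exactly
  n_eff <- g$n
  if (n_eff >= 12L) {
    k <- sample(1:3, 1L)
    sizes <- sample.int(500L, k)
    gaps <- if (k > 1L) sample.int(200L, k - 1L) - 1L else integer(0)
    starts <- cumsum(c(0L, (sizes + c(gaps, 0L))[-k]))
    span <- starts[k] + sizes[k]
  } else {
    span <- sample.int(2000L, 1L) - 1L  # zero-length intervals are legal
  }
  end <- start + span
  if (identical(mut, "negative-start")) start <- -sample.int(1000L, 1L)
  if (identical(mut, "start-after-end") && span > 0L) {
    tmp <- start; start <- end; end <- tmp
  }

  tok <- c(chrom, fmt_int(start), fmt_int(end))
  if (n_eff >= 4L) tok[4] <- rand_name()
  if (n_eff >= 5L) {
    score <- if (identical(mut, "score-range"))
      sample(-100:2000, 1L) else sample(0:1000, 1L)
    tok[5] <- fmt_int(score)
  }
  if (n_eff >= 6L) {
    pool <- c("+", "-", ".")
    if (identical(mut, "strand-symbol")) pool <- c(pool, "*", "?")
    tok[6] <- sample(pool, 1L)
  }
  if (n_eff >= 7L) {
    lo <- min(start, end)
    hi <- max(start, end)
    ts <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    tok[7] <- fmt_int(ts)
    if (n_eff >= 8L) tok[8] <- fmt_int(ts + sample.int(hi - ts + 1L, 1L) - 1L)
  }
  if (n_eff >= 9L) {
    tok[9] <- if (sample(c(TRUE, FALSE), 1L)) "0" else
      paste(sample(0:255, 3L, replace = TRUE), collapse = ",")
  }
  if (n_eff >= 10L) tok[10] <- if (n_eff >= 12L) fmt_int(k) else "1"
  if (n_eff >= 11L) tok[11] <- if (n_eff >= 12L)
    paste(sizes, collapse = ",") else fmt_int(max(span, 1L))
  if (n_eff >= 12L) tok[12] <- paste(starts, collapse = ",")
  tok
}

#' Generate a BED file from a grammar instance
#'
#' Emits exactly `n_lines` data lines, interleaved with blank and `#`
#' comment lines when the grammar allows them. Byte-deterministic in
#' `(grammar, seed, n_lines)`.
#'
#' @param grammar a [instantiate_grammar()] result.
#' @param seed integer seed for the file's own randomness.
#' @param n_lines number of data lines (>= 0).
#' @return the file content as one string (trailing newline included;
#'   empty for `n_lines = 0` with no decorations).
#' @export
generate_file <- function(grammar, seed, n_lines = 10L) {
  stopifnot(inherits(grammar, "bed_grammar"), n_lines >= 0L)
  local_seed(seed, {
    out <- character(0)
    join <- function(tok) {
      if (grammar$delimiter == "tab") return(paste(tok, collapse = "\t"))
      seps <- sample(c("\t", " "), length(tok) - 1L, replace = TRUE)
      paste0(paste0(tok[-length(tok)], seps, collapse = ""),
             tok[length(tok)])
    }
    decorate <- function() {
      if (grammar$allow_comments && runif(1) < 0.15) {
        out <<- c(out, paste0("#", rand_name()))
      }
      if (grammar$allow_blank && runif(1) < 0.15) {
        out <<- c(out, "")
      }
    }
    for (i in seq_len(n_lines)) {
      decorate()
      out <- c(out, join(fuzz_record(grammar)))
    }
    decorate()
    if (length(out) == 0L) "" else paste0(paste(out, collapse = "\n"), "\n")
  })
}

#' Differential testing of two BED consumers
#'
#' For each trial a fresh grammar is sampled from the meta-grammar and a
#' fresh file generated from it; both tools run on the file and their
#' classified verdicts ([classify_outcome()]) are compared. Disagreements
#' are recorded with the full file content for triage. The whole report is
#' deterministic in `(tool_a, tool_b, n_trials, seed)`.
#'
#' @param tool_a,tool_b [tool_spec()] objects.
#' @param n_trials number of generated files.
#' @param seed master seed; per-trial seeds are derived from it.
#' @param validity grammar validity class for the trials.
#' @param n_lines data lines per generated file.
#' @param dir where trial files are written.
#' @param timeout per-run timeout in seconds.
#' @return object of class `bed_discordance_report`: list with `trials`,
#'   `tool_a`, `tool_b` and `discordances` (data frame: `trial`, `file`,
#'   `verdict_a`, `verdict_b`, `content`).
#' @export
differential_run <- function(tool_a, tool_b, n_trials, seed,
                             validity = "possibly-invalid", n_lines = 5L,
                             dir = tempdir(), timeout = 60) {
  stopifnot(inherits(tool_a, "bed_tool_spec"),
            inherits(tool_b, "bed_tool_spec"), n_trials >= 0L)
  trial_seeds <- local_seed(seed,
                            sample.int(.Machine$integer.max, n_trials))
  rows <- list()
  for (i in seq_len(n_trials)) {
    grammar <- instantiate_grammar(trial_seeds[i], validity)
    content <- generate_file(grammar, trial_seeds[i], n_lines)
    path <- file.path(dir, sprintf("fuzz-trial-%04d.bed", i))
    con <- file(path, open = "wb")
    writeLines(sub("\n$", "", content), con, sep = "\n", useBytes = TRUE)
    close(con)
    dialect_name <- grammar$dialect$whitespace
    va <- run_tool_on_case(tool_a, path, dialect = dialect_name,
                           timeout = timeout)$classified
    vb <- run_tool_on_case(tool_b, path, dialect = dialect_name,
                           timeout = timeout)$classified
    if (va != vb) {
      rows[[length(rows) + 1L]] <-
        data.frame(trial = i, file = path, verdict_a = va, verdict_b = vb,
                   content = content, stringsAsFactors = FALSE)
    }
  }
  structure(
    list(trials = n_trials, tool_a = tool_a$name, tool_b = tool_b$name,
         discordances = if (length(rows)) do.call(rbind, rows) else
           data.frame(trial = integer(0), file = character(0),
                      verdict_a = character(0), verdict_b = character(0),
                      content = character(0))),
    class = "bed_discordance_report")
}

#' @export
print.bed_discordance_report <- function(x, ...) {
  cat(sprintf("differential run: %s vs %s, %d trials, %d discordances\n",
              x$tool_a, x$tool_b, x$trials, nrow(x$discordances)))
  invisible(x)
}
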