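# Strict validation of BED lines and files against the GA4GH BED v1 rules.
# Every violation is reported as a coded, line-addressed issue; a file is
# valid iff it produces no error-severity issues.

#' Describe a BED parsing dialect
#'
#' The specification allows both tabs and spaces as field delimiters
#' provided no field value itself contains a space; many tools only accept
#' tabs. A dialect pins down the delimiter rule plus blank-line and
#' comment-line handling so that a validation verdict is a pure function of
#' file bytes + dialect + mode.
#'
#' @param whitespace `"flexible"` (fields split on maximal runs of tabs and
#'   spaces) or `"tabs"` (split on single tab characters; empty fields are
#'   preserved and rejected downstream).
#' @param allow_blank are blank lines permitted? The specification permits
#'   them, so the default is `TRUE`.
#' @param skip_comments skip lines starting with `#`, `track` or `browser`
#'   without validating them. Off by default in strict mode: the base
#'   specification has no comment syntax, and tools disagree about it.
#' @return an object of class `bed_dialect`.
#' @export
bed_dialect <- function(whitespace = c("flexible", "tabs"),
                        allow_blank = TRUE, skip_comments = FALSE) {
  whitespace <- match.arg(whitespace)
  structure(list(whitespace = whitespace,
                 allow_blank = isTRUE(allow_blank),
                 skip_comments = isTRUE(skip_comments)),
            class = "bed_dialect")
}

#' Split one BED line into field tokens
#'
#' Splitting never fails; field-count and content validation happen
#' downstream. Under the tabs-only dialect the line is split on every single
#' tab, so doubled tabs yield empty tokens (later rejected as
#' `MISSING_FIELD`). Under the flexible dialect the line is split on maximal
#' runs of tabs and spaces, after stripping leading/trailing whitespace.
#'
#' @param line one line of text, no newline.
#' @param dialect a [bed_dialect()].
#' @return character vector of field tokens (length 0 for a blank line).
#' @examples
#' split_fields("chr1\t250000\t250100", bed_dialect())
#' split_fields("a b\tc", bed_dialect("tabs"))      # "a b", "c"
#' split_fields("a b\tc", bed_dialect("flexible"))  # "a", "b", "c"
#' @export
split_fields <- function(line, dialect = bed_dialect()) {
  stopifnot(is.character(line), length(line) == 1L)
  if (dialect$whitespace == "tabs") {
    if (line == "") return(character(0))
    strsplit(line, "\t", fixed = TRUE)[[1]]
  } else {
    trimmed <- gsub("^[ \t]+|[ \t]+$", "", line)
    if (trimmed == "") return(character(0))
    strsplit(trimmed, "[ \t]+")[[1]]
  }
}

issue <- function(severity, line, field, code, message) {
  data.frame(severity = severity, line = as.integer(line),
             field = as.integer(field), code = code, message = message,
             stringsAsFactors = FALSE)
}

no_issues <- function() {
  issue("error", 1L, 1L, "X", "x")[0, ]
}

# exact comparison of unsigned decimal strings of any length:
# returns -1, 0 or 1 for a < b, a == b, a > b
cmp_dec <- function(a, b) {
  a <- sub("^0+(?=.)", "", a, perl = TRUE)
  b <- sub("^0+(?=.)", "", b, perl = TRUE)
  if (nchar(a) != nchar(b)) return(sign(nchar(a) - nchar(b)))
  if (a == b) 0L else if (a < b) -1L else 1L
}

is_uint <- function(tok) grepl("^[0-9]+$", tok)
is_int <- function(tok) grepl("^-?[0-9]+$", tok)

# classify a coordinate token: "" (ok), or an issue code
coord_code <- function(tok) {
  if (is_uint(tok)) "" else if (grepl("^-[0-9]+$", tok)) "NEGATIVE_COORD"
  else "COORD_FORMAT"
}

#' Validate the fields of one BED data line
#'
#' Applies the closed rule table in field order and returns every violation
#' found (it does not stop at the first). Rules, by field: chrom non-empty,
#' at most 255 characters from `[A-Za-z0-9._-]`; chromStart/chromEnd
#' unsigned decimal integers with chromStart <= chromEnd; name at most 255
#' characters with no whitespace; score an integer in 0--1000; strand one of
#' `+`, `-`, `.`; chromStart <= thickStart <= thickEnd <= chromEnd; itemRgb
#' the literal `0` or a triple of integers each in 0--255; blockCount a
#' positive integer; blockSizes/blockStarts comma lists of exactly
#' blockCount entries (one trailing comma tolerated), sizes >= 1, starts
#' >= 0; first blockStart 0, blocks ascending and non-overlapping, last
#' block ending at chromEnd - chromStart. Custom fields (beyond
#' `variant$n`) are not validated.
#'
#' @param fields character vector of tokens from [split_fields()].
#' @param variant the [bed_variant()] governing the line.
#' @param strict reserved; custom-mode relaxation happens through `variant`.
#' @return data frame of issues (zero rows when the line is clean) with
#'   columns `severity`, `line`, `field`, `code`, `message`. `line` is set
#'   to 1 here; [validate_file()] renumbers.
#' @examples
#' validate_line(c("chr1", "250000", "250100"), bed_variant(3))
#' validate_line(c("chr1", "250000", "250100", "x", "1001"), bed_variant(5))
#' @export
validate_line <- function(fields, variant, strict = TRUE) {
  stopifnot(inherits(variant, "bed_variant"))
  n_std <- min(length(fields), variant$n)
  out <- list()
  add <- function(field, code, msg, severity = "error") {
    out[[length(out) + 1L]] <<- issue(severity, 1L, field, code, msg)
  }

  if (length(fields) < variant$n + variant$m) {
    add(length(fields) + 1L, "MISSING_FIELD",
        sprintf("line has %d fields, %s needs %d", length(fields),
                format(variant), variant$n + variant$m))
  }

  # empty tokens (doubled tabs in tabs-only mode) fail fast per field
  empty <- which(fields == "")
  for (i in empty) {
    add(i, "MISSING_FIELD", sprintf("field %d is empty", i))
  }

  f <- function(i) if (i <= length(fields)) fields[i] else NA_character_
  ok <- function(i) i <= length(fields) && fields[i] != ""

  # chrom
  if (ok(1)) {
    if (!grepl("^[A-Za-z0-9._-]{1,255}$", f(1))) {
      add(1L, "CHROM_FORMAT",
          sprintf("chrom '%s' must be 1-255 characters from [A-Za-z0-9._-]",
                  f(1)))
    }
  }
  # chromStart / chromEnd
  coord_ok <- logical(2)
  for (i in 2:3) {
    if (!ok(i)) next
    code <- coord_code(f(i))
    if (code == "") {
      coord_ok[i - 1L] <- TRUE
    } else {
      add(i, code, sprintf("%s '%s' is not an unsigned integer",
                           c("chromStart", "chromEnd")[i - 1L], f(i)))
    }
  }
  if (all(coord_ok) && cmp_dec(f(2), f(3)) > 0L) {
    add(2L, "COORD_ORDER",
        sprintf("chromStart %s greater than chromEnd %s", f(2), f(3)))
  }
  # name
  if (n_std >= 4L && ok(4)) {
    if (nchar(f(4)) > 255L || grepl("[ \t]", f(4))) {
      add(4L, "NAME_FORMAT",
          sprintf("name '%s' must be at most 255 characters with no whitespace",
                  substr(f(4), 1, 40)))
    }
  }
  # score
  if (n_std >= 5L && ok(5)) {
    if (!is_int(f(5))) {
      add(5L, "SCORE_FORMAT", sprintf("score '%s' is not an integer", f(5)))
    } else if (grepl("^-", f(5)) || cmp_dec(f(5), "1000") > 0L) {
      add(5L, "SCORE_RANGE",
          sprintf("score %s outside 0-1000 inclusive", f(5)))
    }
  }
  # strand
  if (n_std >= 6L && ok(6) && !(f(6) %in% c("+", "-", "."))) {
    add(6L, "STRAND_SYMBOL",
        sprintf("strand '%s' must be one of + - .", f(6)))
  }
  # thickStart / thickEnd
  thick_ok <- logical(2)
  for (i in 7:8) {
    if (n_std < i || !ok(i)) next
    code <- coord_code(f(i))
    if (code == "") {
      thick_ok[i - 6L] <- TRUE
    } else {
      add(i, code, sprintf("%s '%s' is not an unsigned integer",
                           c("thickStart", "thickEnd")[i - 6L], f(i)))
    }
  }
  if (n_std >= 8L && all(coord_ok) && all(thick_ok)) {
    if (cmp_dec(f(2), f(7)) > 0L || cmp_dec(f(7), f(8)) > 0L ||
        cmp_dec(f(8), f(3)) > 0L) {
      add(7L, "THICK_OUT_OF_BOUNDS",
          sprintf("need chromStart <= thickStart <= thickEnd <= chromEnd, got %s <= %s <= %s <= %s",
                  f(2), f(7), f(8), f(3)))
    }
  } else if (n_std == 7L && all(coord_ok) && thick_ok[1]) {
    # BED7: thickEnd absent; thickStart must still sit inside the interval
    if (cmp_dec(f(2), f(7)) > 0L || cmp_dec(f(7), f(3)) > 0L) {
      add(7L, "THICK_OUT_OF_BOUNDS",
          sprintf("thickStart %s outside interval [%s, %s]", f(7), f(2), f(3)))
    }
  }
  # itemRgb
  if (n_std >= 9L && ok(9) && f(9) != "0") {
    parts <- strsplit(f(9), ",", fixed = TRUE)[[1]]
    if (length(parts) != 3L || !all(is_uint(parts)) ||
        any(as.numeric(parts) > 255)) {
      add(9L, "RGB_FORMAT",
          sprintf("itemRgb '%s' must be '0' or R,G,B with each value 0-255",
                  f(9)))
    }
  }
  # blocks
  if (n_std >= 10L && ok(10)) {
    if (!is_uint(f(10)) || cmp_dec(f(10), "1") < 0L) {
      add(10L, "BLOCK_COUNT",
          sprintf("blockCount '%s' must be a positive integer", f(10)))
    } else if (n_std >= 12L && ok(11) && ok(12)) {
      bc <- as.numeric(f(10))
      sizes <- strsplit(sub(",$", "", f(11)), ",", fixed = TRUE)[[1]]
      starts <- strsplit(sub(",$", "", f(12)), ",", fixed = TRUE)[[1]]
      fmt_bad <- FALSE
      if (!all(is_uint(sizes)) || any(sizes == "0")) {
        add(11L, "BLOCK_LIST_FORMAT",
            sprintf("blockSizes '%s' must be comma-separated integers >= 1",
                    f(11)))
        fmt_bad <- TRUE
      }
      if (!all(is_uint(starts))) {
        add(12L, "BLOCK_LIST_FORMAT",
            sprintf("blockStarts '%s' must be comma-separated integers >= 0",
                    f(12)))
        fmt_bad <- TRUE
      }
      if (!fmt_bad && (length(sizes) != bc || length(starts) != bc)) {
        add(11L, "BLOCK_LIST_LENGTH",
            sprintf("blockCount is %s but blockSizes has %d and blockStarts %d entries",
                    f(10), length(sizes), length(starts)))
        fmt_bad <- TRUE
      }
      if (!fmt_bad && all(coord_ok)) {
        sz <- as.numeric(sizes)
        st <- as.numeric(starts)
        span <- as.numeric(f(3)) - as.numeric(f(2))
        bad_struct <- st[1] != 0 ||
          (bc > 1 && any(st[-1] < (st + sz)[-bc])) ||
          st[bc] + sz[bc] != span
        if (bad_struct) {
          add(12L, "BLOCK_STRUCTURE",
              "blocks must start at 0, ascend without overlap and end at chromEnd - chromStart")
        }
      }
    }
  }

  if (length(out) == 0L) no_issues() else do.call(rbind, out)
}

#' Validate a BED file
#'
#' Reads the file line by line, fixes the variant from the first data line
#' (later lines with a different field count are `MIXED_FIELD_COUNT`
#' errors), and applies [validate_line()] to every data line. Blank lines
#' are permitted and counted, not errors. Undecodable bytes yield an
#' `ENCODING` error; carriage-return line endings yield a warning (style,
#' not a violation).
#'
#' @param path path to a BED file.
#' @param dialect a [bed_dialect()].
#' @param mode `"strict"` (standard variants only; 10 or 11 fields are
#'   `PROHIBITED_VARIANT`) or `"custom"`.
#' @param declared_n in custom mode, how many leading fields are standard.
#' @return an object of class `bed_validation_report`: a list with `path`,
#'   `dialect`, `variant` (of the first data line, or `NULL`), `n_records`,
#'   `n_blank`, `issues` (data frame) and `valid` (`TRUE` iff no
#'   error-severity issues).
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t250000\t250100", f)
#' validate_file(f)$valid
#' @export
validate_file <- function(path, dialect = bed_dialect(),
                          mode = c("strict", "custom"), declared_n = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    bedcert_stop("IO_ERROR", sprintf("cannot read '%s'", path))
  }
  # read bytes and split on LF ourselves so carriage returns stay visible
  # (readLines would silently normalize CRLF endings)
  size <- file.info(path)$size
  lines <- if (is.na(size) || size == 0) character(0) else {
    txt <- readChar(path, size, useBytes = TRUE)
    txt <- sub("\n$", "", txt, useBytes = TRUE)
    strsplit(txt, "\n", fixed = TRUE, useBytes = TRUE)[[1]]
  }
  report <- validate_lines(lines, dialect, mode, declared_n)
  report$path <- path
  report
}

#' Validate BED content held in memory
#'
#' Same semantics as [validate_file()] but for a character vector of lines
#' or a single string with embedded newlines (as produced by
#' [generate_file()]).
#'
#' @param text character vector of lines, or one string with `\n`s.
#' @inheritParams validate_file
#' @return a `bed_validation_report`; see [validate_file()].
#' @export
validate_text <- function(text, dialect = bed_dialect(),
                          mode = c("strict", "custom"), declared_n = NULL) {
  mode <- match.arg(mode)
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(sub("\n$", "", text), "\n", fixed = TRUE)[[1]]
  }
  validate_lines(text, dialect, mode, declared_n)
}

validate_lines <- function(lines, dialect, mode, declared_n) {
  issues <- list()
  n_records <- 0L
  n_blank <- 0L
  file_variant <- NULL
  first_count <- NA_integer_

  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!validUTF8(line)) {
      issues[[length(issues) + 1L]] <-
        issue("error", ln, NA_integer_, "ENCODING",
              sprintf("line %d contains undecodable bytes", ln))
      next
    }
    if (endsWith(line, "\r")) {
      issues[[length(issues) + 1L]] <-
        issue("warning", ln, NA_integer_, "CRLF",
              "carriage-return line ending")
      line <- sub("\r$", "", line)
    }
    if (grepl("^[ \t]*$", line)) {
      n_blank <- n_blank + 1L
      if (!dialect$allow_blank) {
        issues[[length(issues) + 1L]] <-
          issue("error", ln, NA_integer_, "BLANK_LINE",
                "blank lines disallowed by this dialect")
      }
      next
    }
    if (dialect$skip_comments &&
        grepl("^(#|track([ \t]|$)|browser([ \t]|$))", line)) {
      next
    }

    fields <- split_fields(line, dialect)
    n_records <- n_records + 1L

    if (!is.null(file_variant) && length(fields) != first_count) {
      issues[[length(issues) + 1L]] <-
        issue("error", ln, NA_integer_, "MIXED_FIELD_COUNT",
              sprintf("line %d has %d fields but the file started with %d",
                      ln, length(fields), first_count))
      next
    }

    variant <- tryCatch(
      detect_variant(length(fields), mode, declared_n),
      bedcert_error = function(e) e
    )
    if (inherits(variant, "bedcert_error")) {
      issues[[length(issues) + 1L]] <-
        issue("error", ln, NA_integer_, variant$code, variant$message)
      if (is.null(file_variant)) first_count <- length(fields)
      next
    }
    if (is.null(file_variant)) {
      file_variant <- variant
      first_count <- length(fields)
    }

    li <- validate_line(fields, variant)
    if (nrow(li) > 0L) {
      li$line <- ln
      issues[[length(issues) + 1L]] <- li
    }
  }

  issues <- if (length(issues)) do.call(rbind, issues) else no_issues()
  structure(
    list(path = NA_character_, dialect = dialect, mode = mode,
         variant = file_variant, n_records = n_records, n_blank = n_blank,
         issues = issues,
         valid = !any(issues$severity == "error")),
    class = "bed_validation_report"
  )
}

#' @export
print.bed_validation_report <- function(x, ...) {
  cat(sprintf("BED validation: %s\n",
              if (is.na(x$path)) "<in-memory>" else x$path))
  cat(sprintf("  variant: %s | records: %d | blank lines: %d\n",
              if (is.null(x$variant)) "none" else format(x$variant),
              x$n_records, x$n_blank))
  if (nrow(x$issues) == 0L) {
    cat("  no issues; VALID\n")
  } else {
    apply(x$issues, 1L, function(r) {
      cat(sprintf("  %s:%s:%s: [%s] %s\n", r[["line"]],
                  ifelse(is.na(r[["field"]]), "-", r[["field"]]),
                  r[["severity"]], r[["code"]], r[["message"]]))
    })
    cat(sprintf("  %s\n", if (x$valid) "VALID (warnings only)" else "INVALID"))
  }
  invisible(x)
}

#' The closed table of validator rule codes
#'
#' @param errors_only if `TRUE` (default) return only error-severity codes.
#' @return character vector of every code [validate_file()] can emit.
#' @export
rule_codes <- function(errors_only = TRUE) {
  errs <- c("ENCODING", "MISSING_FIELD", "MALFORMED_FIELD_COUNT",
            "PROHIBITED_VARIANT", "MIXED_FIELD_COUNT", "CHROM_FORMAT",
            "NEGATIVE_COORD", "COORD_FORMAT", "COORD_ORDER", "NAME_FORMAT",
            "SCORE_FORMAT", "SCORE_RANGE", "STRAND_SYMBOL",
            "THICK_OUT_OF_BOUNDS", "RGB_FORMAT", "BLOCK_COUNT",
            "BLOCK_LIST_FORMAT", "BLOCK_LIST_LENGTH", "BLOCK_STRUCTURE",
            "BLANK_LINE")
  if (errors_only) errs else c(errs, "CRLF")
}
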