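# The conformance corpus: 92 deterministic test files across BED3-BED12,
# each labelled expected-pass or expected-fail. Base cases introduced at one
# variant are repeated ("expanded") for every later variant with neutral
# valid filler appended; any case landing on BED10 or BED11 is expected-fail
# regardless, because the specification prohibits those variants.
#
# The published total (92) and the global constraints (coordinates within
# [250000, 260000]; zero expected-pass cases for BED10/BED11) are fixed;
# the per-variant breakdown is package-defined and recorded in the manifest.

CORPUS_VARIANTS <- c(3:12)

#' Construct a corpus test case
#'
#' @param id short case identifier, e.g. `"02-negative-start"`.
#' @param n BED variant (number of fields) of the file, 3--12.
#' @param expectation `"pass"` (a conforming consumer must accept silently)
#'   or `"fail"` (must reject with non-zero exit or an error/warning).
#' @param content character vector of file lines.
#' @param dialect `"flexible"` or `"tabs"`: the dialect under which the
#'   expectation holds (tab-delimited content behaves identically under
#'   both; it matters only for cases built around delimiter semantics).
#' @param provenance which rule the case exercises.
#' @return object of class `bed_test_case`.
#' @export
bed_test_case <- function(id, n, expectation = c("pass", "fail"), content,
                          dialect = "flexible", provenance = "") {
  expectation <- match.arg(expectation)
  stopifnot(n %in% 3:12, is.character(content))
  if (n %in% c(10L, 11L)) expectation <- "fail"
  structure(list(id = id, n = as.integer(n), expectation = expectation,
                 content = content, dialect = dialect,
                 provenance = provenance),
            class = "bed_test_case")
}

#' @export
format.bed_test_case <- function(x, ...) {
  sprintf("bed%d/%s [%s]", x$n, x$id, x$expectation)
}

#' @export
print.bed_test_case <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# the three stock records every case is built from
stock_records <- function() {
  list(c("chr7", "250000", "250150"),
       c("chr7", "251000", "251500"),
       c("chrX", "255000", "256000"))
}

# neutral valid filler for standard fields (from+1)..to of one record
fill_tokens <- function(tokens, to, id) {
  from <- length(tokens)
  for (k in seq_len(to - from) + from) {
    tokens[k] <- switch(k - 3L,
      id,                                      # name
      "500",                                   # score
      "+",                                     # strand
      tokens[2],                               # thickStart = chromStart
      tokens[3],                               # thickEnd = chromEnd
      "0",                                     # itemRgb
      "1",                                     # blockCount
      {                                        # blockSizes: span the interval
        if (is_uint(tokens[2]) && is_uint(tokens[3]) &&
            cmp_dec(tokens[2], tokens[3]) <= 0L) {
          fmt_int(as.numeric(tokens[3]) - as.numeric(tokens[2]))
        } else "150"
      },
      "0"                                      # blockStarts
    )
  }
  tokens
}

#' Repeat a test case at a wider BED variant
#'
#' Appends neutral valid filler (name = case id, score 500, strand `+`,
#' thick = the whole interval, itemRgb `0`, one block spanning the interval)
#' to every data line. The expectation is inherited -- a failing base stays
#' failing -- except that any BED10 or BED11 target becomes expected-fail,
#' since the specification prohibits those variants.
#'
#' @param case a [bed_test_case()].
#' @param target_n target variant, at least `case$n`.
#' @return the expanded `bed_test_case`.
#'   Errors: `INVALID_EXPANSION` when `target_n < case$n`.
#' @examples
#' base <- corpus_cases()[["bed5/06-score-too-large"]]
#' expand_case(base, 12)$expectation  # still "fail"
#' @export
expand_case <- function(case, target_n) {
  stopifnot(inherits(case, "bed_test_case"))
  target_n <- as.integer(target_n)
  if (target_n < case$n) {
    bedcert_stop("INVALID_EXPANSION",
                 sprintf("cannot expand BED%d case '%s' down to BED%d",
                         case$n, case$id, target_n))
  }
  if (target_n == case$n) return(case)
  content <- vapply(case$content, function(line) {
    if (grepl("^[ \t]*$", line)) return(line)
    tokens <- strsplit(line, "\t", fixed = TRUE)[[1]]
    paste(fill_tokens(tokens, target_n, case$id), collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  bed_test_case(case$id, target_n,
                if (target_n %in% c(10L, 11L)) "fail" else case$expectation,
                content, case$dialect, case$provenance)
}

tab_lines <- function(recs) vapply(recs, paste, character(1), collapse = "\t")

# base cases that get expanded to every variant from their own up to BED12
expanded_bases <- function() {
  R <- stock_records()
  with_r1 <- function(r1) tab_lines(c(list(r1), R[-1]))
  at5 <- function(recs, id) lapply(recs, fill_tokens, to = 5L, id = id)
  at6 <- function(recs, id) lapply(recs, fill_tokens, to = 6L, id = id)

  list(
    bed_test_case("01-valid", 3, "pass", tab_lines(R),
                  provenance = "baseline conforming records"),
    bed_test_case("02-negative-start", 3, "fail",
                  with_r1(c("chr7", "-250000", "250150")),
                  provenance = "NEGATIVE_COORD: negative chromStart"),
    bed_test_case("03-start-after-end", 3, "fail",
                  with_r1(c("chr7", "250200", "250150")),
                  provenance = "COORD_ORDER: chromStart > chromEnd"),
    bed_test_case("04-non-numeric-start", 3, "fail",
                  with_r1(c("chr7", "25O000", "250150")),
                  provenance = "COORD_FORMAT: letter in chromStart"),
    bed_test_case("05-bad-chrom-char", 3, "fail",
                  with_r1(c("chr7;7", "250000", "250150")),
                  provenance = "CHROM_FORMAT: ';' not in chrom charset"),
    bed_test_case("06-score-too-large", 5, "fail", {
      recs <- at5(stock_records(), "06-score-too-large")
      recs[[1]][5] <- "1001"
      tab_lines(recs)
    }, provenance = "SCORE_RANGE: score above 1000"),
    bed_test_case("07-non-integer-score", 5, "fail", {
      recs <- at5(stock_records(), "07-non-integer-score")
      recs[[1]][5] <- "0.5"
      tab_lines(recs)
    }, provenance = "SCORE_FORMAT: p-value style score"),
    bed_test_case("08-bad-strand", 6, "fail", {
      recs <- at6(stock_records(), "08-bad-strand")
      recs[[1]][6] <- "*"
      tab_lines(recs)
    }, provenance = "STRAND_SYMBOL: '*' is not a strand")
  )
}

# one-off cases tied to a single variant
single_cases <- function() {
  R <- stock_records()
  at <- function(n, id) lapply(R, fill_tokens, to = n, id = id)
  set_field <- function(recs, i, k, value) {
    recs[[i]][k] <- value
    recs
  }
  set_all <- function(recs, k, value) {
    lapply(recs, function(r) { r[k] <- value; r })
  }

  list(
    bed_test_case("other-fully_space_delimited", 3, "pass",
                  vapply(R, paste, character(1), collapse = " "),
                  provenance = "spaces are legal delimiters when fields contain none"),
    bed_test_case("other-space_between_lines", 3, "pass",
                  c(tab_lines(R[1]), "", tab_lines(R[-1])),
                  provenance = "blank lines are permitted"),
    bed_test_case("other-zero_length_interval", 3, "pass",
                  tab_lines(c(list(c("chr7", "250500", "250500")), R[-1])),
                  provenance = "chromStart == chromEnd is a legal empty interval"),
    bed_test_case("other-chrom_scaffold", 3, "pass",
                  tab_lines(list(c("chrUn_KI270752v1", "250000", "250150"),
                                 c("chr7_KI270803v1_alt", "251000", "251500"),
                                 c("chrX", "255000", "256000"))),
                  provenance = "scaffold names within the chrom charset"),
    bed_test_case("other-two_fields", 3, "fail",
                  "chr7\t250000",
                  provenance = "MALFORMED_FIELD_COUNT: below the 3-field minimum"),
    bed_test_case("other-mixed_field_count", 3, "fail",
                  c(tab_lines(R[1]),
                    paste(c(R[[2]], "extra"), collapse = "\t"),
                    tab_lines(R[3])),
                  provenance = "MIXED_FIELD_COUNT: one file must be one variant"),
    bed_test_case("other-bad_encoding", 3, "fail",
                  paste0("chr", rawToChar(as.raw(0xFF)), "7\t250000\t250150"),
                  provenance = "ENCODING: undecodable byte in chrom"),
    bed_test_case("other-name_too_long", 4, "fail",
                  tab_lines(set_field(at(4, "other-name_too_long"), 1, 4,
                                      strrep("N", 256))),
                  provenance = "NAME_FORMAT: 256-character name"),
    bed_test_case("other-empty_name", 5, "fail",
                  tab_lines(set_field(at(5, "other-empty_name"), 1, 4, "")),
                  dialect = "tabs",
                  provenance = "MISSING_FIELD: empty field between two tabs"),
    bed_test_case("other-dot_strand", 6, "pass",
                  tab_lines(set_all(at(6, "other-dot_strand"), 6, ".")),
                  provenance = "strand '.' is legal on every feature"),
    bed_test_case("other-thick_before_start", 7, "fail",
                  tab_lines(set_field(at(7, "other-thick_before_start"), 1, 7,
                                      "249900")),
                  provenance = "THICK_OUT_OF_BOUNDS: thickStart < chromStart"),
    bed_test_case("other-rgb_triple", 9, "pass",
                  tab_lines(set_all(at(9, "other-rgb_triple"), 9, "255,0,0")),
                  provenance = "itemRgb as an explicit 0-255 triple"),
    bed_test_case("other-bad_rgb", 9, "fail",
                  tab_lines(set_field(at(9, "other-bad_rgb"), 1, 9, "256,0,0")),
                  provenance = "RGB_FORMAT: channel above 255"),
    bed_test_case("other-thirteen_fields", 12, "fail",
                  c(paste(c(fill_tokens(R[[1]], 12, "other-thirteen_fields"),
                            "extra"), collapse = "\t"),
                    tab_lines(at(12, "other-thirteen_fields")[-1])),
                  provenance = "MALFORMED_FIELD_COUNT: above the 12-field maximum"),
    bed_test_case("other-block_count_zero", 12, "fail",
                  tab_lines(set_field(at(12, "other-block_count_zero"), 1, 10,
                                      "0")),
                  provenance = "BLOCK_COUNT: blockCount must be positive"),
    bed_test_case("other-block_list_too_long", 12, "fail",
                  tab_lines(set_field(at(12, "other-block_list_too_long"), 1,
                                      11, "100,50")),
                  provenance = "BLOCK_LIST_LENGTH: more sizes than blockCount"),
    bed_test_case("other-block_size_zero", 12, "fail",
                  tab_lines(set_field(at(12, "other-block_size_zero"), 1, 11,
                                      "0")),
                  provenance = "BLOCK_LIST_FORMAT: block sizes must be >= 1"),
    bed_test_case("other-blocks_not_spanning", 12, "fail",
                  tab_lines(set_field(at(12, "other-blocks_not_spanning"), 1,
                                      11, "100")),
                  provenance = "BLOCK_STRUCTURE: last block misses chromEnd"),
    bed_test_case("other-trailing_comma_blocks", 12, "pass", {
      recs <- at(12, "other-trailing_comma_blocks")
      recs <- lapply(recs, function(r) { r[11] <- paste0(r[11], ",")
                                         r[12] <- paste0(r[12], ","); r })
      tab_lines(recs)
    }, provenance = "UCSC-style trailing comma in block lists")
  )
}

#' All corpus test cases, in memory
#'
#' Expands every base case across the BED variants and appends the one-off
#' cases. Fully deterministic: no randomness is involved.
#'
#' @return named list of [bed_test_case()] objects; names are
#'   `"bed<n>/<id>"`. The list has exactly 92 elements.
#' @examples
#' length(corpus_cases())  # 92
#' @export
corpus_cases <- function() {
  cases <- list()
  for (base in expanded_bases()) {
    for (n in CORPUS_VARIANTS[CORPUS_VARIANTS >= base$n]) {
      cases[[length(cases) + 1L]] <- expand_case(base, n)
    }
  }
  cases <- c(cases, single_cases())
  names(cases) <- vapply(cases, function(x) sprintf("bed%d/%s", x$n, x$id),
                         character(1))
  stopifnot(!anyDuplicated(names(cases)))
  cases
}

#' Write the conformance corpus to disk
#'
#' Lays the 92 cases out as
#' `<dir>/bed<n>/{expected_pass,expected_fail}/<id>.bed` plus a
#' `manifest.tsv`. Two runs produce byte-identical trees.
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest: a data frame of class `corpus_manifest`
#'   with columns `id`, `variant`, `expectation`, `dialect`, `file`
#'   (relative path) and `provenance`.
#' @export
generate_corpus <- function(dir) {
  cases <- corpus_cases()
  rows <- lapply(cases, function(case) {
    sub_dir <- file.path(sprintf("bed%d", case$n),
                         paste0("expected_", case$expectation))
    data.frame(id = sprintf("bed%d/%s", case$n, case$id),
               variant = case$n, expectation = case$expectation,
               dialect = case$dialect,
               file = file.path(sub_dir, paste0(case$id, ".bed")),
               provenance = case$provenance, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, c(rows, make.row.names = FALSE))

  for (i in seq_along(cases)) {
    path <- file.path(dir, manifest$file[i])
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    con <- file(path, open = "wb")  # byte-stable across platforms
    writeLines(cases[[i]]$content, con, sep = "\n", useBytes = TRUE)
    close(con)
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  class(manifest) <- c("corpus_manifest", "data.frame")
  invisible(manifest)
}

#' Read a corpus manifest back from disk
#'
#' @param dir the corpus directory written by [generate_corpus()].
#' @return the `corpus_manifest` data frame.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.tsv")
  if (!file.exists(path)) {
    bedcert_stop("IO_ERROR", sprintf("no manifest.tsv under '%s'", dir))
  }
  manifest <- utils::read.table(path, sep = "\t", header = TRUE,
                                colClasses = "character")
  manifest$variant <- as.integer(manifest$variant)
  class(manifest) <- c("corpus_manifest", "data.frame")
  manifest
}

#' Per-variant expected-pass / expected-fail counts
#'
#' @param manifest a `corpus_manifest`.
#' @return data frame with columns `variant`, `n_pass`, `n_fail`, `total`.
#' @export
corpus_summary <- function(manifest) {
  sp <- split(manifest$expectation, manifest$variant)
  out <- data.frame(variant = as.integer(names(sp)),
                    n_pass = vapply(sp, function(x) sum(x == "pass"), 0L),
                    n_fail = vapply(sp, function(x) sum(x == "fail"), 0L),
                    row.names = NULL)
  out$total <- out$n_pass + out$n_fail
  out[order(out$variant), ]
}

#' Write small auxiliary fixtures for secondary-input tools
#'
#' Some BED consumers take BED as a secondary input alongside a sequence or
#' chromosome-sizes file. This writes a deterministic mock FASTA whose
#' sequences extend beyond position 260000 (so every corpus interval lies on
#' the mock chromosomes) and a two-column chromosome-sizes file covering
#' every chromosome the corpus uses.
#'
#' @param dir output directory (created if needed).
#' @return character vector of the two file paths (FASTA, sizes), invisibly.
#' @export
make_minimal_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chroms <- c(chr7 = 300000, chrX = 280000,
              chrUn_KI270752v1 = 270000, chr7_KI270803v1_alt = 270000)
  fasta <- file.path(dir, "mock_genome.fa")
  con <- file(fasta, open = "wb")
  for (nm in names(chroms)) {
    len <- chroms[[nm]]
    seq <- strrep("ACGT", len / 4L)
    wrapped <- sub("\n$", "", gsub("(.{60})", "\\1\n", seq))
    writeLines(c(paste0(">", nm), wrapped), con, sep = "\n", useBytes = TRUE)
  }
  close(con)
  sizes <- file.path(dir, "mock_genome.chrom.sizes")
  con <- file(sizes, open = "wb")
  writeLines(paste(names(chroms), chroms, sep = "\t"), con, sep = "\n",
             useBytes = TRUE)
  close(con)
  invisible(c(fasta = fasta, sizes = sizes))
}
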