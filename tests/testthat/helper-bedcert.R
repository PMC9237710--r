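# Shared fixtures, all built in code at test time.

# generate the corpus once per test run and reuse it across files
cached_corpus_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "bedcert-test-corpus")
      generate_corpus(dir)
    }
    dir
  }
})

# the two fuzzer-generated files from the published differential-testing
# example; file 2's first line has four tab-delimited fields followed by
# three '#' comment lines
table1_file2_lines <- function() {
  c("chr12\t632184\t753365\tVx6", "#I", "#_", "#_")
}

write_bed <- function(lines, path = tempfile(fileext = ".bed")) {
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  path
}

# independent random-record generator for round-trip properties (not the
# fuzzer: the two sides of the check must not share a generator)
random_valid_record <- function() {
  n <- sample(c(3:9, 12L), 1L)
  m <- sample(0:2, 1L)
  chrom <- paste0("chr", sample(c(1:22, "X", "Y", "Un_KI270752v1"), 1L))
  start <- sample(0:1000000, 1L)
  args <- list(chrom = chrom, chromStart = start)
  if (n >= 12L) {
    k <- sample(1:3, 1L)
    sizes <- sample(1:300, k, replace = TRUE)
    gaps <- if (k > 1L) sample(0:100, k - 1L, replace = TRUE) else integer(0)
    starts <- cumsum(c(0L, (sizes + c(gaps, 0L))[-k]))
    args$chromEnd <- start + starts[k] + sizes[k]
  } else {
    args$chromEnd <- start + sample(0:2000, 1L)
  }
  rand_word <- function() {
    paste(sample(c(letters, 0:9), sample(1:12, 1L), replace = TRUE),
          collapse = "")
  }
  if (n >= 4L) args$name <- rand_word()
  if (n >= 5L) args$score <- sample(0:1000, 1L)
  if (n >= 6L) args$strand <- sample(c("+", "-", "."), 1L)
  rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
  if (n >= 7L) args$thickStart <- rint(start, args$chromEnd)
  if (n >= 8L) args$thickEnd <- rint(args$thickStart, args$chromEnd)
  if (n >= 9L) {
    args$itemRgb <- if (runif(1) < 0.5) "0" else
      sample(0:255, 3L, replace = TRUE)
  }
  if (n >= 10L) {
    args$blockCount <- k
    args$blockSizes <- sizes
    args$blockStarts <- starts
  }
  if (m > 0L) args$custom <- replicate(m, rand_word())
  list(record = do.call(bed_record, args), variant = bed_variant(n, m))
}
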