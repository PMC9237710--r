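# A parsed BED data line. Coordinates are 0-based half-open: chromStart is
# inclusive, chromEnd exclusive, so interval length = chromEnd - chromStart
# and zero-length intervals (chromStart == chromEnd) are legal.

FIELD_NAMES <- c("chrom", "chromStart", "chromEnd", "name", "score", "strand",
                 "thickStart", "thickEnd", "itemRgb", "blockCount",
                 "blockSizes", "blockStarts")

#' Construct a BED record
#'
#' The three mandatory fields define an interval on a chromosome; the nine
#' optional fields must be used as an ordered prefix ("all fields preceding
#' the last field used must contain values"), so e.g. a record with a
#' `strand` must also carry `name` and `score`. Coordinates are stored as
#' doubles (exact for values below 2^53).
#'
#' @param chrom chromosome or scaffold name.
#' @param chromStart,chromEnd 0-based half-open interval; `chromStart <= chromEnd`.
#' @param name optional feature label (no whitespace, at most 255 characters).
#' @param score optional integer in 0--1000.
#' @param strand optional `"+"`, `"-"` or `"."`.
#' @param thickStart,thickEnd optional sub-interval drawn "thick" by genome
#'   browsers; must satisfy `chromStart <= thickStart <= thickEnd <= chromEnd`.
#' @param itemRgb optional display colour: the string `"0"` or an integer
#'   vector of length 3 with entries in 0--255.
#' @param blockCount,blockSizes,blockStarts optional exon-style block
#'   structure; the two lists must each have `blockCount` entries,
#'   `blockStarts` are relative to `chromStart`, the first start is 0 and the
#'   last block ends at `chromEnd - chromStart`.
#' @param custom character vector of trailing custom-field values (BEDn+m).
#' @return an object of class `bed_record`.
#' @examples
#' bed_record("chr1", 250000, 250100)
#' bed_record("chr1", 250000, 250100, name = "x", score = 500, strand = "+")
#' @export
bed_record <- function(chrom, chromStart, chromEnd, name = NULL, score = NULL,
                       strand = NULL, thickStart = NULL, thickEnd = NULL,
                       itemRgb = NULL, blockCount = NULL, blockSizes = NULL,
                       blockStarts = NULL, custom = character()) {
  rec <- list(chrom = as.character(chrom),
              chromStart = as.numeric(chromStart),
              chromEnd = as.numeric(chromEnd),
              name = if (!is.null(name)) as.character(name),
              score = if (!is.null(score)) as.numeric(score),
              strand = if (!is.null(strand)) as.character(strand),
              thickStart = if (!is.null(thickStart)) as.numeric(thickStart),
              thickEnd = if (!is.null(thickEnd)) as.numeric(thickEnd),
              itemRgb = if (!is.null(itemRgb)) {
                if (is.character(itemRgb)) itemRgb else as.numeric(itemRgb)
              },
              blockCount = if (!is.null(blockCount)) as.numeric(blockCount),
              blockSizes = if (!is.null(blockSizes)) as.numeric(blockSizes),
              blockStarts = if (!is.null(blockStarts)) as.numeric(blockStarts),
              custom = as.character(custom))

  present <- !vapply(rec[FIELD_NAMES], is.null, logical(1))
  if (any(!present[1:3])) {
    bedcert_stop("MISSING_FIELD", "chrom, chromStart and chromEnd are mandatory")
  }
  # optional fields form a prefix: no gaps allowed
  last_used <- max(which(present))
  if (!all(present[seq_len(last_used)])) {
    gap <- FIELD_NAMES[which(!present[seq_len(last_used)])[1]]
    bedcert_stop("MISSING_FIELD",
                 sprintf("field '%s' must be given before later fields", gap))
  }
  if (rec$chromStart > rec$chromEnd) {
    bedcert_stop("COORD_ORDER",
                 sprintf("chromStart %s > chromEnd %s",
                         fmt_int(rec$chromStart), fmt_int(rec$chromEnd)))
  }
  if (!is.null(rec$blockCount)) {
    if (length(rec$blockSizes) != rec$blockCount ||
        length(rec$blockStarts) != rec$blockCount) {
      bedcert_stop("BLOCK_LIST_LENGTH",
                   sprintf("blockSizes/blockStarts must each have %s entries",
                           fmt_int(rec$blockCount)))
    }
  }
  structure(rec, n_fields = last_used, class = "bed_record")
}

#' Number of standard fields present in a record
#' @param record a [bed_record()].
#' @return integer in 3--12.
#' @export
n_fields <- function(record) {
  stopifnot(inherits(record, "bed_record"))
  attr(record, "n_fields")
}

# integers as plain decimal text, never scientific notation
fmt_int <- function(x) {
  format(x, scientific = FALSE, trim = TRUE)
}

fmt_field <- function(record, name) {
  v <- record[[name]]
  switch(name,
    chrom = , name = , strand = v,
    itemRgb = if (is.character(v)) v else paste(fmt_int(v), collapse = ","),
    blockSizes = , blockStarts = paste(fmt_int(v), collapse = ","),
    fmt_int(v)  # all plain integer fields
  )
}

#' Serialize a BED record to one text line
#'
#' Emits exactly `n + m` delimiter-separated fields for the requested
#' variant. Space delimiting is only legal when no field value itself
#' contains a space.
#'
#' @param record a [bed_record()].
#' @param variant a [bed_variant()]; the record must carry at least `n`
#'   standard fields and exactly `m` custom fields.
#' @param delimiter `"tab"` or `"space"`.
#' @return a single line of text (no trailing newline).
#'   Errors: `DELIMITER_CONFLICT` if space delimiting is requested while a
#'   field contains a space; `MISSING_FIELD` if the record is too short for
#'   the variant.
#' @examples
#' r <- bed_record("chr1", 250000, 250100)
#' serialize_record(r, bed_variant(3))
#' @export
serialize_record <- function(record, variant, delimiter = c("tab", "space")) {
  delimiter <- match.arg(delimiter)
  stopifnot(inherits(record, "bed_record"), inherits(variant, "bed_variant"))
  if (n_fields(record) < variant$n) {
    bedcert_stop("MISSING_FIELD",
                 sprintf("record has %d standard fields, %s needs %d",
                         n_fields(record), format(variant), variant$n))
  }
  if (length(record$custom) != variant$m) {
    bedcert_stop("MISSING_FIELD",
                 sprintf("record has %d custom fields, %s needs %d",
                         length(record$custom), format(variant), variant$m))
  }
  fields <- c(vapply(FIELD_NAMES[seq_len(variant$n)],
                     function(nm) fmt_field(record, nm), character(1)),
              record$custom)
  if (delimiter == "space" && any(grepl("[ \t]", fields))) {
    bedcert_stop("DELIMITER_CONFLICT",
                 "space delimiter requested but a field contains whitespace")
  }
  paste(fields, collapse = if (delimiter == "tab") "\t" else " ")
}

#' Parse already-split fields into a BED record
#'
#' Strict parse: the fields are validated with [validate_line()] first and
#' the first error aborts with its code. The inverse of
#' [serialize_record()]: for any valid record `r`,
#' `parse_record(split_fields(serialize_record(r, v), d), v)` equals `r`.
#'
#' @param fields character vector of field tokens (from [split_fields()]).
#' @param variant a [bed_variant()]; defaults to strict detection from the
#'   field count.
#' @return a [bed_record()].
#' @export
parse_record <- function(fields, variant = NULL) {
  if (is.null(variant)) variant <- detect_variant(length(fields))
  issues <- validate_line(fields, variant)
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L) {
    bedcert_stop(errs$code[1], errs$message[1])
  }
  std <- fields[seq_len(variant$n)]
  args <- list(chrom = std[1], chromStart = as.numeric(std[2]),
               chromEnd = as.numeric(std[3]))
  if (variant$n >= 4L) args$name <- std[4]
  if (variant$n >= 5L) args$score <- as.numeric(std[5])
  if (variant$n >= 6L) args$strand <- std[6]
  if (variant$n >= 7L) args$thickStart <- as.numeric(std[7])
  if (variant$n >= 8L) args$thickEnd <- as.numeric(std[8])
  if (variant$n >= 9L) {
    args$itemRgb <- if (identical(std[9], "0")) "0" else
      as.numeric(strsplit(std[9], ",", fixed = TRUE)[[1]])
  }
  if (variant$n >= 10L) args$blockCount <- as.numeric(std[10])
  if (variant$n >= 11L) args$blockSizes <- parse_comma_list(std[11])
  if (variant$n >= 12L) args$blockStarts <- parse_comma_list(std[12])
  if (variant$m > 0L) args$custom <- fields[variant$n + seq_len(variant$m)]
  do.call(bed_record, args)
}

# comma-separated integer list; one trailing comma tolerated (UCSC style)
parse_comma_list <- function(token) {
  token <- sub(",$", "", token)
  as.numeric(strsplit(token, ",", fixed = TRUE)[[1]])
}

#' @export
format.bed_record <- function(x, ...) {
  v <- bed_variant(n_fields(x), length(x$custom))
  serialize_record(x, v)
}

#' @export
print.bed_record <- function(x, ...) {
  cat("<bed_record> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.bed_record` <- function(e1, e2) {
  isTRUE(all.equal(unclass(e1), unclass(e2), check.attributes = FALSE))
}
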