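# BED variant designations: standard BEDn (n in {3..9, 12}) and custom
# BEDn+m (first n standard fields followed by m user-defined fields).

#' Construct a BED variant designation
#'
#' A variant records how many standard fields (`n`) and custom fields (`m`) a
#' file carries. Standard variants have `m = 0` and
#' `n` in \{3, 4, 5, 6, 7, 8, 9, 12\}: BED10 and BED11 are prohibited by the
#' BED specification, so they can never be standard.
#'
#' @param n number of standard fields, integer in 3--12.
#' @param m number of trailing custom fields, non-negative integer.
#' @return an object of class `bed_variant` with fields `n`, `m`, `standard`.
#' @examples
#' bed_variant(5)        # standard BED5
#' bed_variant(9, 1)     # custom BED9+1
#' bed_variant(10)$standard  # FALSE: BED10 is never standard
#' @export
bed_variant <- function(n, m = 0L) {
  n <- as.integer(n)
  m <- as.integer(m)
  stopifnot(length(n) == 1L, length(m) == 1L, !is.na(n), !is.na(m))
  if (n < 3L || n > 12L) {
    bedcert_stop("MALFORMED_FIELD_COUNT",
                 sprintf("BED variant must have 3-12 standard fields, got %d", n))
  }
  if (m < 0L) {
    bedcert_stop("MALFORMED_FIELD_COUNT",
                 sprintf("custom field count must be non-negative, got %d", m))
  }
  structure(
    list(n = n, m = m, standard = (m == 0L && n %in% STANDARD_N)),
    class = "bed_variant"
  )
}

STANDARD_N <- c(3L, 4L, 5L, 6L, 7L, 8L, 9L, 12L)

#' The eight standard BED variants
#'
#' @return list of `bed_variant` objects: BED3--BED9 and BED12.
#' @examples
#' length(standard_variants())  # 8
#' @export
standard_variants <- function() {
  lapply(STANDARD_N, bed_variant)
}

#' @export
format.bed_variant <- function(x, ...) {
  if (x$m == 0L) sprintf("BED%d", x$n) else sprintf("BED%d+%d", x$n, x$m)
}

#' @export
print.bed_variant <- function(x, ...) {
  cat(format(x), if (x$standard) "(standard)" else "(custom)", "\n")
  invisible(x)
}

#' @export
`==.bed_variant` <- function(e1, e2) {
  e1$n == e2$n && e1$m == e2$m
}

#' Determine the BED variant implied by a field count
#'
#' In strict mode a line's field count fixes the standard variant: counts
#' 3--9 and 12 map to the matching BEDn; 10 and 11 are prohibited; anything
#' outside 3--12 is malformed. In custom mode the caller declares how many
#' leading fields are standard and the remainder are custom (BEDn+m).
#'
#' @param field_count observed number of whitespace-delimited fields.
#' @param mode `"strict"` (standard variants only) or `"custom"`.
#' @param declared_n in custom mode, the declared number of standard fields
#'   (3--12, at most `field_count`); defaults to `min(field_count, 12)`.
#' @return a [bed_variant()].
#'   Errors (classed, see [error_code()]): `MALFORMED_FIELD_COUNT` when
#'   `field_count` is outside 3--12 in strict mode; `PROHIBITED_VARIANT` for
#'   10 or 11 fields in strict mode.
#' @examples
#' detect_variant(5)                          # BED5
#' error_code(detect_variant(10))             # "PROHIBITED_VARIANT"
#' detect_variant(10, "custom", declared_n = 9)  # BED9+1
#' @export
detect_variant <- function(field_count, mode = c("strict", "custom"),
                           declared_n = NULL) {
  mode <- match.arg(mode)
  field_count <- as.integer(field_count)
  stopifnot(length(field_count) == 1L, !is.na(field_count), field_count >= 0L)

  if (mode == "strict") {
    if (field_count < 3L || field_count > 12L) {
      bedcert_stop("MALFORMED_FIELD_COUNT",
                   sprintf("%d fields: a BED line has 3-12 fields", field_count))
    }
    if (field_count %in% c(10L, 11L)) {
      bedcert_stop("PROHIBITED_VARIANT",
                   sprintf("BED%d is prohibited by the BED specification",
                           field_count))
    }
    return(bed_variant(field_count))
  }

  # custom mode
  if (is.null(declared_n)) declared_n <- min(field_count, 12L)
  declared_n <- as.integer(declared_n)
  if (declared_n < 3L || declared_n > 12L || declared_n > field_count) {
    bedcert_stop("MALFORMED_FIELD_COUNT",
                 sprintf("declared n = %d invalid for %d fields",
                         declared_n, field_count))
  }
  bed_variant(declared_n, field_count - declared_n)
}
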