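# Badges and summary tables: turn result matrices into one-decimal
# per-variant percentages, a sortable tool-by-variant table, and simple SVG
# emblems a developer can embed in documentation.

#' Format a proportion as a one-decimal percentage
#'
#' Rounds half-up at one decimal, so 0.78787... renders as `"78.8%"`.
#'
#' @param proportion real number in `[0, 1]`.
#' @return e.g. `"78.8%"`.
#' @examples
#' format_percentage(26/33)  # "78.8%"
#' format_percentage(1)      # "100.0%"
#' @export
format_percentage <- function(proportion) {
  stopifnot(is.numeric(proportion), proportion >= 0, proportion <= 1)
  sprintf("%.1f%%", floor(proportion * 1000 + 0.5) / 10)
}

badge_color <- function(pct) {
  if (pct >= 90) "#4c1" else if (pct >= 70) "#dfb317" else "#e05d44"
}

badge_svg <- function(label, value, color) {
  # flat two-panel badge; widths scale with text length
  wl <- 12 + 7 * nchar(label)
  wv <- 12 + 7 * nchar(value)
  sprintf(paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="20">',
    '<rect width="%d" height="20" fill="#555"/>',
    '<rect x="%d" width="%d" height="20" fill="%s"/>',
    '<g fill="#fff" text-anchor="middle" ',
    'font-family="DejaVu Sans,Verdana,sans-serif" font-size="11">',
    '<text x="%d" y="14">%s</text><text x="%d" y="14">%s</text>',
    '</g></svg>'),
    wl + wv, wl, wl, wv, color,
    wl %/% 2, label, wl + wv %/% 2, value)
}

#' Build BED badges from per-variant scores
#'
#' Emits one "BED parser" badge listing the variants the tool supports plus
#' one performance badge per scored variant, each showing the one-decimal
#' percentage of tests that behaved as expected. Rendering is
#' deterministic; colors are bucketed (green at or above 90%, yellow at or
#' above 70%, red below).
#'
#' @param scores data frame from [score_by_variant()] (possibly empty).
#' @param supported list of [bed_variant()]s (or integer vector of `n`) the
#'   tool declares support for; defaults to the scored variants.
#' @param dir output directory for the `.svg` files, or `NULL` to skip
#'   rendering.
#' @return data frame of badge descriptors: `label`, `value`, `color`,
#'   `file` (`NA` when not rendered).
#' @export
make_badges <- function(scores, supported = NULL, dir = NULL) {
  if (is.null(supported)) supported <- scores$variant
  if (is.list(supported)) {
    supported <- vapply(supported, function(v) v$n, integer(1))
  }
  labels <- c("BED parser", sprintf("BED%d", scores$variant))
  values <- c(paste(sprintf("BED%d", sort(unique(supported))), collapse = " "),
              vapply(scores$proportion, format_percentage, character(1)))
  colors <- c("#007ec6",
              vapply(scores$proportion * 100, badge_color, character(1)))
  files <- rep(NA_character_, length(labels))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    slug <- c("bed-parser", sprintf("bed%d", scores$variant))
    for (i in seq_along(labels)) {
      files[i] <- file.path(dir, paste0(slug[i], ".svg"))
      writeLines(badge_svg(labels[i], values[i], colors[i]), files[i])
    }
  }
  data.frame(label = labels, value = values, color = colors, file = files,
             stringsAsFactors = FALSE)
}

#' Tool-by-variant summary table
#'
#' One row per tool, one column per BED variant, cells holding the
#' proportion of tests that behaved as expected. Rows are sorted ascending
#' by BED3 performance, then by each subsequent variant.
#'
#' @param results one data frame from [evaluate_tool()], or a list of them
#'   (one per tool); they are concatenated.
#' @param file optional path: when given the table is also written as TSV.
#' @return data frame with column `tool` then `BED3`...`BED12`.
#' @export
summary_table <- function(results, file = NULL) {
  if (is.data.frame(results)) results <- list(results)
  results <- do.call(rbind, results)
  variants <- sort(unique(results$variant))
  tools <- unique(results$tool)
  tab <- data.frame(tool = tools, stringsAsFactors = FALSE)
  for (v in variants) {
    col <- vapply(tools, function(tl) {
      sub <- results[results$tool == tl & results$variant == v, ]
      if (nrow(sub) == 0L) NA_real_ else mean(sub$behaved_as_expected)
    }, numeric(1))
    tab[[sprintf("BED%d", v)]] <- col
  }
  ord <- do.call(order, tab[, -1, drop = FALSE])
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(file)) {
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tab
}
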