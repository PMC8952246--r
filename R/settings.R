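#' Session settings
#'
#' Collects the handful of knobs that control how tables are read and how
#' plots order their x axis: the sample-name separator, an explicit ordering
#' of x-axis factor levels, the unit of the quantification values, the field
#' separators used for the two input tables, and the delimiter used to split
#' multi-valued annotation cells.
#'
#' @param separator single character separating the factor tokens inside a
#'   sample column name (default `"."`).
#' @param x_value_order character vector giving the display order of x-axis
#'   factor levels; `NULL` means first-appearance order.
#' @param unit unit label of the quantification values (e.g. `"TPM"`).
#' @param table_field_separators named list with entries `expression` and
#'   `info`, the field delimiters of the two input tables.
#' @param multivalue_delimiter delimiter splitting multi-valued annotation
#'   cells (e.g. several MapMan bins in one cell).
#' @return An object of class `gxp_settings`.
#' @export
gxp_settings <- function(separator = ".",
                         x_value_order = NULL,
                         unit = "",
                         table_field_separators = list(expression = "\t", info = "\t"),
                         multivalue_delimiter = ",") {
  if (!is.character(separator) || length(separator) != 1L || nchar(separator) != 1L) {
    stop("`separator` must be a single character", call. = FALSE)
  }
  if (!is.null(x_value_order)) x_value_order <- as.character(x_value_order)
  stopifnot(is.list(table_field_separators))
  if (is.null(table_field_separators$expression)) table_field_separators$expression <- "\t"
  if (is.null(table_field_separators$info)) table_field_separators$info <- "\t"
  structure(
    list(
      separator = separator,
      x_value_order = x_value_order,
      unit = as.character(unit),
      table_field_separators = table_field_separators[c("expression", "info")],
      multivalue_delimiter = as.character(multivalue_delimiter)
    ),
    class = "gxp_settings"
  )
}

#' @export
print.gxp_settings <- function(x, ...) {
  cat("gxp settings\n")
  cat("  separator:            ", dQuote(x$separator), "\n", sep = "")
  cat("  unit:                 ", if (nzchar(x$unit)) x$unit else "<none>", "\n", sep = "")
  cat("  x-value order:        ",
      if (is.null(x$x_value_order)) "<first appearance>" else paste(x$x_value_order, collapse = ", "),
      "\n", sep = "")
  cat("  multivalue delimiter: ", dQuote(x$multivalue_delimiter), "\n", sep = "")
  invisible(x)
}
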