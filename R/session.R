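#' Assemble a session bundle
#'
#' A session bundle holds everything needed to resume or share an analysis:
#' the settings, the expression matrix, the optional info table, and any
#' plot specifications and analysis results produced so far.
#'
#' @param settings a [gxp_settings()] object.
#' @param expression a `gxp_expression`.
#' @param info a `gxp_info` or `NULL`.
#' @param plot_specs list of plot specification objects.
#' @param analysis_results list of analysis result objects (distance
#'   matrices, dendrograms, PCA results, overrepresentation tables).
#' @return A `gxp_session` object.
#' @export
gxp_session <- function(settings, expression, info = NULL,
                        plot_specs = list(), analysis_results = list()) {
  stopifnot(inherits(settings, "gxp_settings"), inherits(expression, "gxp_expression"))
  if (!is.null(info)) stopifnot(inherits(info, "gxp_info"))
  structure(
    list(
      settings = settings, expression = expression, info = info,
      plot_specs = plot_specs, analysis_results = analysis_results
    ),
    class = "gxp_session"
  )
}

#' @export
print.gxp_session <- function(x, ...) {
  cat(sprintf(
    "gxp session: %d x %d expression matrix, %s info table, %d plot(s), %d analysis result(s)\n",
    nrow(x$expression$values), ncol(x$expression$values),
    if (is.null(x$info)) "no" else "with", length(x$plot_specs), length(x$analysis_results)
  ))
  invisible(x)
}

GXP_SCHEMA_VERSION <- "1.0"

#' Export a session to a database bundle
#'
#' Writes a zip archive containing `GXP_settings.json`, the quantification
#' and (if present) information tables as full-precision TSV, and JSON
#' documents for plot specifications and analysis results. The archive's
#' schema is versioned; [import_database()] refuses unknown versions.
#' Output is written atomically (temp file + rename).
#'
#' @param session a `gxp_session`.
#' @param path output path of the bundle (conventionally `*.zip`).
#' @return `path`, invisibly.
#' @export
export_database <- function(session, path) {
  stopifnot(inherits(session, "gxp_session"))
  s <- session$settings
  settings_json <- jsonlite::toJSON(
    list(
      schema_version = GXP_SCHEMA_VERSION,
      separator = s$separator,
      x_value_order = s$x_value_order,
      unit = s$unit,
      table_field_separators = s$table_field_separators,
      multivalue_delimiter = s$multivalue_delimiter
    ),
    auto_unbox = TRUE, null = "null", pretty = TRUE, digits = NA
  )

  tmp_expr <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp_expr), add = TRUE)
  write_quantification_table(session$expression, tmp_expr,
    delimiter = s$table_field_separators$expression
  )

  files <- list(
    "GXP_settings.json" = charToRaw(paste0(settings_json, "\n")),
    "expression.tsv" = readBin(tmp_expr, "raw", file.size(tmp_expr))
  )

  manifest <- list(
    schema_version = GXP_SCHEMA_VERSION,
    expression_unit = session$expression$unit,
    has_info = !is.null(session$info),
    n_plot_specs = length(session$plot_specs),
    n_analysis_results = length(session$analysis_results)
  )

  if (!is.null(session$info)) {
    tmp_info <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp_info), add = TRUE)
    write_info_table(session$info, tmp_info, delimiter = s$table_field_separators$info)
    files[["info.tsv"]] <- readBin(tmp_info, "raw", file.size(tmp_info))
    kinds <- vapply(session$info$columns, `[[`, "", "kind")
    manifest$info_categorical_columns <- I(names(kinds)[kinds == "categorical"])
  }

  # plot specs and analysis results use jsonlite's type-preserving JSON
  # serialization; 17 significant digits round-trip IEEE doubles exactly
  files[["plot_specs.json"]] <-
    charToRaw(jsonlite::serializeJSON(session$plot_specs, digits = I(17)))
  files[["analysis_results.json"]] <-
    charToRaw(jsonlite::serializeJSON(session$analysis_results, digits = I(17)))
  files[["manifest.json"]] <-
    charToRaw(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE))

  tmp_zip <- tempfile(tmpdir = dirname(path), fileext = ".zip.part")
  write_zip_archive(files, tmp_zip)
  if (!file.rename(tmp_zip, path)) {
    unlink(tmp_zip)
    stop(sprintf("cannot write bundle to %s", path), call. = FALSE)
  }
  invisible(path)
}

#' Import a session from a database bundle
#'
#' Restores the full session written by [export_database()]. The archive
#' must contain `GXP_settings.json` and carry a recognized schema version.
#'
#' @param path path of the bundle.
#' @return A `gxp_session`.
#' @export
import_database <- function(path) {
  if (!file.exists(path)) stop(sprintf("bundle not found: %s", path), call. = FALSE)
  exdir <- tempfile("gxp_import_")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  members <- tryCatch(
    utils::unzip(path, exdir = exdir),
    error = function(e) stop(sprintf("corrupted bundle %s: %s", path, conditionMessage(e)), call. = FALSE),
    warning = function(w) stop(sprintf("corrupted bundle %s: %s", path, conditionMessage(w)), call. = FALSE)
  )
  have <- basename(members)
  if (!"GXP_settings.json" %in% have) {
    stop(sprintf("not a GXP database bundle (missing GXP_settings.json): %s", path), call. = FALSE)
  }
  sj <- jsonlite::fromJSON(file.path(exdir, "GXP_settings.json"), simplifyVector = TRUE)
  if (!identical(sj$schema_version, GXP_SCHEMA_VERSION)) {
    stop(sprintf(
      "unsupported bundle schema version %s (this build reads %s)",
      sj$schema_version, GXP_SCHEMA_VERSION
    ), call. = FALSE)
  }
  settings <- gxp_settings(
    separator = sj$separator,
    x_value_order = sj$x_value_order,
    unit = sj$unit,
    table_field_separators = as.list(sj$table_field_separators),
    multivalue_delimiter = sj$multivalue_delimiter
  )
  manifest <- jsonlite::fromJSON(file.path(exdir, "manifest.json"), simplifyVector = TRUE)

  expression <- load_quantification_table(
    file.path(exdir, "expression.tsv"),
    delimiter = settings$table_field_separators$expression,
    separator = settings$separator,
    unit = manifest$expression_unit
  )
  info <- NULL
  if (isTRUE(manifest$has_info)) {
    info <- load_info_table(
      file.path(exdir, "info.tsv"),
      delimiter = settings$table_field_separators$info,
      multivalue_delimiter = settings$multivalue_delimiter,
      categorical_columns = manifest$info_categorical_columns
    )
  }
  plot_specs <- jsonlite::unserializeJSON(
    readChar(file.path(exdir, "plot_specs.json"),
             file.size(file.path(exdir, "plot_specs.json")))
  )
  analysis_results <- jsonlite::unserializeJSON(
    readChar(file.path(exdir, "analysis_results.json"),
             file.size(file.path(exdir, "analysis_results.json")))
  )
  gxp_session(settings, expression, info,
    plot_specs = plot_specs, analysis_results = analysis_results
  )
}
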