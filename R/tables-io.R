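#' Parse a factor-encoding sample column name
#'
#' Sample columns of a quantification table encode the experimental design in
#' their names: tokens separated by `separator`, where the last token is the
#' replicate index, the second-to-last the x-axis factor level (e.g. the
#' treatment), and any leading tokens are group-factor levels (e.g. species or
#' genotype). `"S_lycopersicum.ctrl1.1"` therefore decomposes into group
#' `"S_lycopersicum"`, x value `"ctrl1"` and replicate `"1"`.
#'
#' Parsing is anchored on the right so that any number of group factors
#' (including zero, as in `"cold.3"`) is supported without a token-count
#' parameter.
#'
#' @param raw the column name.
#' @param separator single-character token separator (default `"."`).
#' @return A `gxp_sample_key`: list with `raw_name`, `group_values`
#'   (character, possibly empty), `x_value`, `replicate_id`.
#' @examples
#' parse_sample_name("S_lycopersicum.ctrl1.1")
#' parse_sample_name("A*B*eL*2", separator = "*")
#' @export
parse_sample_name <- function(raw, separator = ".") {
  stopifnot(is.character(raw), length(raw) == 1L)
  tokens <- strsplit(raw, separator, fixed = TRUE)[[1]]
  if (length(tokens) < 2L || any(!nzchar(tokens[c(length(tokens) - 1L, length(tokens))]))) {
    stop(sprintf(
      "malformed sample name %s: need at least <x-value>%s<replicate>",
      dQuote(raw), separator
    ), call. = FALSE)
  }
  n <- length(tokens)
  structure(
    list(
      raw_name = raw,
      group_values = if (n > 2L) tokens[seq_len(n - 2L)] else character(0),
      x_value = tokens[n - 1L],
      replicate_id = tokens[n]
    ),
    class = "gxp_sample_key"
  )
}

#' Reassemble a sample name from its parsed key
#'
#' Inverse of [parse_sample_name()]: joins group values, x value and replicate
#' id with `separator`.
#'
#' @param key a `gxp_sample_key`.
#' @param separator token separator used when the name was parsed.
#' @return The raw column name.
#' @export
join_sample_name <- function(key, separator = ".") {
  paste(c(key$group_values, key$x_value, key$replicate_id), collapse = separator)
}

#' @export
print.gxp_sample_key <- function(x, ...) {
  cat(sprintf(
    "sample %s: groups=[%s] x=%s rep=%s\n", x$raw_name,
    paste(x$group_values, collapse = ","), x$x_value, x$replicate_id
  ))
  invisible(x)
}

# Shared reader for both input tables: header + first column of identifiers.
read_id_table <- function(path, delimiter) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path,
    header = TRUE, sep = delimiter, quote = "\"",
    check.names = FALSE, colClasses = "character",
    comment.char = "", stringsAsFactors = FALSE,
    na.strings = NULL
  )
  if (nrow(df) == 0L || ncol(df) < 1L) stop(sprintf("empty table: %s", path), call. = FALSE)
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(sprintf(
      "duplicate identifier(s) in %s: %s", path,
      paste(dQuote(utils::head(dup, 5L)), collapse = ", ")
    ), call. = FALSE)
  }
  cn <- colnames(df)[-1L]
  dupc <- unique(cn[duplicated(cn)])
  if (length(dupc) > 0L) {
    stop(sprintf("duplicate column name(s): %s", paste(dQuote(dupc), collapse = ", ")),
      call. = FALSE
    )
  }
  df
}

#' Construct an expression matrix
#'
#' Low-level constructor used by [load_quantification_table()] and the fixture
#' generator. `values` rows are quantified entities (transcripts or
#' metabolites), columns are samples whose names follow the factor grammar of
#' [parse_sample_name()].
#'
#' @param values numeric matrix with rownames = entity ids and colnames =
#'   raw sample names.
#' @param separator sample-name token separator.
#' @param unit unit label for the values.
#' @return A `gxp_expression` object: `values`, `samples` (list of
#'   `gxp_sample_key`), `unit`, `separator`.
#' @export
gxp_expression <- function(values, separator = ".", unit = "") {
  stopifnot(is.matrix(values), is.numeric(values))
  ids <- rownames(values)
  if (is.null(ids) || anyDuplicated(ids)) stop("entity ids must be unique rownames", call. = FALSE)
  raw <- colnames(values)
  if (is.null(raw) || anyDuplicated(raw)) stop("sample names must be unique colnames", call. = FALSE)
  if (anyNA(values)) stop("missing values are not allowed in the quantification matrix", call. = FALSE)
  samples <- lapply(raw, parse_sample_name, separator = separator)
  structure(
    list(values = values, samples = samples, unit = as.character(unit), separator = separator),
    class = "gxp_expression"
  )
}

#' @export
print.gxp_expression <- function(x, ...) {
  cat(sprintf(
    "gxp expression matrix: %d entities x %d samples%s\n",
    nrow(x$values), ncol(x$values),
    if (nzchar(x$unit)) paste0(" [", x$unit, "]") else ""
  ))
  xv <- unique(vapply(x$samples, `[[`, "", "x_value"))
  cat("  x values: ", paste(xv, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.gxp_expression <- function(x) dim(x$values)

#' Entity identifiers of an expression matrix or info table
#' @param x a `gxp_expression` or `gxp_info` object.
#' @return Character vector of identifiers in row order.
#' @export
entity_ids <- function(x) {
  if (inherits(x, "gxp_expression")) return(rownames(x$values))
  if (inherits(x, "gxp_info")) return(x$entity_ids)
  stop("unsupported type", call. = FALSE)
}

#' Load a quantification table
#'
#' Reads a delimited text table whose first column holds unique entity
#' identifiers and whose remaining column names encode the experimental
#' design (see [parse_sample_name()]). Every quantification cell must parse
#' as a finite number; missing values are rejected so that upstream problems
#' surface immediately.
#'
#' @param path file path.
#' @param delimiter field delimiter (default tab).
#' @param separator sample-name token separator.
#' @param unit unit label carried along to plots.
#' @return A `gxp_expression` object.
#' @export
load_quantification_table <- function(path, delimiter = "\t", separator = ".", unit = "") {
  df <- read_id_table(path, delimiter)
  if (ncol(df) < 2L) stop(sprintf("no sample columns in %s", path), call. = FALSE)
  ids <- df[[1L]]
  raw_names <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(raw_names),
                 dimnames = list(ids, raw_names))
  for (j in seq_along(raw_names)) {
    cell <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) | !nzchar(trimws(cell)))
    if (length(bad) > 0L) {
      stop(sprintf(
        "non-numeric quantification cell %s at row %s (id %s), column %s",
        dQuote(cell[bad[1L]]), bad[1L], dQuote(ids[bad[1L]]), dQuote(raw_names[j])
      ), call. = FALSE)
    }
    vals[, j] <- num
  }
  gxp_expression(vals, separator = separator, unit = unit)
}

#' Write an expression matrix back to a delimited file
#'
#' Values are formatted with full precision (`%.17g`) so that a write/read
#' cycle reproduces the matrix bit-exactly.
#'
#' @param expr a `gxp_expression`.
#' @param path output path.
#' @param delimiter field delimiter.
#' @param id_header header of the identifier column.
#' @return `path`, invisibly.
#' @export
write_quantification_table <- function(expr, path, delimiter = "\t", id_header = "identifier") {
  header <- paste(c(id_header, colnames(expr$values)), collapse = delimiter)
  rows <- vapply(seq_len(nrow(expr$values)), function(i) {
    paste(c(rownames(expr$values)[i], sprintf("%.17g", expr$values[i, ])), collapse = delimiter)
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Load an information table
#'
#' Reads the optional annotation table: first column holds entity identifiers
#' matching the quantification table, subsequent columns carry free-text,
#' categorical (possibly multi-valued) or numeric annotations. A column is
#' typed numeric iff every non-empty cell parses as a number; other columns
#' are `categorical` when named in `categorical_columns` and `text` otherwise
#' (search and term indexing treat the two alike).
#'
#' @param path file path.
#' @param delimiter field delimiter (default tab).
#' @param multivalue_delimiter delimiter used to split multi-valued
#'   categorical cells on demand (e.g. by [build_term_index()]).
#' @param categorical_columns names of columns to flag as categorical.
#' @return A `gxp_info` object: `entity_ids` plus a named list `columns` of
#'   annotation columns (`name`, `kind`, `cells`, `multivalue_delimiter`).
#' @export
load_info_table <- function(path, delimiter = "\t", multivalue_delimiter = ",",
                            categorical_columns = NULL) {
  df <- read_id_table(path, delimiter)
  ids <- df[[1L]]
  cols <- list()
  for (nm in colnames(df)[-1L]) {
    cells <- df[[nm]]
    num <- suppressWarnings(as.numeric(cells))
    nonmissing <- nzchar(trimws(cells))
    kind <- if (any(nonmissing) && !anyNA(num[nonmissing])) "numeric"
            else if (nm %in% categorical_columns) "categorical"
            else "text"
    cols[[nm]] <- list(
      name = nm,
      kind = kind,
      cells = if (kind == "numeric") ifelse(nonmissing, num, NA_real_) else cells,
      multivalue_delimiter = if (kind == "numeric") NULL else multivalue_delimiter
    )
  }
  structure(list(entity_ids = ids, columns = cols), class = "gxp_info")
}

#' @export
print.gxp_info <- function(x, ...) {
  kinds <- vapply(x$columns, `[[`, "", "kind")
  cat(sprintf("gxp info table: %d entities, %d columns\n", length(x$entity_ids), length(x$columns)))
  for (nm in names(x$columns)) cat(sprintf("  %s <%s>\n", nm, kinds[[nm]]))
  invisible(x)
}

#' Write an information table back to a delimited file
#' @param info a `gxp_info`.
#' @param path output path.
#' @param delimiter field delimiter.
#' @param id_header header of the identifier column.
#' @return `path`, invisibly.
#' @export
write_info_table <- function(info, path, delimiter = "\t", id_header = "identifier") {
  fmt_col <- function(col) {
    if (col$kind == "numeric") ifelse(is.na(col$cells), "", sprintf("%.17g", col$cells))
    else col$cells
  }
  mat <- vapply(info$columns, fmt_col, character(length(info$entity_ids)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(info$entity_ids))
  header <- paste(c(id_header, names(info$columns)), collapse = delimiter)
  rows <- vapply(seq_along(info$entity_ids), function(i) {
    paste(c(info$entity_ids[i], mat[i, ]), collapse = delimiter)
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Search entities by identifier or annotation text
#'
#' Case-insensitive substring search over entity identifiers and all text and
#' categorical annotation cells. The empty query matches everything. Results
#' preserve input row order.
#'
#' @param expr a `gxp_expression`, or `NULL` to search the info table alone.
#' @param info a `gxp_info`, or `NULL` to search identifiers alone.
#' @param query search string (fixed, not a regex).
#' @return Character vector of matching entity ids.
#' @export
search_entities <- function(expr = NULL, info = NULL, query = "") {
  if (is.null(expr) && is.null(info)) stop("need an expression matrix or an info table", call. = FALSE)
  ids <- if (!is.null(expr)) entity_ids(expr) else entity_ids(info)
  if (!nzchar(query)) return(ids)
  q <- tolower(query)
  hit <- grepl(q, tolower(ids), fixed = TRUE)
  if (!is.null(info)) {
    idx <- match(ids, info$entity_ids)
    for (col in info$columns) {
      if (col$kind == "numeric") next
      cells <- tolower(col$cells[idx])
      cells[is.na(cells)] <- ""
      hit <- hit | grepl(q, cells, fixed = TRUE)
    }
  }
  ids[hit]
}

#' Reconcile identifiers between the two input tables
#'
#' Entities present in only one table are kept in their table but excluded
#' from joint operations; a warning reports the mismatch counts.
#'
#' @param expr a `gxp_expression`.
#' @param info a `gxp_info`.
#' @return Character vector of ids present in both tables, in expression
#'   row order.
#' @export
common_entities <- function(expr, info) {
  eids <- entity_ids(expr)
  iids <- entity_ids(info)
  shared <- eids[eids %in% iids]
  n_e <- sum(!(eids %in% iids))
  n_i <- sum(!(iids %in% eids))
  if (n_e + n_i > 0L) {
    warning(sprintf(
      "%d expression-only and %d info-only identifier(s) excluded from joint operations",
      n_e, n_i
    ), call. = FALSE)
  }
  shared
}
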