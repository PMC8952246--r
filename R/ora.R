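#' Selection criteria for overrepresentation analysis
#'
#' A criterion is a conjunction of clauses. A clause either compares an
#' annotation column against a value (`<`, `<=`, `>`, `>=`, `=` on numeric
#' columns; `=` and `contains` on text/categorical columns) or fixes an
#' explicit identifier list. An entity is selected iff it satisfies every
#' clause; entities with a missing numeric cell never satisfy a numeric
#' clause.
#'
#' @param ... clauses created with [clause()] and/or [id_clause()].
#' @return A `gxp_criterion`.
#' @export
gxp_criterion <- function(...) {
  clauses <- list(...)
  if (length(clauses) == 0L) stop("a criterion needs at least one clause", call. = FALSE)
  ok <- vapply(clauses, inherits, TRUE, what = "gxp_clause")
  if (!all(ok)) stop("all arguments must be clauses", call. = FALSE)
  structure(list(clauses = clauses), class = "gxp_criterion")
}

#' @rdname gxp_criterion
#' @param column annotation column name.
#' @param comparator one of `"<"`, `"<="`, `">"`, `">="`, `"="`,
#'   `"contains"`.
#' @param value threshold (numeric columns) or string (text columns).
#' @export
clause <- function(column, comparator, value) {
  comparator <- match.arg(comparator, c("<", "<=", ">", ">=", "=", "contains"))
  structure(list(type = "compare", column = column, comparator = comparator, value = value),
            class = "gxp_clause")
}

#' @rdname gxp_criterion
#' @param ids explicit entity identifiers to select.
#' @export
id_clause <- function(ids) {
  structure(list(type = "ids", ids = as.character(ids)), class = "gxp_clause")
}

#' Parse a compact criterion string
#'
#' Accepts the CLI syntax `"column<value"`, `"column>=value"`,
#' `"column=value"` or `"column~value"` (contains). Multiple clauses can be
#' joined with `" and "`.
#'
#' @param text criterion string.
#' @return A `gxp_criterion`.
#' @export
parse_criterion <- function(text) {
  parts <- strsplit(text, "\\s+and\\s+")[[1]]
  clauses <- lapply(parts, function(p) {
    m <- regexec("^([^<>=~!]+?)\\s*(<=|>=|<|>|=|~)\\s*(.+)$", p)[[1]]
    if (m[1] == -1) stop(sprintf("cannot parse criterion clause: %s", dQuote(p)), call. = FALSE)
    col <- substr(p, m[2], m[2] + attr(m, "match.length")[2] - 1L)
    op <- substr(p, m[3], m[3] + attr(m, "match.length")[3] - 1L)
    val <- substr(p, m[4], m[4] + attr(m, "match.length")[4] - 1L)
    if (op == "~") op <- "contains"
    num <- suppressWarnings(as.numeric(val))
    clause(trimws(col), op, if (!is.na(num) && op != "contains") num else val)
  })
  do.call(gxp_criterion, clauses)
}

#' Select entities satisfying a criterion
#'
#' @param info a `gxp_info`.
#' @param criterion a `gxp_criterion` (or a string for [parse_criterion()]).
#' @return Character vector of selected entity ids in table row order.
#' @export
select_entities <- function(info, criterion) {
  stopifnot(inherits(info, "gxp_info"))
  if (is.character(criterion)) criterion <- parse_criterion(criterion)
  stopifnot(inherits(criterion, "gxp_criterion"))
  keep <- rep(TRUE, length(info$entity_ids))
  for (cl in criterion$clauses) {
    if (cl$type == "ids") {
      absent <- setdiff(cl$ids, info$entity_ids)
      if (length(absent) > 0L) {
        warning(sprintf(
          "identifier(s) not in info table ignored: %s",
          paste(dQuote(absent), collapse = ", ")
        ), call. = FALSE)
      }
      keep <- keep & (info$entity_ids %in% cl$ids)
      next
    }
    col <- info$columns[[cl$column]]
    if (is.null(col)) stop(sprintf("unknown column %s", dQuote(cl$column)), call. = FALSE)
    if (col$kind == "numeric") {
      if (cl$comparator == "contains") {
        stop(sprintf("'contains' not valid on numeric column %s", dQuote(cl$column)),
          call. = FALSE
        )
      }
      if (!is.numeric(cl$value)) {
        stop(sprintf("numeric column %s compared against non-numeric value", dQuote(cl$column)),
          call. = FALSE
        )
      }
      hit <- switch(cl$comparator,
        "<" = col$cells < cl$value,
        "<=" = col$cells <= cl$value,
        ">" = col$cells > cl$value,
        ">=" = col$cells >= cl$value,
        "=" = col$cells == cl$value
      )
      hit[is.na(hit)] <- FALSE # missing numeric cells never satisfy a clause
    } else {
      val <- as.character(cl$value)
      hit <- switch(cl$comparator,
        "=" = col$cells == val,
        "contains" = grepl(tolower(val), tolower(col$cells), fixed = TRUE),
        stop(sprintf(
          "comparator %s not valid on %s column %s",
          dQuote(cl$comparator), col$kind, dQuote(cl$column)
        ), call. = FALSE)
      )
      hit[is.na(hit)] <- FALSE
    }
    keep <- keep & hit
  }
  info$entity_ids[keep]
}

#' Index annotation terms of a column
#'
#' Splits (possibly multi-valued) annotation cells into individual terms and
#' maps each term to the set of entities carrying it. Empty cells contribute
#' nothing.
#'
#' @param info a `gxp_info`.
#' @param column name of a text or categorical column.
#' @param delimiter multi-value delimiter; `NULL` uses the column's own
#'   declared delimiter; `NA` disables splitting.
#' @return A `gxp_term_index`: named list term -> character vector of ids,
#'   with attribute `column`.
#' @export
build_term_index <- function(info, column, delimiter = NULL) {
  stopifnot(inherits(info, "gxp_info"))
  col <- info$columns[[column]]
  if (is.null(col)) stop(sprintf("unknown column %s", dQuote(column)), call. = FALSE)
  if (col$kind == "numeric") {
    stop(sprintf("cannot index numeric column %s for terms", dQuote(column)), call. = FALSE)
  }
  if (is.null(delimiter)) delimiter <- col$multivalue_delimiter
  index <- list()
  for (i in seq_along(info$entity_ids)) {
    cell <- col$cells[i]
    if (is.na(cell) || !nzchar(trimws(cell))) next
    terms <- if (!is.null(delimiter) && !is.na(delimiter) && nzchar(delimiter)) {
      trimws(strsplit(cell, delimiter, fixed = TRUE)[[1]])
    } else {
      trimws(cell)
    }
    terms <- unique(terms[nzchar(terms)])
    for (tm in terms) index[[tm]] <- c(index[[tm]], info$entity_ids[i])
  }
  structure(index[order(names(index))], class = "gxp_term_index", column = column)
}

#' Hypergeometric probability mass
#'
#' Probability of drawing exactly `k` annotated entities when `n` entities
#' are drawn without replacement from a background of `N` entities of which
#' `K` are annotated: `choose(K,k) * choose(N-K,n-k) / choose(N,n)`.
#' Computed via log-gamma for numeric stability at genome scale.
#'
#' @param k number of annotated entities drawn.
#' @param K number of annotated entities in the background.
#' @param n number of entities drawn.
#' @param N background size.
#' @return The probability (vectorized over `k`).
#' @export
hypergeom_pmf <- function(k, K, n, N) {
  stopifnot(length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (K < 0 || n < 0 || N < 0 || K > N || n > N) {
    stop("require 0 <= K, n <= N", call. = FALSE)
  }
  if (any(k < max(0, n + K - N) - 0.5) || any(k > min(K, n) + 0.5)) {
    stop("k outside the support [max(0, n+K-N), min(K, n)]", call. = FALSE)
  }
  exp(hypergeom_log_pmf(k, K, n, N))
}

hypergeom_log_pmf <- function(k, K, n, N) {
  lchoose_ <- function(a, b) lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)
  lchoose_(K, k) + lchoose_(N - K, n - k) - lchoose_(N, n)
}

#' One-sided Fisher's exact test (alternative: greater)
#'
#' Tests whether the count `a` of selected-and-annotated entities in a 2x2
#' contingency table is larger than expected under the hypergeometric null
#' with fixed margins. The p-value sums the hypergeometric probabilities of
#' the observed table and every more extreme one (larger `a`), until the
#' off-diagonal cells reach zero. Accumulation happens in log space so very
#' small p-values do not underflow to zero.
#'
#' @param a selected and annotated.
#' @param b selected, not annotated.
#' @param c_ not selected, annotated.
#' @param d neither.
#' @return The p-value in (0, 1].
#' @export
fisher_exact_greater <- function(a, b, c_, d) {
  counts <- c(a, b, c_, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("contingency counts must be non-negative integers", call. = FALSE)
  }
  N <- a + b + c_ + d
  K <- a + c_ # term size
  n <- a + b  # selection size
  if (N == 0L) return(1)
  hi <- min(K, n)
  if (a > hi) stop("inconsistent contingency table", call. = FALSE)
  ks <- a:hi
  logp <- hypergeom_log_pmf(ks, K, n, N)
  m <- max(logp)
  p <- exp(m + log(sum(exp(logp - m))))
  min(p, 1)
}

#' Multiple-testing adjustment
#'
#' Bonferroni multiplies each p-value by the number of tests and caps at 1.
#' Benjamini-Hochberg applies the step-up procedure: p-values are ranked
#' ascending, scaled by `m/rank`, and made monotone from the largest rank
#' down. Output order matches input order.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @param method `"benjamini_hochberg"` (default) or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("benjamini_hochberg", "bonferroni")) {
  method <- match.arg(method)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (method == "bonferroni") {
    return(pmin(1, m * p))
  }
  ord <- order(p, decreasing = TRUE) # largest rank first
  ranks <- m:1
  scaled <- m / ranks * p[ord]
  adj <- pmin(1, cummin(scaled))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Run an overrepresentation analysis
#'
#' Selects entities of interest, cross-tabulates each annotation term of the
#' chosen column against the selection over the whole-information-table
#' background (all rows, including entities without any term), computes
#' one-sided Fisher's exact p-values and adjusts them for multiple testing.
#'
#' @param info a `gxp_info`.
#' @param criterion a `gxp_criterion` or criterion string; see
#'   [select_entities()].
#' @param column annotation column holding the tested terms.
#' @param method multiple-testing method, see [adjust_pvalues()].
#' @param alpha significance level used to flag the significant subset
#'   (the full table is always retained).
#' @param delimiter multi-value delimiter forwarded to [build_term_index()].
#' @return A `gxp_ora`: data frame with columns `term`, `a`, `term_size`,
#'   `selection_size`, `N`, `p_raw`, `p_adj`, `significant`, sorted by
#'   `p_adj` then term name; attributes `method`, `alpha`, `column`,
#'   `selection`.
#' @export
run_ora <- function(info, criterion, column,
                    method = c("benjamini_hochberg", "bonferroni"),
                    alpha = 0.05, delimiter = NULL) {
  method <- match.arg(method)
  selection <- if (is.character(criterion) && length(criterion) > 1L) {
    # a plain character vector of length > 1 is an explicit id list
    select_entities(info, gxp_criterion(id_clause(criterion)))
  } else {
    select_entities(info, criterion)
  }
  if (length(selection) == 0L) {
    stop("empty selection: no overrepresentation test possible", call. = FALSE)
  }
  index <- build_term_index(info, column, delimiter = delimiter)
  N <- length(info$entity_ids)
  n_sel <- length(selection)
  terms <- names(index)
  a <- vapply(index, function(ids) sum(ids %in% selection), 0L)
  K <- vapply(index, length, 0L)
  p_raw <- vapply(seq_along(terms), function(i) {
    fisher_exact_greater(a[i], n_sel - a[i], K[i] - a[i], N - n_sel - K[i] + a[i])
  }, 0)
  p_adj <- adjust_pvalues(p_raw, method)
  res <- data.frame(
    term = terms, a = unname(a), term_size = unname(K),
    selection_size = n_sel, N = N,
    p_raw = unname(p_raw), p_adj = p_adj,
    stringsAsFactors = FALSE
  )
  res$significant <- res$p_adj < alpha
  res <- res[order(res$p_adj, res$term), , drop = FALSE]
  rownames(res) <- NULL
  structure(res,
    class = c("gxp_ora", "data.frame"),
    method = method, alpha = alpha, column = column, selection = selection
  )
}

#' @export
print.gxp_ora <- function(x, ...) {
  cat(sprintf(
    "gxp overrepresentation analysis on column %s: %d terms, %d significant at alpha=%g (%s)\n",
    dQuote(attr(x, "column")), nrow(x), sum(x$significant), attr(x, "alpha"), attr(x, "method")
  ))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Write an ORA result as TSV
#' @param ora a `gxp_ora`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ora_tsv <- function(ora, path) {
  utils::write.table(as.data.frame(ora)[, c("term", "a", "term_size", "selection_size", "N", "p_raw", "p_adj")],
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
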