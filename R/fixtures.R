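#' Describe a synthetic omics fixture
#'
#' The generated world mimics a two-species stress-treatment RNA-seq design:
#' a group factor with two levels, four x-axis factor levels (control plus
#' three stress treatments), three biological replicates per bin, and
#' log-normal multiplicative noise on TPM-like quantifications. A planted
#' set of differentially expressed entities separates the two groups by a
#' large shift (default 5 noise standard deviations, in log2 units), and a
#' planted annotation term is enriched among those entities. Given the same
#' seed the generator is byte-deterministic.
#'
#' @param n_entities number of quantified entities.
#' @param group_levels levels of the single group factor (e.g. species).
#' @param x_levels x-axis factor levels; the first is the control.
#' @param replicates biological replicates per (group, x) bin.
#' @param noise_sd standard deviation (log2) of the replicate noise.
#' @param n_de number of differentially expressed entities (default 20% of
#'   `n_entities`, i.e. 40 of the default 200).
#' @param de_shift log2 shift of DE entities in the second group relative to
#'   the first (default `-5 * noise_sd`: strong down-regulation).
#' @param condition_sd standard deviation (log2) of per-condition effects
#'   shared by both groups.
#' @param term_column name of the multi-valued bin annotation column.
#' @param enriched_term planted term (a MapMan-style bin path).
#' @param enriched_in_de,enriched_in_rest how many DE / non-DE entities
#'   carry the planted term (defaults: 75% of the DE set and 6.25% of the
#'   rest, i.e. 30 and 10 at default size).
#' @param separator sample-name token separator.
#' @param seed RNG seed.
#' @return A `gxp_fixture_design`.
#' @export
fixture_design <- function(n_entities = 200,
                           group_levels = c("S_lycopersicum", "S_pennellii"),
                           x_levels = c("ctrl1", "cold", "eL", "N-"),
                           replicates = 3,
                           noise_sd = 0.5,
                           n_de = max(1L, round(0.2 * n_entities)),
                           de_shift = -5 * noise_sd,
                           condition_sd = 0.15,
                           term_column = "mapman_bin",
                           enriched_term = "1.1.1.1.1",
                           enriched_in_de = max(1L, round(0.75 * n_de)),
                           enriched_in_rest = round(0.0625 * (n_entities - n_de)),
                           separator = ".",
                           seed = 42) {
  if (replicates < 1) stop("degenerate design: need at least 1 replicate", call. = FALSE)
  if (n_de > n_entities) stop("more DE entities than entities", call. = FALSE)
  if (enriched_in_de > n_de || enriched_in_rest > n_entities - n_de) {
    stop("planted term counts exceed available entities", call. = FALSE)
  }
  structure(
    list(
      n_entities = as.integer(n_entities), group_levels = group_levels,
      x_levels = x_levels, replicates = as.integer(replicates),
      noise_sd = noise_sd, n_de = as.integer(n_de),
      de_shift = de_shift, condition_sd = condition_sd,
      term_column = term_column, enriched_term = enriched_term,
      enriched_in_de = as.integer(enriched_in_de),
      enriched_in_rest = as.integer(enriched_in_rest),
      separator = separator, seed = as.integer(seed)
    ),
    class = "gxp_fixture_design"
  )
}

with_fixture_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

# background vocabulary of bin paths and description phrases
fixture_bin_vocab <- c(
  "1.1.1.2", "1.2.3", "1.3.1", "2.1", "4.1.2", "5.2", "7.10.1",
  "9.1.4.2", "13.1.2", "21.3", "24.2.1.5", "27.1", "35.2"
)
fixture_descriptions <- c(
  "light harvesting complex protein", "photosystem II subunit",
  "rubisco small subunit", "cell wall expansin", "lipid transfer protein",
  "amino acid transporter", "terpene synthase", "heat shock protein",
  "transcription factor bHLH", "unknown protein", "ribosomal protein L3",
  "solute transporter", "protein kinase"
)

#' Generate a synthetic fixture
#'
#' Produces the quantification table, the information table and a
#' machine-readable truth record, either in memory or written to `dir` as
#' `quantification.tsv`, `info.tsv` and `truth.json`.
#'
#' The info table carries a numeric `log2FC` column equal to each entity's
#' planted group shift plus small scatter (so filtering with
#' `log2FC < de_shift/2` recovers exactly the planted DE set), the
#' multi-valued bin annotation column with the planted enrichment, and a
#' free-text `description` column in which exactly two entities mention
#' "chalcone synthase".
#'
#' @param design a [fixture_design()].
#' @param dir output directory (created if missing), or `NULL` for
#'   in-memory results only.
#' @return List with `expression` (`gxp_expression`), `info` (`gxp_info`),
#'   `truth` (list), and, if `dir` was given, `paths`.
#' @export
generate_fixture <- function(design = fixture_design(), dir = NULL) {
  stopifnot(inherits(design, "gxp_fixture_design"))
  d <- design
  sim <- with_fixture_rng(d$seed, {
    ids <- sprintf("gene_%04d", seq_len(d$n_entities))
    de_ids <- sort(sample(ids, d$n_de))
    is_de <- ids %in% de_ids

    # sample design: group x condition x replicate
    grid <- expand.grid(
      rep = seq_len(d$replicates), x = d$x_levels, group = d$group_levels,
      stringsAsFactors = FALSE
    )
    sample_names <- paste(grid$group, grid$x, grid$rep, sep = d$separator)

    mu <- stats::runif(d$n_entities, 4, 12)                  # baseline log2 level
    cond_eff <- matrix(stats::rnorm(d$n_entities * length(d$x_levels), 0, d$condition_sd),
      nrow = d$n_entities,
      dimnames = list(ids, d$x_levels)
    )
    cond_eff[, 1L] <- 0 # control is the reference condition
    group_eff <- ifelse(is_de, d$de_shift, 0) # applied to the second group

    log2vals <- matrix(NA_real_, d$n_entities, nrow(grid), dimnames = list(ids, sample_names))
    for (j in seq_len(nrow(grid))) {
      g2 <- grid$group[j] == d$group_levels[2L]
      log2vals[, j] <- mu + cond_eff[, grid$x[j]] +
        (if (g2) group_eff else 0) +
        stats::rnorm(d$n_entities, 0, d$noise_sd)
    }
    values <- 2^log2vals

    # info table columns
    log2fc <- ifelse(is_de, d$de_shift, 0) + stats::rnorm(d$n_entities, 0, 0.1)
    bins <- lapply(seq_len(d$n_entities), function(i) {
      sample(fixture_bin_vocab, sample(1:3, 1))
    })
    names(bins) <- ids
    term_carriers <- c(
      sample(de_ids, d$enriched_in_de),
      sample(ids[!is_de], d$enriched_in_rest)
    )
    for (id in term_carriers) bins[[id]] <- c(d$enriched_term, bins[[id]])
    bin_cells <- vapply(bins, paste, "", collapse = ",")

    desc <- sample(fixture_descriptions, d$n_entities, replace = TRUE)
    chalcone_ids <- sort(sample(ids, 2L))
    desc[match(chalcone_ids, ids)] <- "chalcone synthase, flavonoid biosynthesis"

    truth <- list(
      seed = d$seed,
      n_entities = d$n_entities,
      group_levels = d$group_levels,
      x_levels = d$x_levels,
      replicates = d$replicates,
      noise_sd = d$noise_sd,
      sample_names = sample_names,
      sample_groups = grid$group,
      sample_x = grid$x,
      de_ids = de_ids,
      de_shift = d$de_shift,
      term_column = d$term_column,
      enriched_term = d$enriched_term,
      enriched_term_ids = sort(term_carriers),
      enriched_in_de = d$enriched_in_de,
      enriched_in_rest = d$enriched_in_rest,
      chalcone_ids = chalcone_ids,
      column_kinds = list(log2FC = "numeric", description = "text"),
      bin_means = NULL
    )
    truth$column_kinds[[d$term_column]] <- "categorical"

    info_df_cols <- list(log2FC = log2fc, description = desc)
    info_df_cols[[d$term_column]] <- bin_cells
    list(values = values, truth = truth, info_cols = info_df_cols, ids = ids)
  })

  expr <- gxp_expression(sim$values, separator = d$separator, unit = "TPM")
  info_lines <- c(
    paste(c("identifier", names(sim$info_cols)), collapse = "\t"),
    vapply(seq_along(sim$ids), function(i) {
      paste(c(sim$ids[i], vapply(sim$info_cols, function(col) {
        if (is.numeric(col)) sprintf("%.17g", col[i]) else col[i]
      }, "")), collapse = "\t")
    }, "")
  )

  out <- list(expression = expr, truth = sim$truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    qp <- file.path(dir, "quantification.tsv")
    ip <- file.path(dir, "info.tsv")
    tp <- file.path(dir, "truth.json")
    write_quantification_table(expr, qp)
    writeLines(info_lines, ip)
    jsonlite::write_json(sim$truth, tp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    out$paths <- list(quantification = qp, info = ip, truth = tp)
    out$info <- load_info_table(ip, categorical_columns = d$term_column)
  } else {
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(info_lines, tmp)
    out$info <- load_info_table(tmp, categorical_columns = d$term_column)
  }
  out
}
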