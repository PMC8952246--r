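# interpolate between colors in RGB space; clamped at the domain ends
ramp_fn <- function(colors, domain) {
  ramp <- grDevices::colorRamp(colors, space = "rgb")
  lo <- domain[1]; hi <- domain[2]
  span <- if (hi > lo) hi - lo else 1
  function(v) {
    t <- pmin(1, pmax(0, (v - lo) / span))
    rgb <- ramp(t)
    grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  }
}

# blue -> white -> red over [-L, L] (down/up regulation convention)
diverging_color_fn <- function(limit) {
  ramp_fn(c("#2166ac", "#ffffff", "#b2182b"), c(-limit, limit))
}

# white -> red over [lo, hi]
sequential_color_fn <- function(domain) {
  ramp_fn(c("#ffffff", "#b2182b"), domain)
}

#' Load a pathway-sketch layout
#'
#' A sketch layout names a diagram canvas and its areas. Each area anchors a
#' grid of gene boxes at a canvas position and owns a dot-separated numeric
#' bin prefix (e.g. `"1.1"`); genes whose functional bin annotation falls
#' under that prefix are drawn inside the area. The package ships two small
#' synthetic layouts (`metabolism_overview_mini`, `photosynthesis_mini`)
#' under `inst/extdata/`.
#'
#' @param path path of a layout JSON file (fields: `name`, `schema_version`,
#'   `canvas` with `width`/`height`, `areas` with `id`, `bin_prefix`, `x`,
#'   `y`, `grid_width`, `label`).
#' @return A `gxp_sketch_layout`.
#' @export
load_sketch_layout <- function(path) {
  if (!file.exists(path)) stop(sprintf("layout not found: %s", path), call. = FALSE)
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sketch_layout(
    name = spec$name,
    canvas = c(width = spec$canvas$width, height = spec$canvas$height),
    areas = lapply(spec$areas, function(a) {
      list(
        id = a$id, bin_prefix = a$bin_prefix, x = a$x, y = a$y,
        grid_width = a$grid_width, label = if (is.null(a$label)) a$id else a$label
      )
    })
  )
}

#' @rdname load_sketch_layout
#' @param name layout name.
#' @param canvas named numeric vector `width`, `height`.
#' @param areas list of area definitions (see above).
#' @export
sketch_layout <- function(name, canvas, areas) {
  prefixes <- vapply(areas, `[[`, "", "bin_prefix")
  if (anyDuplicated(prefixes)) {
    stop(sprintf(
      "duplicate area bin prefix(es): %s",
      paste(dQuote(unique(prefixes[duplicated(prefixes)])), collapse = ", ")
    ), call. = FALSE)
  }
  bad <- !vapply(prefixes, is_valid_bin, TRUE)
  if (any(bad)) {
    stop(sprintf("malformed area bin prefix(es): %s",
                 paste(dQuote(prefixes[bad]), collapse = ", ")), call. = FALSE)
  }
  for (a in areas) {
    if (a$x < 0 || a$y < 0 || a$x > canvas[["width"]] || a$y > canvas[["height"]]) {
      stop(sprintf("area %s anchored outside the canvas", dQuote(a$id)), call. = FALSE)
    }
  }
  structure(list(name = name, canvas = canvas, areas = areas),
            class = "gxp_sketch_layout")
}

#' @export
print.gxp_sketch_layout <- function(x, ...) {
  cat(sprintf(
    "gxp sketch layout %s: %d areas on %gx%g canvas\n",
    dQuote(x$name), length(x$areas), x$canvas[["width"]], x$canvas[["height"]]
  ))
  invisible(x)
}

is_valid_bin <- function(bin) {
  grepl("^[0-9]+(\\.[0-9]+)*$", bin)
}

# component-wise prefix test: "1.1" matches "1.1.1.1.1" but not "1.10"
bin_has_prefix <- function(bin, prefix) {
  bt <- strsplit(bin, ".", fixed = TRUE)[[1]]
  pt <- strsplit(prefix, ".", fixed = TRUE)[[1]]
  length(pt) <= length(bt) && all(bt[seq_along(pt)] == pt)
}

#' Assign genes to sketch areas by bin annotation
#'
#' A gene joins an area iff one of its bins equals the area's prefix or
#' starts with the prefix followed by a further `"."` component (matching is
#' component-wise, so bin `"1.10"` does not fall under prefix `"1.1"`).
#' When several areas match, the most specific (longest) prefix wins; ties
#' across a gene's multiple bins resolve by bin input order. Genes matching
#' no area, or carrying only malformed bins, are reported unassigned with a
#' reason.
#'
#' @param bins named list mapping gene id -> character vector of bin
#'   identifiers.
#' @param layout a `gxp_sketch_layout`.
#' @return List with `assignment` (data frame `gene`, `area`, `bin`) and
#'   `unassigned` (data frame `gene`, `reason`).
#' @export
assign_genes_to_areas <- function(bins, layout) {
  stopifnot(inherits(layout, "gxp_sketch_layout"))
  prefixes <- vapply(layout$areas, `[[`, "", "bin_prefix")
  prefix_len <- lengths(strsplit(prefixes, ".", fixed = TRUE))
  area_ids <- vapply(layout$areas, `[[`, "", "id")

  genes <- names(bins)
  as_gene <- character(0); as_area <- character(0); as_bin <- character(0)
  un_gene <- character(0); un_reason <- character(0)
  for (g in genes) {
    gbins <- bins[[g]]
    malformed <- !vapply(gbins, is_valid_bin, TRUE)
    valid <- gbins[!malformed]
    best <- NULL
    for (b in valid) {
      hits <- which(vapply(prefixes, bin_has_prefix, TRUE, bin = b))
      if (length(hits) == 0L) next
      hit <- hits[which.max(prefix_len[hits])]
      if (is.null(best) || prefix_len[hit] > best$len) {
        best <- list(area = area_ids[hit], bin = b, len = prefix_len[hit])
      }
    }
    if (!is.null(best)) {
      as_gene <- c(as_gene, g); as_area <- c(as_area, best$area); as_bin <- c(as_bin, best$bin)
    } else {
      reason <- if (length(valid) == 0L) {
        if (length(gbins) == 0L) "no bin annotation" else "malformed bin annotation"
      } else {
        "no matching area"
      }
      un_gene <- c(un_gene, g); un_reason <- c(un_reason, reason)
    }
  }
  list(
    assignment = data.frame(gene = as_gene, area = as_area, bin = as_bin,
                            stringsAsFactors = FALSE),
    unassigned = data.frame(gene = un_gene, reason = un_reason,
                            stringsAsFactors = FALSE)
  )
}

#' Build a color scale for sketch boxes
#'
#' Divergent mode maps `[-L, +L]` through blue-white-red, the conventional
#' down/up-regulation palette for log fold changes. Sequential mode maps
#' white-to-red over `[0, Q3]` or `[Q1, Q3]` of the plotted values, with
#' quartiles computed by linear interpolation between order statistics
#' (R's default quantile type 7). Values outside the domain clamp to the
#' end colors; the mapping is monotone.
#'
#' @param values numeric values that will be plotted.
#' @param mode `"divergent"` or `"sequential"`.
#' @param limit positive limit `L` of the divergent domain (required in
#'   divergent mode).
#' @param sequential_from lower end of the sequential domain: `"zero"` or
#'   `"q1"` (first quartile).
#' @return A `gxp_color_scale`: `mode`, `domain`, and `color(v)` function.
#' @export
build_color_scale <- function(values, mode = c("divergent", "sequential"),
                              limit = NULL, sequential_from = c("zero", "q1")) {
  mode <- match.arg(mode)
  sequential_from <- match.arg(sequential_from)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no non-missing values to scale", call. = FALSE)
  if (mode == "divergent") {
    if (is.null(limit) || !is.numeric(limit) || limit <= 0) {
      stop("divergent mode needs a positive `limit`", call. = FALSE)
    }
    domain <- c(-limit, limit)
    fn <- diverging_color_fn(limit)
  } else {
    q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
    domain <- c(if (sequential_from == "zero") 0 else q[1], q[2])
    if (domain[2] <= domain[1]) domain[2] <- domain[1] + 1e-9
    fn <- sequential_color_fn(domain)
  }
  structure(list(mode = mode, domain = domain, color = fn),
            class = "gxp_color_scale")
}

#' Extract the numeric value plotted per gene
#'
#' Either the mean expression of the replicates of one experimental
#' condition (one x-axis bin, optionally restricted to one group-factor
#' combination), or an arbitrary numeric column of the info table (e.g. a
#' log fold change or an adjusted p-value). Genes with a missing value are
#' excluded and reported via the `excluded` attribute.
#'
#' @param expr a `gxp_expression` (bin-mean mode) or `NULL`.
#' @param info a `gxp_info` (column mode) or `NULL`.
#' @param x_value x-axis factor level selecting the condition (bin-mean
#'   mode).
#' @param group group-factor label restricting the bin (optional).
#' @param column numeric info column (column mode).
#' @return Named numeric vector gene -> value with attribute `excluded`
#'   (character vector of gene ids without a value).
#' @export
mapman_values <- function(expr = NULL, info = NULL, x_value = NULL,
                          group = NULL, column = NULL) {
  if (!is.null(column)) {
    stopifnot(inherits(info, "gxp_info"))
    col <- info$columns[[column]]
    if (is.null(col)) stop(sprintf("unknown column %s", dQuote(column)), call. = FALSE)
    if (col$kind != "numeric") {
      stop(sprintf("column %s is not numeric", dQuote(column)), call. = FALSE)
    }
    v <- stats::setNames(col$cells, info$entity_ids)
    excluded <- names(v)[is.na(v)]
    v <- v[!is.na(v)]
    attr(v, "excluded") <- excluded
    return(v)
  }
  stopifnot(inherits(expr, "gxp_expression"), !is.null(x_value))
  prof <- aggregate_replicates(expr)
  sel <- prof$x_value == x_value
  if (!is.null(group)) sel <- sel & prof$group == group
  if (!any(sel)) stop(sprintf("no samples in bin x=%s", dQuote(x_value)), call. = FALSE)
  sub <- prof[sel, , drop = FALSE]
  v <- stats::setNames(sub$mean, sub$entity_id)
  # if several groups match, average their bin means
  if (anyDuplicated(names(v))) v <- vapply(split(unname(v), names(v)), mean, 0)[unique(sub$entity_id)]
  attr(v, "excluded") <- character(0)
  v
}

#' Place genes into a sketch and color them
#'
#' Combines [assign_genes_to_areas()], [build_color_scale()] and a value
#' mapping into a renderable sketch: every gene with both an area and a
#' value gets a grid cell (row-major fill in input order) and a color;
#' everything else is accounted for as unassigned or excluded. A
#' five-number summary (min, Q1, median, Q3, max) of the plotted values is
#' attached.
#'
#' @param values named numeric vector gene -> value (see [mapman_values()]).
#' @param bins named list gene -> bin vector.
#' @param layout a `gxp_sketch_layout`.
#' @param scale a `gxp_color_scale`, or `NULL` to build a divergent scale
#'   from the value range.
#' @param box_size box side length in pixels (positive integer).
#' @param descriptions optional named character vector gene -> description
#'   carried into the SVG metadata.
#' @return A `gxp_mapman_plot`.
#' @export
mapman_plot <- function(values, bins, layout, scale = NULL, box_size = 8L,
                        descriptions = NULL) {
  stopifnot(inherits(layout, "gxp_sketch_layout"))
  box_size <- as.integer(box_size)
  if (is.na(box_size) || box_size < 1L) stop("box_size must be a positive integer", call. = FALSE)
  genes <- names(bins)
  excluded <- setdiff(genes, names(values))
  with_value <- genes[genes %in% names(values)]
  asg <- assign_genes_to_areas(bins[with_value], layout)
  if (is.null(scale)) {
    lim <- max(abs(values[asg$assignment$gene]), 1e-9)
    scale <- build_color_scale(values[asg$assignment$gene], "divergent", limit = lim)
  }
  placements <- asg$assignment
  if (nrow(placements) > 0L) {
    placements$value <- unname(values[placements$gene])
    placements$color <- scale$color(placements$value)
    placements$description <- if (is.null(descriptions)) "" else {
      d <- descriptions[placements$gene]; d[is.na(d)] <- ""; unname(d)
    }
    # row-major grid cell per area, input order
    cells <- integer(nrow(placements))
    for (aid in unique(placements$area)) {
      idx <- which(placements$area == aid)
      cells[idx] <- seq_along(idx) - 1L
    }
    placements$cell <- cells
  } else {
    placements$value <- numeric(0); placements$color <- character(0)
    placements$description <- character(0); placements$cell <- integer(0)
  }
  plotted <- placements$value
  summary5 <- if (length(plotted) > 0L) {
    stats::setNames(stats::quantile(plotted, c(0, .25, .5, .75, 1), type = 7, names = FALSE),
                    c("min", "q1", "median", "q3", "max"))
  } else {
    stats::setNames(rep(NA_real_, 5), c("min", "q1", "median", "q3", "max"))
  }
  structure(
    list(
      layout = layout, placements = placements,
      unassigned = asg$unassigned,
      excluded = excluded,
      scale = scale, box_size = box_size, summary = summary5
    ),
    class = "gxp_mapman_plot"
  )
}

#' @export
print.gxp_mapman_plot <- function(x, ...) {
  cat(sprintf(
    "gxp mapman plot on %s: %d genes placed, %d unassigned, %d excluded\n",
    dQuote(x$layout$name), nrow(x$placements), nrow(x$unassigned), length(x$excluded)
  ))
  s <- x$summary
  cat(sprintf("  values: min %.3g | Q1 %.3g | median %.3g | Q3 %.3g | max %.3g\n",
              s[1], s[2], s[3], s[4], s[5]))
  invisible(x)
}

#' Render a MapMan-style sketch to SVG
#'
#' One rectangle per placed gene at its grid cell, a color-scale legend in
#' the top-right corner, and a summary strip along the bottom printing the
#' five-number distribution of the plotted values. Each rectangle carries
#' the gene id, description and value as `data-` attributes.
#'
#' @param plot a `gxp_mapman_plot`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
render_mapman_svg <- function(plot, path) {
  stopifnot(inherits(plot, "gxp_mapman_plot"))
  lay <- plot$layout
  w <- lay$canvas[["width"]]
  h <- lay$canvas[["height"]] + 28 # summary strip
  bs <- plot$box_size
  body <- c(svg_text(10, 16, lay$name, list(class = "sketch-title", "font-size" = 13)))
  area_by_id <- stats::setNames(lay$areas, vapply(lay$areas, `[[`, "", "id"))
  for (a in lay$areas) {
    body <- c(body, svg_text(a$x, a$y - 4, a$label,
      list(class = "area-label", "font-size" = 9)))
  }
  for (i in seq_len(nrow(plot$placements))) {
    p <- plot$placements[i, ]
    a <- area_by_id[[p$area]]
    col_i <- p$cell %% a$grid_width
    row_i <- p$cell %/% a$grid_width
    x <- a$x + col_i * (bs + 1)
    y <- a$y + row_i * (bs + 1)
    body <- c(body, svg_rect(x, y, bs, bs, list(
      class = "gene-box", fill = p$color, stroke = "#555", "stroke-width" = 0.4,
      "data-gene-id" = p$gene, "data-description" = p$description,
      "data-value" = sprintf("%.6g", p$value), "data-bin" = p$bin
    )))
  }
  # legend: gradient with labeled endpoints, top-right
  dom <- plot$scale$domain
  lx <- w - 130; ly <- 10
  steps <- 30
  for (k in seq_len(steps)) {
    v <- dom[1] + (k - 0.5) / steps * diff(dom)
    body <- c(body, svg_rect(lx + (k - 1) * 3.4, ly, 3.4, 10,
      list(class = "legend-step", fill = plot$scale$color(v))))
  }
  body <- c(body,
    svg_text(lx, ly + 21, sprintf("%.3g", dom[1]), list(class = "legend-min", "font-size" = 9)),
    svg_text(lx + steps * 3.4, ly + 21, sprintf("%.3g", dom[2]),
      list(class = "legend-max", "text-anchor" = "end", "font-size" = 9)))
  # summary strip
  s <- plot$summary
  body <- c(body, svg_text(10, lay$canvas[["height"]] + 18,
    sprintf("values: min %.3g | Q1 %.3g | median %.3g | Q3 %.3g | max %.3g  (%d genes, %d unassigned, %d excluded)",
            s[1], s[2], s[3], s[4], s[5],
            nrow(plot$placements), nrow(plot$unassigned), length(plot$excluded)),
    list(class = "summary-strip", "font-size" = 10)))
  write_svg(svg_document(w, h, body), path)
}
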