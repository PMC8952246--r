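#' Aggregate replicates into expression profiles
#'
#' Biological replicates sharing the same group-factor combination and x-axis
#' factor level form one bin. For every requested entity and every bin this
#' returns the bin mean, an error-bar half-height (`spread`), the replicate
#' count and the underlying replicate values.
#'
#' @param expr a `gxp_expression`.
#' @param ids entity ids to profile (default: all).
#' @param x_order explicit ordering of the x-axis factor levels; `NULL` means
#'   first appearance order in the sample columns.
#' @param spread error-bar estimator: `"sd"` (sample standard deviation,
#'   the default) or `"sem"` (standard error of the mean). Single-replicate
#'   bins always have spread 0.
#' @return A `gxp_profiles` object: data frame with columns `entity_id`,
#'   `group` (collapsed group-factor label), `x_value`, `mean`, `spread`,
#'   `n`, and list column `replicate_values`; attributes `x_order`, `unit`,
#'   `spread_type`, `groups`.
#' @export
aggregate_replicates <- function(expr, ids = entity_ids(expr), x_order = NULL,
                                 spread = c("sd", "sem")) {
  stopifnot(inherits(expr, "gxp_expression"))
  spread <- match.arg(spread)
  all_ids <- entity_ids(expr)
  missing_ids <- setdiff(ids, all_ids)
  if (length(missing_ids) > 0L) {
    stop(sprintf("unknown entity id(s): %s", paste(dQuote(missing_ids), collapse = ", ")),
      call. = FALSE
    )
  }
  group_of <- vapply(expr$samples, function(k) paste(k$group_values, collapse = expr$separator), "")
  x_of <- vapply(expr$samples, `[[`, "", "x_value")
  groups <- unique(group_of)
  x_seen <- unique(x_of)
  if (is.null(x_order)) {
    x_order <- x_seen
  } else {
    missing_x <- setdiff(x_seen, x_order)
    if (length(missing_x) > 0L) {
      stop(sprintf(
        "x_order does not cover x value(s): %s",
        paste(dQuote(missing_x), collapse = ", ")
      ), call. = FALSE)
    }
    x_order <- x_order[x_order %in% x_seen]
  }

  rows <- list()
  for (id in ids) {
    v <- expr$values[id, ]
    for (g in groups) {
      for (xv in x_order) {
        sel <- which(group_of == g & x_of == xv)
        if (length(sel) == 0L) next
        reps <- unname(v[sel])
        n <- length(reps)
        s <- if (n == 1L) 0 else stats::sd(reps)
        if (spread == "sem" && n > 1L) s <- s / sqrt(n)
        rows[[length(rows) + 1L]] <- list(
          entity_id = id, group = g, x_value = xv,
          mean = mean(reps), spread = s, n = n, replicate_values = reps
        )
      }
    }
  }
  df <- data.frame(
    entity_id = vapply(rows, `[[`, "", "entity_id"),
    group = vapply(rows, `[[`, "", "group"),
    x_value = vapply(rows, `[[`, "", "x_value"),
    mean = vapply(rows, `[[`, 0, "mean"),
    spread = vapply(rows, `[[`, 0, "spread"),
    n = vapply(rows, function(r) as.integer(r$n), 0L),
    stringsAsFactors = FALSE
  )
  df$replicate_values <- lapply(rows, `[[`, "replicate_values")
  structure(df,
    class = c("gxp_profiles", "data.frame"),
    x_order = x_order, unit = expr$unit, spread_type = spread, groups = groups
  )
}

#' Build a profile plot specification
#'
#' Lays aggregated profiles out into panels and colored series. With several
#' group-factor combinations, `bars` and `lines` place each combination in
#' its own panel side-by-side, while `stacked_lines` overlays all
#' combinations as differently colored curves in a single panel. Colors
#' distinguish groups when one entity is plotted and entities when several
#' are (groups then stay separated by panel).
#'
#' @param profiles a `gxp_profiles` from [aggregate_replicates()].
#' @param mode `"bars"`, `"lines"` or `"stacked_lines"`.
#' @return A `gxp_plot_spec` with `kind = "profile"`.
#' @export
build_plot_spec <- function(profiles, mode = c("bars", "lines", "stacked_lines")) {
  stopifnot(inherits(profiles, "gxp_profiles"), nrow(profiles) > 0L)
  mode <- match.arg(mode)
  groups <- attr(profiles, "groups")
  entities <- unique(profiles$entity_id)
  if (mode == "stacked_lines" && (length(groups) < 2L)) {
    if (identical(groups, "") || length(groups) == 0L) {
      warning("no group factors: stacked_lines degrades to lines", call. = FALSE)
      mode <- "lines"
    }
  }

  panels <- if (mode == "stacked_lines") "all" else groups
  color_by <- if (length(entities) > 1L) "entity" else "group"
  color_keys <- if (color_by == "entity") entities else groups
  colors <- stats::setNames(gxp_palette(length(color_keys)), color_keys)

  series <- list()
  for (id in entities) {
    for (g in groups) {
      pts <- profiles[profiles$entity_id == id & profiles$group == g, , drop = FALSE]
      if (nrow(pts) == 0L) next
      pts <- pts[match(attr(profiles, "x_order")[attr(profiles, "x_order") %in% pts$x_value], pts$x_value), , drop = FALSE]
      series[[length(series) + 1L]] <- list(
        entity_id = id,
        group = g,
        panel = if (mode == "stacked_lines") "all" else g,
        color = unname(colors[match(if (color_by == "entity") id else g, color_keys)]),
        label = if (mode == "stacked_lines" && length(entities) == 1L) g else id,
        points = pts[, c("x_value", "mean", "spread", "n")]
      )
    }
  }
  structure(
    list(
      kind = "profile", mode = mode, series = series, panels = panels,
      x_order = attr(profiles, "x_order"), unit = attr(profiles, "unit"),
      color_by = color_by
    ),
    class = "gxp_plot_spec"
  )
}

#' @export
print.gxp_plot_spec <- function(x, ...) {
  cat(sprintf(
    "gxp plot spec <%s/%s>: %d series, %d panel(s)\n",
    x$kind, if (is.null(x$mode)) "-" else x$mode,
    length(x$series), length(x$panels)
  ))
  invisible(x)
}

#' Render a profile plot specification to SVG
#'
#' Draws the panels of a profile [build_plot_spec()] side by side: grouped
#' bars or line curves over one axis tick per x-axis factor level, with
#' error bars wherever a bin holds more than one replicate.
#'
#' @param spec a `gxp_plot_spec` of kind `"profile"`.
#' @param path output file path.
#' @param panel_width,panel_height pixel size of one panel.
#' @return `path`, invisibly.
#' @export
render_profile_svg <- function(spec, path, panel_width = 320, panel_height = 260) {
  stopifnot(inherits(spec, "gxp_plot_spec"), identical(spec$kind, "profile"))
  margin <- list(left = 56, right = 16, top = 30, bottom = 46)
  xo <- spec$x_order
  n_panels <- length(spec$panels)
  total_w <- n_panels * panel_width
  total_h <- panel_height

  ymax <- max(vapply(spec$series, function(s) max(s$points$mean + s$points$spread), 0))
  ymin <- min(0, min(vapply(spec$series, function(s) min(s$points$mean - s$points$spread), 0)))
  yticks <- nice_axis_ticks(ymin, ymax)
  ydom <- range(c(yticks, ymin, ymax))

  body <- character(0)
  for (pi in seq_along(spec$panels)) {
    panel <- spec$panels[pi]
    x0 <- (pi - 1L) * panel_width
    plot_x <- c(x0 + margin$left, x0 + panel_width - margin$right)
    plot_y <- c(total_h - margin$bottom, margin$top)
    sy <- scale_linear(ydom, plot_y)
    slot_w <- diff(plot_x) / length(xo)
    center_of <- function(ix) plot_x[1] + (ix - 0.5) * slot_w

    body <- c(body, svg_text((plot_x[1] + plot_x[2]) / 2, margin$top - 12,
      if (identical(panel, "all")) "" else panel,
      list(class = "panel-title", "text-anchor" = "middle", "font-size" = 12)
    ))
    # axes
    body <- c(body,
      svg_line(plot_x[1], plot_y[1], plot_x[2], plot_y[1], list(stroke = "#000")),
      svg_line(plot_x[1], plot_y[1], plot_x[1], plot_y[2], list(stroke = "#000"))
    )
    for (tv in yticks) {
      body <- c(body,
        svg_line(plot_x[1] - 4, sy(tv), plot_x[1], sy(tv), list(stroke = "#000")),
        svg_text(plot_x[1] - 6, sy(tv) + 3, format(tv),
          list(class = "y-tick-label", "text-anchor" = "end", "font-size" = 10))
      )
    }
    for (ix in seq_along(xo)) {
      body <- c(body,
        svg_line(center_of(ix), plot_y[1], center_of(ix), plot_y[1] + 4, list(stroke = "#000")),
        svg_text(center_of(ix), plot_y[1] + 16, xo[ix],
          list(class = "x-tick-label", "text-anchor" = "middle", "font-size" = 10))
      )
    }
    if (nzchar(spec$unit)) {
      body <- c(body, svg_text(x0 + 14, (plot_y[1] + plot_y[2]) / 2, spec$unit,
        list(class = "y-axis-label", "text-anchor" = "middle", "font-size" = 11,
             transform = sprintf("rotate(-90 %s %s)", svg_num(x0 + 14),
                                 svg_num((plot_y[1] + plot_y[2]) / 2)))))
    }

    panel_series <- Filter(function(s) identical(s$panel, panel), spec$series)
    nser <- length(panel_series)
    for (si in seq_along(panel_series)) {
      s <- panel_series[[si]]
      pts <- s$points
      px <- vapply(pts$x_value, function(v) center_of(match(v, xo)), 0)
      if (spec$mode == "bars") {
        bw <- slot_w * 0.7 / max(nser, 1L)
        offs <- (si - (nser + 1) / 2) * bw
        for (k in seq_len(nrow(pts))) {
          y_val <- sy(pts$mean[k])
          body <- c(body, svg_rect(px[k] + offs - bw / 2, min(y_val, sy(0)),
            bw, abs(y_val - sy(0)),
            list(class = "bar", fill = s$color,
                 "data-entity" = s$entity_id, "data-x" = pts$x_value[k])))
        }
      } else {
        pathd <- paste(sprintf("%s%s,%s", c("M", rep("L", length(px) - 1L)),
                               svg_num(px), svg_num(sy(pts$mean))), collapse = " ")
        body <- c(body, svg_tag("path", list(
          class = "profile-line", d = pathd, fill = "none",
          stroke = s$color, "stroke-width" = 2, "data-entity" = s$entity_id
        )))
        for (k in seq_len(nrow(pts))) {
          body <- c(body, svg_tag("circle", list(
            class = "profile-point", cx = svg_num(px[k]), cy = svg_num(sy(pts$mean[k])),
            r = 2.5, fill = s$color
          )))
        }
      }
      # error bars for bins with replication
      for (k in seq_len(nrow(pts))) {
        if (pts$n[k] > 1L && pts$spread[k] > 0) {
          ex <- px[k] + if (spec$mode == "bars") (si - (nser + 1) / 2) * (slot_w * 0.7 / nser) else 0
          lo <- sy(pts$mean[k] - pts$spread[k]); hi <- sy(pts$mean[k] + pts$spread[k])
          body <- c(body,
            svg_line(ex, lo, ex, hi, list(class = "error-bar", stroke = "#333")),
            svg_line(ex - 3, lo, ex + 3, lo, list(class = "error-bar-cap", stroke = "#333")),
            svg_line(ex - 3, hi, ex + 3, hi, list(class = "error-bar-cap", stroke = "#333"))
          )
        }
      }
    }
    # legend
    for (si in seq_along(panel_series)) {
      s <- panel_series[[si]]
      ly <- margin$top + (si - 1L) * 14
      body <- c(body,
        svg_rect(plot_x[2] - 70, ly, 9, 9, list(fill = s$color, class = "legend-swatch")),
        svg_text(plot_x[2] - 58, ly + 8, s$label,
          list(class = "legend-label", "font-size" = 10)))
    }
  }
  write_svg(svg_document(total_w, total_h, body), path)
}
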