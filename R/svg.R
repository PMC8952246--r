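# String-based SVG 1.1 emission. Plots here are static documents built from
# a handful of primitives; attribute values are always escaped and numbers
# formatted with a fixed precision so output is deterministic.

svg_num <- function(x) sprintf("%.3f", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

svg_tag <- function(name, attrs = list(), content = NULL) {
  a <- if (length(attrs) > 0L) {
    paste0(" ", paste(sprintf("%s=\"%s\"", names(attrs),
                              xml_escape(as.character(unlist(attrs)))), collapse = " "))
  } else ""
  if (is.null(content)) {
    sprintf("<%s%s/>", name, a)
  } else {
    sprintf("<%s%s>%s</%s>", name, a, paste(content, collapse = ""), name)
  }
}

svg_text <- function(x, y, label, attrs = list()) {
  svg_tag("text", c(list(x = svg_num(x), y = svg_num(y)), attrs), xml_escape(label))
}

svg_line <- function(x1, y1, x2, y2, attrs = list()) {
  svg_tag("line", c(list(x1 = svg_num(x1), y1 = svg_num(y1),
                         x2 = svg_num(x2), y2 = svg_num(y2)), attrs))
}

svg_rect <- function(x, y, w, h, attrs = list()) {
  svg_tag("rect", c(list(x = svg_num(x), y = svg_num(y),
                         width = svg_num(w), height = svg_num(h)), attrs))
}

svg_document <- function(width, height, body) {
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    sprintf(paste0(
      "<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
      "width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">\n"
    ), svg_num(width), svg_num(height), svg_num(width), svg_num(height)),
    paste(body, collapse = "\n"),
    "\n</svg>\n"
  )
}

# write atomically: SVG files appear complete or not at all
write_svg <- function(doc, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".svg.part")
  writeLines(doc, tmp, sep = "")
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop(sprintf("cannot write SVG to %s", path), call. = FALSE)
  }
  invisible(path)
}

# fixed qualitative palette; assignment order = input order (deterministic)
gxp_palette <- function(n) {
  base <- c(
    "#d62728", "#2ca02c", "#1f77b4", "#ff7f0e", "#9467bd",
    "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf"
  )
  rep_len(base, n)
}

# linear mapping from data domain to pixel range
scale_linear <- function(domain, range) {
  d <- diff(domain)
  if (d == 0) d <- 1
  force(range)
  function(v) range[1] + (v - domain[1]) / d * diff(range)
}

nice_axis_ticks <- function(lo, hi, n = 5) {
  if (lo == hi) hi <- lo + 1
  pretty(c(lo, hi), n = n)
}
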