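test_layout <- function() {
  sketch_layout(
    name = "test",
    canvas = c(width = 400, height = 300),
    areas = list(
      list(id = "ps", bin_prefix = "1.1", x = 20, y = 30, grid_width = 4, label = "PS"),
      list(id = "lhc", bin_prefix = "1.1.1", x = 200, y = 30, grid_width = 4, label = "LHC"),
      list(id = "terp", bin_prefix = "9.1", x = 20, y = 160, grid_width = 4, label = "Terpenes")
    )
  )
}

test_that("bin matching is component-wise prefix with most-specific-area wins", {
  lay <- test_layout()
  asg <- assign_genes_to_areas(list(
    gA = "1.1.1.1.1",   # matches 1.1 and 1.1.1 -> longest wins
    gB = "1.1.2",       # only 1.1
    gC = "9.1.4.2",     # terpene
    gD = "1.10",        # component boundary: NOT under 1.1
    gE = "24.2.1.5",    # no area
    gF = "not-a-bin",   # malformed
    gG = character(0)   # unannotated
  ), lay)
  a <- asg$assignment
  expect_identical(a$area[a$gene == "gA"], "lhc")
  expect_identical(a$area[a$gene == "gB"], "ps")
  expect_identical(a$area[a$gene == "gC"], "terp")
  un <- asg$unassigned
  expect_setequal(un$gene, c("gD", "gE", "gF", "gG"))
  expect_identical(un$reason[un$gene == "gF"], "malformed bin annotation")
  expect_identical(un$reason[un$gene == "gD"], "no matching area")
  expect_identical(un$reason[un$gene == "gG"], "no bin annotation")
})

test_that("layouts validate prefixes and anchors", {
  expect_error(sketch_layout("x", c(width = 10, height = 10), list(
    list(id = "a", bin_prefix = "1.1", x = 1, y = 1, grid_width = 2, label = "a"),
    list(id = "b", bin_prefix = "1.1", x = 2, y = 2, grid_width = 2, label = "b")
  )), "duplicate")
  expect_error(sketch_layout("x", c(width = 10, height = 10), list(
    list(id = "a", bin_prefix = "1.x", x = 1, y = 1, grid_width = 2, label = "a")
  )), "malformed")
  expect_error(sketch_layout("x", c(width = 10, height = 10), list(
    list(id = "a", bin_prefix = "1", x = 50, y = 1, grid_width = 2, label = "a")
  )), "outside")
  # the two shipped layouts load cleanly
  for (f in c("photosynthesis_mini.json", "metabolism_overview_mini.json")) {
    lay <- load_sketch_layout(system.file("extdata", f, package = "gxpr"))
    expect_s3_class(lay, "gxp_sketch_layout")
    expect_gt(length(lay$areas), 3L)
  }
})

test_that("color scales are monotone, clamped, and quartile-anchored", {
  # divergent: 0 maps to the white midpoint, ends clamp
  sc <- build_color_scale(c(-1, 0, 1), "divergent", limit = 2)
  expect_identical(sc$domain, c(-2, 2))
  expect_identical(sc$color(0), "#FFFFFF")
  expect_identical(sc$color(-5), sc$color(-2))
  expect_identical(sc$color(99), sc$color(2))
  # monotone scale position: red rises toward the white midpoint from the
  # blue end, blue falls from the midpoint toward the red end
  rgb_at <- function(v) grDevices::col2rgb(sc$color(v))[, 1]
  lower <- vapply(seq(-2, 0, length.out = 11), function(v) rgb_at(v)["red"], 0)
  upper <- vapply(seq(0, 2, length.out = 11), function(v) rgb_at(v)["blue"], 0)
  expect_true(all(diff(lower) >= 0))
  expect_true(all(diff(upper) <= 0))

  # sequential [Q1, Q3] on 1..8: type-7 quartiles 2.75 and 6.25
  sq <- build_color_scale(1:8, "sequential", sequential_from = "q1")
  expect_equal(sq$domain, c(2.75, 6.25))
  s0 <- build_color_scale(1:8, "sequential", sequential_from = "zero")
  expect_equal(s0$domain, c(0, 6.25))

  expect_error(build_color_scale(numeric(0), "divergent", limit = 1), "no non-missing")
  expect_error(build_color_scale(1:3, "divergent"), "limit")
})

test_that("value extraction takes info columns or x-axis bin means", {
  fx <- generate_fixture(fixture_design(n_entities = 30, seed = 6))
  v <- mapman_values(info = fx$info, column = "log2FC")
  expect_equal(unname(v), fx$info$columns$log2FC$cells, ignore_attr = TRUE)
  expect_length(attr(v, "excluded"), 0L)

  vb <- mapman_values(expr = fx$expression, x_value = "cold", group = "S_lycopersicum")
  prof <- aggregate_replicates(fx$expression)
  want <- prof[prof$x_value == "cold" & prof$group == "S_lycopersicum", ]
  expect_equal(unname(vb[want$entity_id]), want$mean)

  expect_error(mapman_values(info = fx$info, column = "description"), "not numeric")
  expect_error(mapman_values(expr = fx$expression, x_value = "warm"), "warm")
})

test_that("every gene is placed exactly once or accounted for (conservation)", {
  fx <- generate_fixture(fixture_design(seed = 9))
  vals <- mapman_values(info = fx$info, column = "log2FC")
  col <- fx$info$columns$mapman_bin
  bins <- lapply(col$cells, function(s) trimws(strsplit(s, ",", fixed = TRUE)[[1]]))
  names(bins) <- fx$info$entity_ids
  lay <- load_sketch_layout(system.file("extdata", "metabolism_overview_mini.json", package = "gxpr"))
  mp <- mapman_plot(vals, bins, lay, scale = build_color_scale(vals, "divergent", limit = 2))
  accounted <- c(mp$placements$gene, mp$unassigned$gene, mp$excluded)
  expect_identical(sort(accounted), sort(names(bins)))
  expect_identical(anyDuplicated(accounted), 0L)
  # each grid cell within an area holds one gene
  cell_keys <- paste(mp$placements$area, mp$placements$cell)
  expect_identical(anyDuplicated(cell_keys), 0L)
  # placements carry the prefix-matched bin
  for (i in seq_len(nrow(mp$placements))) {
    area <- Filter(function(a) a$id == mp$placements$area[i], lay$areas)[[1]]
    expect_true(gxpr:::bin_has_prefix(mp$placements$bin[i], area$bin_prefix))
  }
  # five-number summary describes the plotted values
  expect_equal(unname(mp$summary),
               unname(quantile(mp$placements$value, c(0, .25, .5, .75, 1), type = 7)))
})

test_that("mapman placement is deterministic given input order", {
  fx <- generate_fixture(fixture_design(n_entities = 40, seed = 10))
  vals <- mapman_values(info = fx$info, column = "log2FC")
  col <- fx$info$columns$mapman_bin
  bins <- lapply(col$cells, function(s) strsplit(s, ",", fixed = TRUE)[[1]])
  names(bins) <- fx$info$entity_ids
  lay <- load_sketch_layout(system.file("extdata", "photosynthesis_mini.json", package = "gxpr"))
  m1 <- mapman_plot(vals, bins, lay, box_size = 6)
  m2 <- mapman_plot(vals, bins, lay, box_size = 6)
  expect_identical(m1$placements, m2$placements)
})

test_that("mapman SVG carries one metadata-bearing rect per placed gene", {
  fx <- generate_fixture(fixture_design(n_entities = 60, seed = 12))
  vals <- mapman_values(info = fx$info, column = "log2FC")
  col <- fx$info$columns$mapman_bin
  bins <- lapply(col$cells, function(s) strsplit(s, ",", fixed = TRUE)[[1]])
  names(bins) <- fx$info$entity_ids
  desc <- stats::setNames(fx$info$columns$description$cells, fx$info$entity_ids)
  lay <- load_sketch_layout(system.file("extdata", "metabolism_overview_mini.json", package = "gxpr"))
  mp <- mapman_plot(vals, bins, lay, scale = build_color_scale(vals, "divergent", limit = 2),
                    box_size = 8, descriptions = desc)
  path <- withr::local_tempfile(fileext = ".svg")
  render_mapman_svg(mp, path)
  doc <- xml2::read_xml(path)
  boxes <- xml2::xml_find_all(doc, "//*[@class='gene-box']")
  expect_length(boxes, nrow(mp$placements))
  expect_setequal(xml2::xml_attr(boxes, "data-gene-id"), mp$placements$gene)
  # all boxes inside the canvas
  xs <- as.numeric(xml2::xml_attr(boxes, "x"))
  ys <- as.numeric(xml2::xml_attr(boxes, "y"))
  expect_true(all(xs >= 0 & xs + 8 <= lay$canvas[["width"]]))
  expect_true(all(ys >= 0 & ys + 8 <= lay$canvas[["height"]]))
  # legend endpoints and summary strip present
  expect_length(xml2::xml_find_all(doc, "//*[@class='legend-min']"), 1L)
  expect_length(xml2::xml_find_all(doc, "//*[@class='legend-max']"), 1L)
  strip <- xml2::xml_find_all(doc, "//*[@class='summary-strip']")
  expect_match(xml2::xml_text(strip), "median")
})
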