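test_that("sample names parse right-anchored with any number of group factors", {
  cases <- list(
    list(raw = "S_lycopersicum.ctrl1.1", sep = ".",
         groups = "S_lycopersicum", x = "ctrl1", rep = "1"),
    list(raw = "S_pennellii.ctrl1.3", sep = ".",
         groups = "S_pennellii", x = "ctrl1", rep = "3"),
    list(raw = "cold.3", sep = ".", groups = character(0), x = "cold", rep = "3"),
    list(raw = "A*B*eL*2", sep = "*", groups = c("A", "B"), x = "eL", rep = "2"),
    list(raw = "w.x.y.z.5", sep = ".", groups = c("w", "x", "y"), x = "z", rep = "5")
  )
  for (cs in cases) {
    key <- parse_sample_name(cs$raw, cs$sep)
    expect_identical(key$group_values, cs$groups, info = cs$raw)
    expect_identical(key$x_value, cs$x, info = cs$raw)
    expect_identical(key$replicate_id, cs$rep, info = cs$raw)
    expect_identical(join_sample_name(key, cs$sep), cs$raw)
  }
})

test_that("malformed sample names are rejected with the offending name", {
  expect_error(parse_sample_name("nodots", "."), "nodots")
  expect_error(parse_sample_name("trailing.", "."), "trailing")
})

test_that("join-then-parse is the identity on random token lists", {
  set.seed(101)
  for (i in 1:200) {
    n_tok <- sample(2:5, 1)
    tokens <- replicate(n_tok, paste(sample(c(letters, 0:9), sample(1:6, 1), replace = TRUE), collapse = ""))
    raw <- paste(tokens, collapse = ".")
    key <- parse_sample_name(raw, ".")
    expect_identical(c(key$group_values, key$x_value, key$replicate_id), tokens)
  }
})

test_that("quantification tables load with parsed keys and strict validation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_counts(path)
  expr <- load_quantification_table(path, unit = "TPM")
  expect_identical(dim(expr), c(3L, 4L))
  expect_identical(entity_ids(expr), c("g1", "g2", "g3"))
  expect_identical(expr$samples[[3]]$x_value, "cold")
  expect_identical(expr$samples[[3]]$group_values, "A")
  expect_identical(expr$unit, "TPM")

  # duplicate identifier
  write_tiny_counts(path, rows = list(c("g1", "1", "1", "1", "1"), c("g1", "2", "2", "2", "2")))
  expect_error(load_quantification_table(path), "g1")

  # non-numeric cell names row and column
  write_tiny_counts(path, rows = list(c("g1", "1", "oops", "3", "4")))
  expect_error(load_quantification_table(path), "oops")
  expect_error(load_quantification_table(path), "A\\.ctrl\\.2")

  # duplicate column name
  write_tiny_counts(path, header = c("id", "A.ctrl.1", "A.ctrl.1", "A.cold.1", "A.cold.2"))
  expect_error(load_quantification_table(path), "A\\.ctrl\\.1")
})

test_that("expression matrices round-trip through TSV bit-exactly", {
  set.seed(5)
  vals <- matrix(exp(rnorm(60, 5, 3)), 10,
    dimnames = list(sprintf("g%02d", 1:10),
                    paste0("A.", rep(c("c", "t"), each = 3), ".", rep(1:3, 2)))
  )
  expr <- gxp_expression(vals)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_quantification_table(expr, path)
  back <- load_quantification_table(path)
  expect_identical(back$values, expr$values)
})

test_that("info tables infer column kinds and split multi-valued cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_info(path)
  info <- load_info_table(path, categorical_columns = "bins")
  expect_identical(info$columns$log2FC$kind, "numeric")
  expect_identical(info$columns$bins$kind, "categorical")
  expect_identical(info$columns$description$kind, "text")
  # missing numeric cell becomes NA
  expect_true(is.na(info$columns$log2FC$cells[3]))
  expect_equal(info$columns$log2FC$cells[1:2], c(-2, 0.5))
  # negative numbers and scientific notation still numeric
  write_tiny_info(path, rows = list(c("a", "1.5", "x", "d"), c("b", "-0.2", "y", "d"),
                                    c("c", "3e-2", "z", "d")))
  info2 <- load_info_table(path)
  expect_identical(info2$columns$log2FC$kind, "numeric")

  write_tiny_info(path, rows = list(c("a", "1", "x", "d"), c("a", "2", "y", "d")))
  expect_error(load_info_table(path), "a")
})

test_that("entity search is case-insensitive over ids and text cells", {
  cpath <- withr::local_tempfile(fileext = ".tsv")
  ipath <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_counts(cpath)
  write_tiny_info(ipath)
  expr <- load_quantification_table(cpath)
  info <- load_info_table(ipath)
  expect_identical(search_entities(expr, info, "g2"), "g2")
  expect_identical(search_entities(expr, info, "CHALCONE synthase"), c("g1", "g3"))
  expect_identical(search_entities(expr, info, ""), c("g1", "g2", "g3"))
  expect_identical(search_entities(expr, info, "no-such-thing"), character(0))
  # numeric columns are not searched
  expect_identical(search_entities(expr, info, "0.5"), character(0))
})

test_that("identifier mismatches between tables are reported and excluded", {
  cpath <- withr::local_tempfile(fileext = ".tsv")
  ipath <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_counts(cpath)
  write_tiny_info(ipath, rows = list(c("g1", "1", "x", "d"), c("gX", "2", "y", "d")))
  expr <- load_quantification_table(cpath)
  info <- load_info_table(ipath)
  expect_warning(shared <- common_entities(expr, info), "2 expression-only")
  expect_identical(shared, "g1")
})

test_that("session bundles export to zip with GXP_settings.json and restore", {
  fx <- generate_fixture(fixture_design(n_entities = 20, seed = 3))
  ses <- gxp_session(gxp_settings(unit = "TPM"), fx$expression, fx$info)
  path <- withr::local_tempfile(fileext = ".zip")
  export_database(ses, path)
  listing <- utils::unzip(path, list = TRUE)
  expect_true("GXP_settings.json" %in% listing$Name)
  back <- import_database(path)
  expect_equal(back, ses)
  # export is byte-deterministic
  path2 <- withr::local_tempfile(fileext = ".zip")
  export_database(ses, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("import rejects corrupted archives and unknown schema versions", {
  path <- withr::local_tempfile(fileext = ".zip")
  writeBin(as.raw(1:100), path)
  expect_error(import_database(path), "corrupt|GXP_settings")
  expect_error(import_database(file.path(tempdir(), "no-such.zip")), "not found")

  # a valid zip without the settings file
  fx <- generate_fixture(fixture_design(n_entities = 5, seed = 1))
  ses <- gxp_session(gxp_settings(), fx$expression)
  export_database(ses, path)
  exdir <- withr::local_tempdir()
  utils::unzip(path, exdir = exdir)
  # tamper: bump the schema version
  sj <- jsonlite::fromJSON(file.path(exdir, "GXP_settings.json"))
  sj$schema_version <- "99.0"
  jsonlite::write_json(sj, file.path(exdir, "GXP_settings.json"), auto_unbox = TRUE, null = "null")
  files <- list.files(exdir)
  payloads <- lapply(file.path(exdir, files), function(f) readBin(f, "raw", file.size(f)))
  names(payloads) <- files
  tampered <- withr::local_tempfile(fileext = ".zip")
  gxpr:::write_zip_archive(payloads, tampered)
  expect_error(import_database(tampered), "99\\.0")
})
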