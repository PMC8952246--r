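test_that("z-transformation centers and scales rows, flagging constant rows", {
  z <- z_transform(matrix(c(1, 2, 3, 5, 5, 5), 2, byrow = TRUE))
  expect_equal(z$values[1, ], c(-1, 0, 1))
  expect_equal(z$values[2, ], c(0, 0, 0))
  expect_identical(z$constant_rows, c(FALSE, TRUE))

  set.seed(9)
  M <- matrix(rnorm(500), 50)
  zz <- z_transform(M)
  expect_true(all(abs(rowMeans(zz$values)) < 1e-9))
  expect_true(all(abs(apply(zz$values, 1, sd) - 1) < 1e-9))
  expect_error(z_transform(matrix(numeric(0), 0, 0)), "empty")
})

test_that("correlation distance implements d = 1 - |c|", {
  x <- c(1, 4, 2, 8, 5)
  dm <- correlation_distance(cbind(a = x, b = x, c = -x))
  expect_equal(dm$C["a", "b"], 1)
  expect_equal(dm$D["a", "b"], 0)
  expect_equal(dm$C["a", "c"], -1)
  expect_equal(dm$D["a", "c"], 0) # anticorrelation is maximum likeness
  expect_equal(unname(diag(dm$D)), rep(0, 3))

  # hand-computed Pearson: x=1:4 vs y=(1,3,2,4) -> c=0.8
  dm2 <- correlation_distance(cbind(x = 1:4, y = c(1, 3, 2, 4)))
  expect_equal(dm2$C["x", "y"], 0.8, tolerance = 1e-12)
  expect_equal(dm2$D["x", "y"], 0.2, tolerance = 1e-12)

  expect_error(correlation_distance(cbind(u = c(1, 1, 1), v = 1:3)), "u")
})

test_that("distance-transform identities hold on random vectors", {
  set.seed(77)
  for (i in 1:100) {
    x <- rnorm(sample(3:20, 1))
    if (sd(x) == 0) next
    dm <- correlation_distance(cbind(a = x, b = -x, c = rnorm(length(x))))
    expect_lt(dm$D["a", "b"], 1e-12)
    expect_true(all(dm$D >= 0 & dm$D <= 1))
    expect_equal(dm$D, t(dm$D))
  }
})

test_that("euclidean distance matches a naive loop oracle", {
  d <- euclidean_distance(cbind(p = c(0, 0), q = c(3, 4)))
  expect_equal(d$D["p", "q"], 5)
  expect_null(d$C)

  set.seed(13)
  M <- matrix(rnorm(50), 10) # 5 columns
  dm <- euclidean_distance(M)
  for (i in 1:5) {
    for (j in 1:5) {
      naive <- sqrt(sum((M[, i] - M[, j])^2))
      expect_equal(unname(dm$D[i, j]), naive, tolerance = 1e-12)
    }
  }
  # transposed mode compares rows
  dt <- euclidean_distance(M, orientation = "entities")
  expect_length(dt$labels, 10L)
  expect_equal(unname(dt$D[1, 2]), sqrt(sum((M[1, ] - M[2, ])^2)), tolerance = 1e-12)
})

test_that("hierarchical clustering handles forced geometries deterministically", {
  # two leaves: one merge at D[1,2]
  D <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  dend <- hierarchical_cluster(structure(
    list(labels = c("a", "b"), metric = "euclidean", D = D, C = NULL),
    class = "gxp_distance"
  ), "average")
  expect_equal(dend$height, 3)
  expect_identical(dend$merge, matrix(c(-1L, -2L), 1))

  # points on a line at 0, 1, 10 (single linkage): first merge {1,2} at height 1
  M <- matrix(c(0, 1, 10), 1, dimnames = list("e", c("p0", "p1", "p10")))
  dend2 <- hierarchical_cluster(euclidean_distance(M), "single")
  expect_identical(dend2$merge[1, ], c(-1L, -2L))
  expect_equal(dend2$height, c(1, 9))
  expect_error(hierarchical_cluster(matrix(0, 1, 1)), "at least 2")
})

test_that("merge sequences match the brute-force reference on random matrices", {
  set.seed(2024)
  linkages <- c("single", "complete", "average")
  for (rep in 1:30) {
    n <- sample(3:6, 1)
    P <- matrix(rnorm(n * 4), ncol = n)
    dm <- euclidean_distance(P)
    for (lk in linkages) {
      dend <- hierarchical_cluster(dm, lk)
      got <- dendrogram_merge_sets(dend)
      want <- oracle_agglomerate(dm$D, lk)
      for (s in seq_along(want)) {
        expect_identical(got[[s]]$members, want[[s]]$members,
          info = sprintf("rep %d linkage %s step %d", rep, lk, s))
        expect_equal(got[[s]]$height, want[[s]]$height, tolerance = 1e-10)
      }
    }
  }
})

test_that("ward linkage agrees with stats::hclust ward.D2 heights", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    P <- matrix(rnorm(n * 3), ncol = n,
                dimnames = list(NULL, paste0("s", 1:n)))
    dm <- euclidean_distance(P)
    dend <- hierarchical_cluster(dm, "ward")
    ref <- stats::hclust(stats::as.dist(dm$D), method = "ward.D2")
    expect_equal(sort(dend$height), sort(ref$height), tolerance = 1e-9)
    # same final two-cluster partition
    got <- root_split(dend)
    want <- split(ref$labels, stats::cutree(ref, 2))
    expect_true(setequal(got$left, want[[1]]) || setequal(got$left, want[[2]]))
  }
})

test_that("clustering is invariant under input column permutation", {
  set.seed(55)
  M <- matrix(rnorm(8 * 30), 30, dimnames = list(NULL, paste0("s", 1:8)))
  dm <- euclidean_distance(M)
  dend <- hierarchical_cluster(dm, "average")
  perm <- sample(8)
  dmp <- euclidean_distance(M[, perm])
  dendp <- hierarchical_cluster(dmp, "average")
  expect_equal(sort(dend$height), sort(dendp$height), tolerance = 1e-10)
  a <- lapply(dendrogram_merge_sets(dend), function(s) sort(dend$labels[s$members]))
  b <- lapply(dendrogram_merge_sets(dendp), function(s) sort(dendp$labels[s$members]))
  expect_setequal(vapply(a, paste, "", collapse = "|"), vapply(b, paste, "", collapse = "|"))
})

test_that("newick export reproduces dendrogram depths and parses as a tree", {
  skip_if_not_installed("ape")
  M <- matrix(c(0, 1, 10, 11, 30, 31), 1,
              dimnames = list("e", paste0("s", 1:6)))
  dend <- hierarchical_cluster(euclidean_distance(M), "single")
  nwk <- as_newick(dend)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, paste0("s", 1:6))
  # ultrametric: all tips equally deep, depth = root height
  depths <- ape::node.depth.edgelength(tree)[seq_len(6)]
  expect_equal(max(abs(depths - max(dend$height))), 0, tolerance = 1e-9)
})

test_that("heatmaps are permuted to leaf order and render with a color scale", {
  fx <- generate_fixture(fixture_design(n_entities = 30, seed = 11))
  dm <- correlation_distance(fx$expression)
  dend <- hierarchical_cluster(dm, "average")
  hm <- heatmap_result(dm, dend)
  expect_identical(hm$labels, dend$labels[dend$order])
  expect_identical(hm$value_kind, "correlation")
  perm <- match(hm$labels, dm$labels)
  expect_equal(hm$values, dm$C[perm, perm])
  expect_equal(hm$values, t(hm$values))

  path <- withr::local_tempfile(fileext = ".svg")
  render_heatmap_svg(hm, path)
  doc <- xml2::read_xml(path)
  expect_identical(xml2::xml_name(doc), "svg")
  cells <- xml2::xml_find_all(doc, "//*[@class='heatmap-cell']")
  expect_length(cells, length(hm$labels)^2)
  expect_gt(length(xml2::xml_find_all(doc, "//*[@class='legend-step']")), 0)
})

test_that("PCA satisfies variance identities and matches the covariance oracle", {
  # rank-1 data: samples on a line -> PC1 explains everything
  base <- rnorm(20)
  line <- outer(base, c(1, 2, 3)) # 3 samples, collinear
  res1 <- run_pca(line)
  expect_equal(res1$explained_fraction[1], 1)

  set.seed(66)
  M <- matrix(rnorm(20 * 6), 20, dimnames = list(NULL, paste0("s", 1:6)))
  res <- run_pca(M)
  expect_equal(sum(res$explained_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(res$explained_fraction) <= 1e-12))
  expect_true(all(res$explained_fraction >= 0 & res$explained_fraction <= 1))

  # oracle: eigendecomposition of the sample covariance of centered samples
  X <- scale(t(M), center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  scores_oracle <- X %*% eg$vectors
  for (k in 1:5) {
    a <- res$scores[, k]
    b <- scores_oracle[, k]
    expect_true(max(abs(a - b)) < 1e-9 || max(abs(a + b)) < 1e-9, info = paste("PC", k))
    expect_equal(res$explained_fraction[k], eg$values[k] / sum(eg$values), tolerance = 1e-9)
  }
  expect_error(run_pca(M[, 1, drop = FALSE]), "2 samples")
})

test_that("PCA sign convention is deterministic (largest loading positive)", {
  set.seed(8)
  M <- matrix(rnorm(60), 10)
  r1 <- run_pca(M)
  r2 <- run_pca(M)
  expect_identical(r1$scores, r2$scores)
  for (k in seq_along(r1$component_labels)) {
    piv <- which.max(abs(r1$loadings[, k]))
    expect_gte(r1$loadings[piv, k], 0)
  }
})

test_that("PCA scatter specs color by condition and label axes with variance", {
  fx <- generate_fixture(fixture_design(n_entities = 40, seed = 2))
  res <- run_pca(z_transform(fx$expression))
  spec <- pca_plot_spec(res, fx$expression$samples)
  expect_identical(spec$kind, "scatter")
  # replicates of the same (group, x) combination share a color
  reps <- spec$points[grepl("S_lycopersicum.cold", spec$points$label, fixed = TRUE), ]
  expect_length(unique(reps$color), 1L)
  # one class per (group, x) combination
  expect_length(spec$color_classes, 8L)
  expect_match(spec$x_label, sprintf("%.1f", 100 * res$explained_fraction[1]), fixed = TRUE)

  path <- withr::local_tempfile(fileext = ".svg")
  render_scatter_svg(spec, path)
  doc <- xml2::read_xml(path)
  expect_length(xml2::xml_find_all(doc, "//*[@class='pca-point']"), 24L)
})
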