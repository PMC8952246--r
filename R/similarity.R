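#' Row-wise z-transformation
#'
#' Centers every row to mean 0 and scales to sample standard deviation 1
#' (denominator n-1). Rows with zero variance cannot be scaled; they are set
#' to all-zero and flagged so downstream code can recognize them while the
#' matrix keeps its shape.
#'
#' @param M numeric matrix (rows = entities, columns = samples), no missing
#'   values.
#' @return A `gxp_zmatrix`: list with `values` (transformed matrix) and
#'   `constant_rows` (logical flag per row).
#' @export
z_transform <- function(M) {
  if (inherits(M, "gxp_expression")) M <- M$values
  stopifnot(is.matrix(M), is.numeric(M))
  if (nrow(M) == 0L || ncol(M) == 0L) stop("empty matrix", call. = FALSE)
  if (anyNA(M)) stop("missing values are not supported", call. = FALSE)
  mu <- rowMeans(M)
  sdv <- apply(M, 1L, stats::sd)
  constant <- sdv == 0
  Z <- (M - mu) / ifelse(constant, 1, sdv)
  Z[constant, ] <- 0
  structure(list(values = Z, constant_rows = constant), class = "gxp_zmatrix")
}

as_value_matrix <- function(M) {
  if (inherits(M, "gxp_expression")) M$values
  else if (inherits(M, "gxp_zmatrix")) M$values
  else M
}

# vectors to compare: samples = columns, entities = rows ("transposed" mode)
orientation_vectors <- function(M, orientation) {
  M <- as_value_matrix(M)
  stopifnot(is.matrix(M), is.numeric(M))
  V <- if (orientation == "samples") M else t(M)
  if (is.null(colnames(V))) colnames(V) <- paste0(if (orientation == "samples") "sample" else "entity", seq_len(ncol(V)))
  V
}

#' Correlation distance between samples or entities
#'
#' Computes pairwise correlation `c` between quantification vectors and maps
#' it to the distance `d = 1 - |c|`, so that perfect correlation and perfect
#' anticorrelation both count as maximal likeness.
#'
#' @param M numeric matrix, `gxp_expression` or `gxp_zmatrix` (rows =
#'   entities, columns = samples).
#' @param orientation `"samples"` compares sample columns; `"entities"`
#'   compares entity rows (transposed mode).
#' @param method correlation flavor, `"pearson"` (default) or `"spearman"`.
#' @return A `gxp_distance` with `labels`, `metric = "correlation"`,
#'   symmetric distance matrix `D` and correlation matrix `C`.
#' @export
correlation_distance <- function(M, orientation = c("samples", "entities"),
                                 method = c("pearson", "spearman")) {
  orientation <- match.arg(orientation)
  method <- match.arg(method)
  V <- orientation_vectors(M, orientation)
  if (ncol(V) < 2L) stop("need at least 2 vectors", call. = FALSE)
  sds <- apply(V, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf(
      "constant vector(s), correlation undefined: %s",
      paste(dQuote(colnames(V)[sds == 0]), collapse = ", ")
    ), call. = FALSE)
  }
  C <- stats::cor(V, method = method)
  D <- 1 - abs(C)
  D[D < 0] <- 0 # guard rounding just below 0
  diag(D) <- 0
  structure(
    list(labels = colnames(V), metric = "correlation", D = D, C = C,
         correlation_method = method),
    class = "gxp_distance"
  )
}

#' Euclidean distance between samples or entities
#'
#' @inheritParams correlation_distance
#' @return A `gxp_distance` with `metric = "euclidean"` and no correlation
#'   matrix.
#' @export
euclidean_distance <- function(M, orientation = c("samples", "entities")) {
  orientation <- match.arg(orientation)
  V <- orientation_vectors(M, orientation)
  if (ncol(V) < 2L) stop("need at least 2 vectors", call. = FALSE)
  D <- as.matrix(stats::dist(t(V), method = "euclidean"))
  dimnames(D) <- list(colnames(V), colnames(V))
  structure(
    list(labels = colnames(V), metric = "euclidean", D = D, C = NULL),
    class = "gxp_distance"
  )
}

#' @export
print.gxp_distance <- function(x, ...) {
  cat(sprintf("gxp %s distance matrix: %d labels\n", x$metric, length(x$labels)))
  invisible(x)
}

#' Write a distance matrix as TSV
#' @param dm a `gxp_distance`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  header <- paste(c("", dm$labels), collapse = "\t")
  rows <- vapply(seq_along(dm$labels), function(i) {
    paste(c(dm$labels[i], sprintf("%.17g", dm$D[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Agglomerative hierarchical clustering
#'
#' Standard bottom-up clustering over a precomputed distance matrix with
#' single, complete, average (default) or Ward linkage (Lance-Williams
#' update; Ward operates on squared distances and reports the square root,
#' matching the usual `ward.D2` convention). Ties are broken
#' deterministically: among equally close pairs, the pair whose clusters
#' contain the lowest original leaf indices merges first.
#'
#' @param dm a `gxp_distance` (or a plain symmetric matrix with dimnames).
#' @param linkage one of `"single"`, `"complete"`, `"average"`, `"ward"`.
#' @return A `gxp_dendrogram`: merge matrix in `stats::hclust` convention
#'   (negative entries = leaves), `height`, `labels`, `order` (leaf display
#'   order), `linkage`, `metric`.
#' @export
hierarchical_cluster <- function(dm, linkage = c("average", "single", "complete", "ward")) {
  linkage <- match.arg(linkage)
  if (inherits(dm, "gxp_distance")) {
    D <- dm$D; labels <- dm$labels; metric <- dm$metric
  } else {
    D <- as.matrix(dm)
    labels <- rownames(D)
    if (is.null(labels)) labels <- paste0("item", seq_len(nrow(D)))
    metric <- "precomputed"
  }
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  W <- if (linkage == "ward") D^2 else D

  active <- seq_len(n)           # cluster slots currently alive
  size <- rep(1L, n)
  min_leaf <- seq_len(n)         # lowest original index per cluster (tie-break)
  node_id <- -seq_len(n)         # hclust convention: negative = leaf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  children <- vector("list", n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        dij <- W[i, j]
        key <- c(dij, sort(c(min_leaf[i], min_leaf[j])))
        if (is.null(best) ||
            key[1] < best$key[1] - 1e-12 ||
            (abs(key[1] - best$key[1]) <= 1e-12 &&
             (key[2] < best$key[2] || (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    h <- if (linkage == "ward") sqrt(W[i, j]) else W[i, j]
    a <- node_id[i]; b <- node_id[j]
    # put the cluster containing the lowest leaf on the left
    if (min_leaf[j] < min_leaf[i]) { tmp <- a; a <- b; b <- tmp }
    merge[step, ] <- c(a, b)
    height[step] <- h
    children[[step]] <- list(left = a, right = b)

    # Lance-Williams update into slot i, retire slot j
    ni <- size[i]; nj <- size[j]
    for (k in active) {
      if (k == i || k == j) next
      W[i, k] <- W[k, i] <- switch(linkage,
        single = min(W[i, k], W[j, k]),
        complete = max(W[i, k], W[j, k]),
        average = (ni * W[i, k] + nj * W[j, k]) / (ni + nj),
        ward = ((ni + size[k]) * W[i, k] + (nj + size[k]) * W[j, k] -
                size[k] * W[i, j]) / (ni + nj + size[k])
      )
    }
    size[i] <- ni + nj
    min_leaf[i] <- min(min_leaf[i], min_leaf[j])
    node_id[i] <- step
    active <- active[active != j]
  }

  # leaf display order by depth-first traversal
  leaf_order <- function(node) {
    if (node < 0L) return(-node)
    c(leaf_order(merge[node, 1L]), leaf_order(merge[node, 2L]))
  }
  structure(
    list(
      merge = merge, height = height, labels = labels,
      order = leaf_order(n - 1L), linkage = linkage, metric = metric
    ),
    class = "gxp_dendrogram"
  )
}

#' @export
print.gxp_dendrogram <- function(x, ...) {
  cat(sprintf(
    "gxp dendrogram: %d leaves, %s linkage on %s distance\n",
    length(x$labels), x$linkage, x$metric
  ))
  invisible(x)
}

#' Convert a dendrogram to a `stats::hclust` object
#' @param x a `gxp_dendrogram`.
#' @param ... unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.gxp_dendrogram <- function(x, ...) {
  structure(
    list(
      merge = x$merge, height = x$height, order = x$order, labels = x$labels,
      method = x$linkage, call = NULL, dist.method = x$metric
    ),
    class = "hclust"
  )
}

#' Membership of the two clusters below the dendrogram root
#' @param dend a `gxp_dendrogram`.
#' @return List of two character vectors of labels.
#' @export
root_split <- function(dend) {
  collect <- function(node) {
    if (node < 0L) return(-node)
    c(collect(dend$merge[node, 1L]), collect(dend$merge[node, 2L]))
  }
  top <- nrow(dend$merge)
  list(
    left = dend$labels[collect(dend$merge[top, 1L])],
    right = dend$labels[collect(dend$merge[top, 2L])]
  )
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are differences between merge heights, so tip-to-node
#' depths reproduce the dendrogram geometry (ultrametric tree).
#'
#' @param dend a `gxp_dendrogram`.
#' @param path optional file path; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to a file).
#' @export
as_newick <- function(dend, path = NULL) {
  esc <- function(lab) gsub("[,;:() ]", "_", lab)
  node_str <- function(node, parent_h) {
    if (node < 0L) return(sprintf("%s:%.10g", esc(dend$labels[-node]), parent_h))
    h <- dend$height[node]
    sprintf("(%s,%s):%.10g",
            node_str(dend$merge[node, 1L], h),
            node_str(dend$merge[node, 2L], h),
            parent_h - h)
  }
  top <- nrow(dend$merge)
  h <- dend$height[top]
  nwk <- sprintf("(%s,%s);",
                 node_str(dend$merge[top, 1L], h),
                 node_str(dend$merge[top, 2L], h))
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Order a distance matrix by dendrogram leaves for heatmap display
#'
#' Permutes the likeness matrix to the dendrogram's leaf order. In
#' correlation mode the displayed cell values are the correlation
#' coefficients; in Euclidean mode the distances themselves.
#'
#' @param dm a `gxp_distance`.
#' @param dend the matching `gxp_dendrogram`.
#' @return A `gxp_heatmap`: `labels` (leaf order), `values` (permuted
#'   matrix), `value_kind` (`"correlation"` or `"distance"`), `dendrogram`.
#' @export
heatmap_result <- function(dm, dend) {
  stopifnot(inherits(dm, "gxp_distance"), inherits(dend, "gxp_dendrogram"))
  if (!identical(sort(dm$labels), sort(dend$labels))) {
    stop("distance matrix and dendrogram label sets differ", call. = FALSE)
  }
  perm <- match(dend$labels[dend$order], dm$labels)
  vals <- if (!is.null(dm$C)) dm$C else dm$D
  structure(
    list(
      labels = dm$labels[perm],
      values = vals[perm, perm, drop = FALSE],
      value_kind = if (!is.null(dm$C)) "correlation" else "distance",
      dendrogram = dend
    ),
    class = "gxp_heatmap"
  )
}

#' Render a clustering heatmap with dendrogram and color scale to SVG
#'
#' @param hm a `gxp_heatmap` from [heatmap_result()].
#' @param path output file path.
#' @param cell pixel size of one heatmap cell.
#' @return `path`, invisibly.
#' @export
render_heatmap_svg <- function(hm, path, cell = 18) {
  n <- length(hm$labels)
  label_w <- 110
  dend_h <- 70
  legend_h <- 40
  w <- label_w + n * cell + 30
  h <- dend_h + n * cell + label_w + legend_h

  if (hm$value_kind == "correlation") {
    dom <- c(-1, 1)
    colf <- diverging_color_fn(1)
  } else {
    dom <- range(hm$values)
    colf <- sequential_color_fn(dom)
  }
  x0 <- label_w
  y0 <- dend_h
  body <- character(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      body <- c(body, svg_rect(x0 + (j - 1) * cell, y0 + (i - 1) * cell, cell, cell,
        list(class = "heatmap-cell", fill = colf(hm$values[i, j]),
             "data-row" = hm$labels[i], "data-col" = hm$labels[j],
             "data-value" = sprintf("%.6g", hm$values[i, j]))))
    }
    body <- c(body, svg_text(x0 - 4, y0 + (i - 0.5) * cell + 3, hm$labels[i],
      list(class = "row-label", "text-anchor" = "end", "font-size" = 9)))
    body <- c(body, svg_text(x0 + (i - 0.5) * cell, y0 + n * cell + 10, hm$labels[i],
      list(class = "col-label", "font-size" = 9,
           transform = sprintf("rotate(90 %s %s)", svg_num(x0 + (i - 0.5) * cell),
                               svg_num(y0 + n * cell + 10)))))
  }

  # dendrogram above columns, drawn from merge heights
  dend <- hm$dendrogram
  maxh <- max(dend$height)
  if (maxh == 0) maxh <- 1
  leaf_x <- stats::setNames(x0 + (seq_len(n) - 0.5) * cell, hm$labels)
  node_pos <- function(node) {
    if (node < 0L) {
      list(x = unname(leaf_x[dend$labels[-node]]), y = y0 - 2)
    } else {
      l <- node_pos(dend$merge[node, 1L]); r <- node_pos(dend$merge[node, 2L])
      yy <- y0 - 2 - (dend$height[node] / maxh) * (dend_h - 10)
      seg <<- c(seg,
        svg_line(l$x, l$y, l$x, yy, list(class = "dend", stroke = "#000")),
        svg_line(r$x, r$y, r$x, yy, list(class = "dend", stroke = "#000")),
        svg_line(l$x, yy, r$x, yy, list(class = "dend", stroke = "#000")))
      list(x = (l$x + r$x) / 2, y = yy)
    }
  }
  seg <- character(0)
  invisible(node_pos(nrow(dend$merge)))
  body <- c(body, seg)

  # color scale legend
  ly <- dend_h + n * cell + label_w + 6
  steps <- 40
  for (k in seq_len(steps)) {
    v <- dom[1] + (k - 0.5) / steps * diff(dom)
    body <- c(body, svg_rect(x0 + (k - 1) * 3, ly, 3, 12,
      list(class = "legend-step", fill = colf(v))))
  }
  body <- c(body,
    svg_text(x0, ly + 24, sprintf("%.3g", dom[1]), list(class = "legend-min", "font-size" = 9)),
    svg_text(x0 + steps * 3, ly + 24, sprintf("%.3g", dom[2]),
      list(class = "legend-max", "text-anchor" = "end", "font-size" = 9)),
    svg_text(x0 + steps * 3 + 8, ly + 10, hm$value_kind, list("font-size" = 9)))

  write_svg(svg_document(w, h, body), path)
}

#' Principal component analysis of samples
#'
#' Treats samples (columns of the expression matrix) as observations and
#' entities as variables; every data point participates (no filtering).
#' Observations are centered per variable, optionally z-scaled, and
#' decomposed by singular value decomposition. Component signs are fixed
#' deterministically: the loading with the largest magnitude in each
#' component is made positive.
#'
#' @param M numeric matrix, `gxp_expression` or `gxp_zmatrix` (rows =
#'   entities, columns = samples).
#' @param scale z-scale entities to unit variance before decomposition
#'   (constant entities are dropped from scaling with their variance left
#'   at zero).
#' @return A `gxp_pca`: `scores` (samples x components),
#'   `loadings` (entities x components), `explained_fraction`,
#'   `component_labels`, `sample_labels`.
#' @export
run_pca <- function(M, scale = FALSE) {
  X <- t(as_value_matrix(M)) # samples x entities
  if (nrow(X) < 2L) stop("need at least 2 samples", call. = FALSE)
  sample_labels <- rownames(X)
  if (is.null(sample_labels)) sample_labels <- paste0("sample", seq_len(nrow(X)))
  Xc <- base::scale(X, center = TRUE, scale = FALSE)
  if (scale) {
    sds <- apply(Xc, 2L, stats::sd)
    nz <- sds > 0
    Xc[, nz] <- sweep(Xc[, nz, drop = FALSE], 2L, sds[nz], "/")
    Xc[, !nz] <- 0
  }
  s <- svd(Xc)
  ncomp <- length(s$d)
  scores <- s$u %*% diag(s$d, ncomp, ncomp)
  loadings <- s$v
  # deterministic sign: largest-|loading| entry positive per component
  for (k in seq_len(ncomp)) {
    piv <- which.max(abs(loadings[, k]))
    if (loadings[piv, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  ev <- s$d^2
  explained <- if (sum(ev) > 0) ev / sum(ev) else rep(0, ncomp)
  labels <- paste0("PC", seq_len(ncomp))
  dimnames(scores) <- list(sample_labels, labels)
  dimnames(loadings) <- list(colnames(X), labels)
  structure(
    list(
      scores = scores, loadings = loadings, explained_fraction = explained,
      component_labels = labels, sample_labels = sample_labels, scaled = scale
    ),
    class = "gxp_pca"
  )
}

#' @export
print.gxp_pca <- function(x, ...) {
  cat(sprintf(
    "gxp PCA: %d samples, PC1 %.1f%%, PC2 %s\n",
    nrow(x$scores), 100 * x$explained_fraction[1],
    if (length(x$explained_fraction) > 1L) sprintf("%.1f%%", 100 * x$explained_fraction[2]) else "-"
  ))
  invisible(x)
}

#' Build a PCA scatter-plot specification
#'
#' Points are the first two principal components; replicates sharing the
#' same group-factor and x-axis-factor combination receive the same color
#' class; axis labels state the percentage of variance each component
#' explains.
#'
#' @param res a `gxp_pca`.
#' @param sample_keys list of `gxp_sample_key` matching the PCA samples
#'   (e.g. `expr$samples`).
#' @return A `gxp_plot_spec` with `kind = "scatter"`.
#' @export
pca_plot_spec <- function(res, sample_keys) {
  stopifnot(inherits(res, "gxp_pca"), length(sample_keys) == nrow(res$scores))
  classes <- vapply(sample_keys, function(k) {
    paste(c(k$group_values, k$x_value), collapse = " / ")
  }, "")
  class_levels <- unique(classes)
  colors <- stats::setNames(gxp_palette(length(class_levels)), class_levels)
  pts <- data.frame(
    label = res$sample_labels,
    x = res$scores[, 1L],
    y = if (ncol(res$scores) > 1L) res$scores[, 2L] else 0,
    class = classes,
    color = unname(colors[classes]),
    stringsAsFactors = FALSE
  )
  rownames(pts) <- NULL
  structure(
    list(
      kind = "scatter", points = pts, color_classes = class_levels,
      x_label = sprintf("PC1 (%.1f%%)", 100 * res$explained_fraction[1]),
      y_label = sprintf("PC2 (%.1f%%)", 100 * if (length(res$explained_fraction) > 1L) res$explained_fraction[2] else 0)
    ),
    class = "gxp_plot_spec"
  )
}

#' Render a PCA scatter specification to SVG
#' @param spec a `gxp_plot_spec` of kind `"scatter"`.
#' @param path output file path.
#' @param width,height canvas size in pixels.
#' @return `path`, invisibly.
#' @export
render_scatter_svg <- function(spec, path, width = 460, height = 400) {
  stopifnot(inherits(spec, "gxp_plot_spec"), identical(spec$kind, "scatter"))
  m <- list(left = 60, right = 130, top = 20, bottom = 50)
  px <- c(m$left, width - m$right)
  py <- c(height - m$bottom, m$top)
  xd <- range(spec$points$x); yd <- range(spec$points$y)
  pad <- function(d) d + c(-1, 1) * (diff(d) * 0.06 + 1e-9)
  sx <- scale_linear(pad(xd), px); sy <- scale_linear(pad(yd), py)
  body <- c(
    svg_line(px[1], py[1], px[2], py[1], list(stroke = "#000")),
    svg_line(px[1], py[1], px[1], py[2], list(stroke = "#000")),
    svg_text(mean(px), height - 12, spec$x_label,
      list(class = "x-axis-label", "text-anchor" = "middle", "font-size" = 12)),
    svg_text(16, mean(py), spec$y_label,
      list(class = "y-axis-label", "text-anchor" = "middle", "font-size" = 12,
           transform = sprintf("rotate(-90 16 %s)", svg_num(mean(py)))))
  )
  for (i in seq_len(nrow(spec$points))) {
    p <- spec$points[i, ]
    body <- c(body, svg_tag("circle", list(
      class = "pca-point", cx = svg_num(sx(p$x)), cy = svg_num(sy(p$y)), r = 4,
      fill = p$color, "data-sample" = p$label, "data-class" = p$class
    )))
  }
  for (k in seq_along(spec$color_classes)) {
    cl <- spec$color_classes[k]
    col <- spec$points$color[match(cl, spec$points$class)]
    body <- c(body,
      svg_rect(width - m$right + 12, m$top + (k - 1) * 14, 9, 9,
        list(fill = col, class = "legend-swatch")),
      svg_text(width - m$right + 25, m$top + (k - 1) * 14 + 8, cl,
        list(class = "legend-label", "font-size" = 9)))
  }
  write_svg(svg_document(width, height, body), path)
}
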