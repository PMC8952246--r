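# in-code fixtures and independent oracles shared across the suite

write_tiny_counts <- function(path,
                              header = c("id", "A.ctrl.1", "A.ctrl.2", "A.cold.1", "A.cold.2"),
                              rows = list(
                                c("g1", "1", "2", "3", "4"),
                                c("g2", "10", "12", "8", "6"),
                                c("g3", "5", "5", "5", "5")
                              ),
                              sep = "\t") {
  lines <- c(paste(header, collapse = sep),
             vapply(rows, paste, "", collapse = sep))
  writeLines(lines, path)
  path
}

write_tiny_info <- function(path,
                            header = c("id", "log2FC", "bins", "description"),
                            rows = list(
                              c("g1", "-2", "1.1,9.1.4.2", "chalcone synthase homolog"),
                              c("g2", "0.5", "9.1", "urea transporter"),
                              c("g3", "", "1.1.1", "chalcone synthase like")
                            ),
                            sep = "\t") {
  lines <- c(paste(header, collapse = sep),
             vapply(rows, paste, "", collapse = sep))
  writeLines(lines, path)
  path
}

tiny_expr <- function() {
  vals <- matrix(c(1, 2, 3, 4, 10, 12, 8, 6, 5, 5, 5, 5),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("g1", "g2", "g3"),
                    c("A.ctrl.1", "A.ctrl.2", "A.cold.1", "A.cold.2"))
  )
  gxp_expression(vals, unit = "TPM")
}

# ---- independent oracles -------------------------------------------------

# Fisher one-sided (greater) by exhaustive enumeration with exact binomial
# coefficients; independent of the package's log-space implementation
oracle_fisher_greater <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  K <- a + c_
  n <- a + b
  ks <- a:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# step-up BH adjustment computed the long way
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i) # rank of p[i] (ties resolved by order())
    adj[i] <- min(1, min(m * p[ord][rank_i:m] / (rank_i:m)))
  }
  adj
}

# brute-force agglomeration from cluster member sets; linkage distance is
# recomputed from the original matrix at every step (no Lance-Williams)
oracle_agglomerate <- function(D, linkage) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  merges <- list()
  link_d <- function(A, B) {
    dd <- D[A, B, drop = FALSE]
    switch(linkage,
      single = min(dd), complete = max(dd), average = mean(dd)
    )
  }
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dij <- link_d(clusters[[i]], clusters[[j]])
        key <- c(dij, sort(c(min(clusters[[i]]), min(clusters[[j]]))))
        if (is.null(best) ||
            key[1] < best$key[1] - 1e-12 ||
            (abs(key[1] - best$key[1]) <= 1e-12 &&
             (key[2] < best$key[2] || (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1L]] <- list(members = merged, height = best$key[1])
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  merges
}

# merge sequence of a gxp_dendrogram in the same representation
dendrogram_merge_sets <- function(dend) {
  sets <- vector("list", nrow(dend$merge))
  members <- function(node) {
    if (node < 0L) -node else sets[[node]]
  }
  out <- list()
  for (s in seq_len(nrow(dend$merge))) {
    m <- sort(c(members(dend$merge[s, 1L]), members(dend$merge[s, 2L])))
    sets[[s]] <- m
    out[[s]] <- list(members = m, height = dend$height[s])
  }
  out
}

sample_group_of <- function(expr) {
  vapply(expr$samples, function(k) paste(k$group_values, collapse = "."), "")
}
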