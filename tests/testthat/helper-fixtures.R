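# Shared fixture builders and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# gene table with given chromosome sizes; ids <prefix>_<chrom>_<rank>
mk_genes <- function(genome, chrom_sizes, prefix = genome) {
  do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    k <- chrom_sizes[[ch]]
    data.frame(genome_id = genome, chrom = ch,
               start = (0:(k - 1)) * 1000L + 1L,
               end = (0:(k - 1)) * 1000L + 600L,
               strand = "+",
               gene_id = sprintf("%s_%s_%03d", prefix, ch, seq_len(k)),
               order_index = 0:(k - 1),
               stringsAsFactors = FALSE)
  }))
}

mk_block <- function(id, ga, gb, genome_a = "A", genome_b = "B",
                     chrom_a = "c1", chrom_b = "c1", ks = NULL,
                     orientation = "same") {
  synteny_block(id, genome_a, genome_b, chrom_a, chrom_b,
                pairs = data.frame(gene_a = ga, gene_b = gb,
                                   ks = ks %||% rep(NA_real_, length(ga)),
                                   stringsAsFactors = FALSE),
                orientation = orientation)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random annotated blocks whose floats are exact at 4 decimals, so the
# canonical write/read round trip is an identity
random_blocks <- function(n_blocks, rng_seed) {
  set.seed(rng_seed)
  lapply(seq_len(n_blocks), function(i) {
    m <- sample(1:12, 1)
    ks <- round(runif(m, 0, 3), 4)
    ks[runif(m) < 0.3] <- NA
    b <- synteny_block(
      sprintf("blk%03d", i), "genomeA", "genomeB",
      chrom_a = sample(c("c1", "c2", NA), 1), chrom_b = sample(c("d1", "d2"), 1),
      pairs = data.frame(gene_a = sprintf("a%03d_%d", sample(999, m), i),
                         gene_b = sprintf("b%03d_%d", sample(999, m), i),
                         ks = ks,
                         is_ortholog = sample(c(TRUE, FALSE, NA), m, replace = TRUE),
                         stringsAsFactors = FALSE),
      orientation = sample(c("same", "inverted"), 1))
    if (runif(1) < 0.8) {
      b$oi <- round(runif(1), 4)
      b$median_ks <- round(runif(1, 0, 2), 4)
    }
    b
  })
}

expect_blocks_equal <- function(got, want, check_n = FALSE) {
  expect_length(got, length(want))
  for (i in seq_along(want)) {
    g <- got[[i]]; w <- want[[i]]
    expect_identical(g$block_id, w$block_id)
    expect_identical(c(g$genome_a, g$genome_b), c(w$genome_a, w$genome_b))
    expect_identical(c(g$chrom_a, g$chrom_b), c(w$chrom_a, w$chrom_b))
    expect_identical(g$orientation, w$orientation)
    expect_identical(g$m, w$m)
    expect_equal(g$oi, w$oi)
    expect_equal(g$median_ks, w$median_ks)
    expect_identical(g$pairs$gene_a, w$pairs$gene_a)
    expect_identical(g$pairs$gene_b, w$pairs$gene_b)
    expect_equal(g$pairs$ks, w$pairs$ks)
    expect_identical(g$pairs$is_ortholog, w$pairs$is_ortholog)
    if (check_n) expect_identical(g$n, w$n)
  }
}

# --- dialect writers (test-side only) ------------------------------------

write_mcscanx_fixture <- function(blocks, path) {
  lines <- c("############### Parameters ###############", "# MATCH_SCORE: 50")
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    lines <- c(lines, sprintf(
      "## Alignment %s: score=%.1f e_value=0 N=%d %s&%s %s",
      b$block_id, 50 * b$m, b$m, b$chrom_a, b$chrom_b,
      if (b$orientation == "inverted") "minus" else "plus"))
    lines <- c(lines, sprintf("%3d-%3d:\t%s\t%s\t      0",
                              i - 1L, seq_len(b$m) - 1L,
                              b$pairs$gene_a, b$pairs$gene_b))
  }
  writeLines(lines, path)
}

write_anchors_fixture <- function(blocks, path) {
  lines <- character(0)
  for (b in blocks) {
    lines <- c(lines, "###", paste(b$pairs$gene_a, b$pairs$gene_b, "100", sep = "\t"))
  }
  writeLines(lines, path)
}

write_wgdi_fixture <- function(blocks, path) {
  rows <- vapply(blocks, function(b) {
    ks <- ifelse(is.na(b$pairs$ks), "NA", formatC(b$pairs$ks, format = "f", digits = 4))
    paste(b$block_id, b$chrom_a, b$chrom_b,
          paste(b$pairs$gene_a, collapse = ";"),
          paste(b$pairs$gene_b, collapse = ";"),
          paste(ks, collapse = ";"), sep = ",")
  }, "")
  writeLines(c("id,chr1,chr2,block1,block2,ks", rows), path)
}

# --- independent MCL oracle ----------------------------------------------
# Dense implementation of the same documented algorithm (self-loops = max
# incident weight, column normalization, expansion/inflation with pruning),
# with the cluster read-out done through igraph's component finder on the
# limit support instead of the package's union-find.

mcl_oracle <- function(graph, inflation = 1.5, expansion = 2L,
                       max_iter = 200L, tol = 1e-9, prune = 1e-5) {
  ids <- sort(graph$nodes$gene_id)
  n <- length(ids)
  if (n == 0) return(list())
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(graph$edges))) {
    a <- graph$edges$gene_a[k]; b <- graph$edges$gene_b[k]
    A[a, b] <- A[b, a] <- graph$edges$weight[k]
  }
  diag(A) <- pmax(apply(A, 2, max), .Machine$double.eps)
  M <- A %*% diag(1 / colSums(A))
  for (it in seq_len(max_iter)) {
    E <- M
    for (e in seq_len(expansion - 1L)) E <- E %*% M
    I <- E^inflation
    cm <- apply(I, 2, max)
    I[I < prune & sweep(I, 2, cm, "<")] <- 0
    I <- I %*% diag(1 / colSums(I))
    if (max(abs(I - M)) < tol) { M <- I; break }
    M <- I
  }
  S <- (M > 0) | (t(M) > 0)
  g <- igraph::graph_from_adjacency_matrix(S * 1, mode = "max", diag = FALSE)
  comp <- igraph::components(g)$membership
  unname(split(ids, comp))
}

canonical_partition <- function(clusters) {
  cl <- lapply(clusters, function(x) sort(unname(x)))
  unname(cl[order(vapply(cl, `[`, "", 1))])
}

partition_from_membership <- function(membership) {
  canonical_partition(split(names(membership), membership))
}

random_graph <- function(n_nodes, p_edge, rng_seed) {
  set.seed(rng_seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  comb <- t(combn(ids, 2))
  keep <- runif(nrow(comb)) < p_edge
  edges <- data.frame(gene_a = comb[keep, 1], gene_b = comb[keep, 2],
                      weight = round(runif(sum(keep), 0.1, 1), 3),
                      stringsAsFactors = FALSE)
  structure(list(nodes = data.frame(gene_id = ids,
                                    genome_id = rep(c("X", "Y"), length.out = n_nodes),
                                    stringsAsFactors = FALSE),
                 edges = edges),
            class = "syntenic_graph")
}

# --- independent chaining oracle -----------------------------------------
# Same documented greedy rule as detect_blocks (sorted by x then y; a pair
# joins the reachable chain with the smallest dx + |dy|, ties to the oldest
# chain; direction fixed by the second pair), written as a plain quadratic
# scan over all chains.

chain_oracle <- function(x, y, max_gap) {
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  chains <- list()
  for (p in seq_along(x)) {
    best <- 0; best_cost <- Inf
    for (ci in seq_along(chains)) {
      ch <- chains[[ci]]
      last <- ch$pts[length(ch$pts)]
      dx <- x[p] - x[last]; dy <- y[p] - y[last]
      if (dx >= 1 && dx <= max_gap && abs(dy) >= 1 && abs(dy) <= max_gap &&
          (is.na(ch$dir) || sign(dy) == ch$dir)) {
        cost <- dx + abs(dy)
        if (cost < best_cost) { best_cost <- cost; best <- ci }
      }
    }
    if (best > 0) {
      last <- chains[[best]]$pts[length(chains[[best]]$pts)]
      if (is.na(chains[[best]]$dir)) {
        chains[[best]]$dir <- as.integer(sign(y[p] - y[last]))
      }
      chains[[best]]$pts <- c(chains[[best]]$pts, p)
    } else {
      chains[[length(chains) + 1]] <- list(pts = p, dir = NA_integer_)
    }
  }
  lapply(chains, function(ch) ord[ch$pts])
}

assign_order_index_for_test <- function(df) synorth:::assign_order_index(df)
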