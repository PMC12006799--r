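# syntenic graph construction, MCL clustering, SOG post-processing

annotated_triangle <- function() {
  # 3 genomes, pairs (a,b), (b,c), (a,c)
  blocks <- list(mk_block("ab", "a1", "b1", "A", "B"),
                 mk_block("bc", "b1", "c1", "B", "C"),
                 mk_block("ac", "a1", "c1", "A", "C"))
  for (i in seq_along(blocks)) blocks[[i]]$oi <- 0.9
  blocks
}

test_that("build_graph makes one edge per distinct pair with max-OI weights", {
  g <- build_graph(annotated_triangle())
  expect_identical(nrow(g$nodes), 3L)
  expect_identical(nrow(g$edges), 3L)
  expect_identical(sort(g$nodes$genome_id), c("A", "B", "C"))

  # pair supported by two blocks with OI 0.7 and 0.9 -> weight 0.9
  b1 <- mk_block("x1", "a1", "b1", "A", "B"); b1$oi <- 0.7
  b2 <- mk_block("x2", "a1", "b1", "A", "B"); b2$oi <- 0.9
  g2 <- build_graph(list(b1, b2))
  expect_identical(nrow(g2$edges), 1L)
  expect_equal(g2$edges$weight, 0.9)
  expect_equal(build_graph(list(b1, b2), weight_mode = "unit")$edges$weight, 1)

  expect_identical(nrow(build_graph(list())$edges), 0L)

  self <- mk_block("bad", "a1", "a2", "A", "A"); self$oi <- 1
  expect_error(build_graph(list(self)), "within-genome")
})

test_that("MCL keeps two disconnected 3-cliques separate and covers all nodes", {
  blocks <- c(lapply(list(c("a1", "b1"), c("b1", "c1"), c("a1", "c1")), function(p)
                mk_block(paste(p, collapse = ""), p[1], p[2],
                         toupper(substr(p[1], 1, 1)), toupper(substr(p[2], 1, 1)))),
              lapply(list(c("a2", "b2"), c("b2", "c2"), c("a2", "c2")), function(p)
                mk_block(paste(p, collapse = ""), p[1], p[2],
                         toupper(substr(p[1], 1, 1)), toupper(substr(p[2], 1, 1)))))
  for (i in seq_along(blocks)) blocks[[i]]$oi <- 0.9
  part <- mcl(build_graph(blocks))
  clusters <- partition_from_membership(part$membership)
  expect_length(clusters, 2)
  expect_identical(clusters[[1]], c("a1", "b1", "c1"))
  expect_identical(clusters[[2]], c("a2", "b2", "c2"))
  expect_true(part$converged)
  # partition property: disjoint cover
  expect_identical(sort(unname(unlist(clusters))), sort(names(part$membership)))
})

test_that("an isolated node is its own singleton cluster", {
  g <- structure(list(nodes = data.frame(gene_id = "solo", genome_id = "A",
                                         stringsAsFactors = FALSE),
                      edges = data.frame(gene_a = character(0),
                                         gene_b = character(0),
                                         weight = numeric(0))),
                 class = "syntenic_graph")
  part <- mcl(g)
  expect_identical(unname(part$membership), 1L)
})

test_that("inflation must exceed 1", {
  expect_error(mcl(build_graph(annotated_triangle()), inflation = 1), "> 1")
})

test_that("a weakly bridged barbell splits into its two cliques, matching the oracle", {
  ids <- list(left = c("l1", "l2", "l3", "l4"), right = c("r1", "r2", "r3", "r4"))
  edges <- do.call(rbind, lapply(ids, function(v) {
    cmb <- t(combn(v, 2))
    data.frame(gene_a = cmb[, 1], gene_b = cmb[, 2], weight = 1,
               stringsAsFactors = FALSE)
  }))
  edges <- rbind(edges, data.frame(gene_a = "l1", gene_b = "r1", weight = 0.1))
  g <- structure(list(nodes = data.frame(gene_id = unlist(ids),
                                         genome_id = rep(c("X", "Y"), 4),
                                         stringsAsFactors = FALSE),
                      edges = edges), class = "syntenic_graph")
  part <- mcl(g, inflation = 1.5)
  got <- partition_from_membership(part$membership)
  want <- canonical_partition(mcl_oracle(g, inflation = 1.5))
  expect_identical(got, want)
  expect_length(got, 2)
  expect_identical(got[[1]], sort(ids$left))
})

test_that("MCL is deterministic and matches the dense oracle on random graphs", {
  for (seed in 1:30) {
    g <- random_graph(n_nodes = sample(2:12, 1), p_edge = runif(1, 0.15, 0.6),
                      rng_seed = 1000 + seed)
    part1 <- mcl(g)
    part2 <- mcl(g)
    expect_identical(part1$membership, part2$membership)
    got <- partition_from_membership(part1$membership)
    want <- canonical_partition(mcl_oracle(g))
    expect_identical(got, want)
    # partition: disjoint cover of all nodes
    expect_identical(sort(unname(unlist(got))), sort(g$nodes$gene_id))
  }
})

test_that("MCL never merges disconnected components", {
  for (seed in 1:10) {
    g1 <- random_graph(6, 0.7, 2000 + seed)
    g2 <- random_graph(6, 0.7, 3000 + seed)
    g2$nodes$gene_id <- sub("^n", "m", g2$nodes$gene_id)
    g2$edges$gene_a <- sub("^n", "m", g2$edges$gene_a)
    g2$edges$gene_b <- sub("^n", "m", g2$edges$gene_b)
    g <- structure(list(nodes = rbind(g1$nodes, g2$nodes),
                        edges = rbind(g1$edges, g2$edges)),
                   class = "syntenic_graph")
    part <- mcl(g)
    for (cl in partition_from_membership(part$membership)) {
      expect_true(all(startsWith(cl, "n")) || all(startsWith(cl, "m")))
    }
  }
})

test_that("make_sogs classifies copy number and occupancy; singletons drop", {
  blocks <- c(annotated_triangle(),
              list(mk_block("dup", "a9", "b9", "A", "B"),
                   mk_block("dup2", "a9b", "b9", "A", "B")))
  blocks[[4]]$oi <- blocks[[5]]$oi <- 0.9
  part <- mcl(build_graph(blocks))
  sogs <- make_sogs(part, genomes = c("A", "B", "C"))
  expect_length(sogs, 2)
  cls <- vapply(sogs, `[[`, "", "class")
  expect_setequal(cls, c("single_copy", "multi_copy"))
  single <- sogs[[which(cls == "single_copy")]]
  expect_equal(single$taxon_occupancy, 1)
  expect_identical(single$copy_profile, c(A = 1L, B = 1L, C = 1L))
  multi <- sogs[[which(cls == "multi_copy")]]
  expect_equal(multi$taxon_occupancy, 2 / 3)
  expect_identical(sort(unname(unlist(multi$members))), c("a9", "a9b", "b9"))
  expect_match(sogs[[1]]$sog_id, "^SOG[0-9]{5}$")
})

test_that("single-genome clusters are excluded from SOG output", {
  nodes <- data.frame(gene_id = c("a1", "a2"), genome_id = "A",
                      stringsAsFactors = FALSE)
  part <- structure(list(membership = setNames(c(1L, 1L), c("a1", "a2")),
                         nodes = nodes, n_iter = 1L, converged = TRUE),
                    class = "mcl_partition")
  sogs <- make_sogs(part, genomes = c("A", "B"))
  expect_length(sogs, 0)
  expect_identical(attr(sogs, "singletons"), 1L)
})

test_that("filter_sogs keeps the 40% boundary, filters by class, is monotone", {
  mk_sog <- function(id, genomes, copies = 1L) {
    members <- setNames(lapply(genomes, function(g)
      sprintf("%s_%s_%d", tolower(g), id, seq_len(copies))), genomes)
    profile <- vapply(members, length, 0L)
    structure(list(sog_id = id, members = members, copy_profile = profile,
                   class = if (all(profile == 1L)) "single_copy" else "multi_copy",
                   taxon_occupancy = length(genomes) / 10),
              class = "sog")
  }
  sogs <- list(mk_sog("S1", paste0("G", 1:6)),          # missing 0.4: boundary
               mk_sog("S2", paste0("G", 1:5)),          # missing 0.5: drop
               mk_sog("S3", paste0("G", 1:10), copies = 2L))
  kept <- filter_sogs(sogs, max_missing = 0.4)
  expect_identical(vapply(kept, `[[`, "", "sog_id"), c("S1", "S3"))
  expect_identical(attr(kept, "counts"),
                   c(single_copy = 1L, multi_copy = 1L))
  expect_identical(vapply(filter_sogs(sogs, 0.4, mode = "single"), `[[`, "", "sog_id"),
                   "S1")
  expect_identical(vapply(filter_sogs(sogs, 0.4, mode = "multi"), `[[`, "", "sog_id"),
                   "S3")
  # monotone in max_missing
  prev <- character(0)
  for (mm in c(0, 0.2, 0.4, 0.6, 0.9)) {
    ids <- vapply(filter_sogs(sogs, mm), `[[`, "", "sog_id")
    expect_true(all(prev %in% ids))
    prev <- ids
  }
  expect_error(filter_sogs(sogs, 1), "\\[0, 1\\)")
  expect_error(filter_sogs(sogs, -0.1), "\\[0, 1\\)")
})

test_that("outgroup genes attach by majority, then weight, then sog_id; ingroup reuse errors", {
  blocks <- annotated_triangle()
  part <- mcl(build_graph(blocks))
  sogs <- make_sogs(part, genomes = c("A", "B", "C"))
  # second SOG to compete for attachment
  extra <- list(mk_block("ab2", "a2", "b2", "A", "B"))
  extra[[1]]$oi <- 0.9
  part2 <- mcl(build_graph(c(blocks, extra)))
  sogs <- make_sogs(part2, genomes = c("A", "B", "C"))
  expect_length(sogs, 2)

  og <- function(id, og_gene, in_genes, oi = 0.8) {
    b <- mk_block(id, in_genes, rep(og_gene, length(in_genes)), "A", "O")
    b$oi <- oi
    b
  }
  # o1 linked 3x to the triangle SOG, 1x to the pair SOG -> majority
  aug <- attach_outgroup(sogs, list(
    og("l1", "o1", "a1"), og("l2", "o1", "a1"), og("l3", "o1", "a1"),
    og("l4", "o1", "a2")))
  in_sog1 <- vapply(aug, function(s) "o1" %in% unlist(s$members), TRUE)
  expect_identical(which(in_sog1),
                   which(vapply(aug, function(s) "a1" %in% unlist(s$members), TRUE)))
  # classification untouched
  expect_identical(vapply(aug, `[[`, "", "class"),
                   vapply(sogs, `[[`, "", "class"))

  # unlinked outgroup gene is reported, not attached
  aug2 <- attach_outgroup(sogs, list(og("l5", "o9", "zz_unknown")))
  expect_identical(attr(aug2, "unattached"), "o9")

  # a block joining two ingroup genomes is a hard error
  bad <- mk_block("bad", "a1", "b1", "A", "B"); bad$oi <- 1
  expect_error(attach_outgroup(sogs, list(bad)), "ingroup")
})

test_that("outgroup ties resolve by summed weight", {
  b1 <- mk_block("s1", "a1", "b1", "A", "B"); b1$oi <- 0.9
  b2 <- mk_block("s2", "a2", "b2", "A", "B"); b2$oi <- 0.9
  sogs <- make_sogs(mcl(build_graph(list(b1, b2))), genomes = c("A", "B"))
  og <- function(id, in_gene, oi) {
    b <- mk_block(id, in_gene, "o1", "A", "O"); b$oi <- oi; b
  }
  aug <- attach_outgroup(sogs, list(og("w1", "a1", 0.9), og("w2", "a2", 0.6)))
  holds_o1 <- vapply(aug, function(s) "o1" %in% unlist(s$members), TRUE)
  expect_identical(holds_o1,
                   vapply(aug, function(s) "a1" %in% unlist(s$members), TRUE))
})

test_that("per-SOG FASTA export writes records and reports missing sequences", {
  blocks <- annotated_triangle()
  sogs <- make_sogs(mcl(build_graph(blocks)), genomes = c("A", "B", "C"))
  dir <- withr::local_tempdir()
  seqs <- c(a1 = "ATGGCT", b1 = "ATGGCA")  # c1 missing
  rep <- export_sog_sequences(sogs, seqs, dir)
  expect_identical(rep$n_written, 2L)
  expect_identical(rep$n_missing, 1L)
  fa <- readLines(file.path(dir, paste0(sogs[[1]]$sog_id, ".fasta")))
  expect_identical(sum(startsWith(fa, ">")), 2L)
  expect_true(any(fa == ">A|a1"))
  expect_true(file.exists(file.path(dir, "missing_sequences.txt")))

  # empty SOG list -> no FASTA files
  dir2 <- withr::local_tempdir()
  export_sog_sequences(list(), seqs, dir2)
  expect_length(list.files(dir2, pattern = "fasta$"), 0)
})
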