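# Collinear block detection by greedy gap-bounded chaining.
#
# Stands in for an external synteny detector inside the benchmark: per
# chromosome pair, homolog pairs are sorted by gene rank on the first
# genome and chained greedily.  A pair extends an open chain when its rank
# gap on both axes is between 1 and max_gap, in the chain's direction
# (fixed by the chain's second pair; same or inverted).  When several
# chains can take a pair the one with the smallest combined gap wins, ties
# going to the oldest chain, which makes the procedure deterministic.
# Chains with at least min_block pairs are emitted as syntenic blocks.

#' Collapse tandem-duplicate partners before chaining
#'
#' Synteny detectors prune tandem arrays before anchoring: when one gene
#' has several homolog partners within `tandem_max` gene ranks of each
#' other on the same chromosome of the other genome, only the best partner
#' is informative for collinearity (the rest are tandem copies).  This
#' keeps, per tandem run of partners, the pair with the smallest Ks
#' (missing Ks losing to any value), ties broken by the smaller gene rank,
#' applied to each genome side in turn.  Deterministic.
#'
#' @param pairs homolog pairs (`gene_a`, `gene_b`, optional `ks`).
#' @param genes_a,genes_b gene tables of the two genomes.
#' @param tandem_max maximum rank gap within a tandem run; 0 disables.
#' @return the reduced pair `data.frame`.
#' @export
collapse_tandem_partners <- function(pairs, genes_a, genes_b, tandem_max = 10L) {
  if (tandem_max < 1 || nrow(pairs) < 2) return(pairs)
  ks <- if (!is.null(pairs$ks)) as.numeric(pairs$ks) else rep(NA_real_, nrow(pairs))
  one_side <- function(pairs, ks, anchor, genes, partner_col) {
    r <- gene_ranks(pairs[[partner_col]], genes, "homolog pair")
    keep <- rep(TRUE, nrow(pairs))
    grp <- paste(pairs[[anchor]], r$chrom, sep = "\r")
    for (g in unique(grp[duplicated(grp)])) {
      idx <- which(grp == g)
      idx <- idx[order(r$rank[idx])]
      run <- cumsum(c(1L, diff(r$rank[idx]) > tandem_max))
      for (u in unique(run)) {
        members <- idx[run == u]
        if (length(members) < 2) next
        score <- ks[members]
        score[is.na(score)] <- Inf
        best <- members[order(score, r$rank[members])][1]
        keep[setdiff(members, best)] <- FALSE
      }
    }
    keep
  }
  keep <- one_side(pairs, ks, "gene_b", genes_a, "gene_a")
  pairs <- pairs[keep, , drop = FALSE]; ks <- ks[keep]
  keep <- one_side(pairs, ks, "gene_a", genes_b, "gene_b")
  pairs <- pairs[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Detect collinear blocks from homolog pairs
#'
#' @param pairs `data.frame` with columns `gene_a`, `gene_b` (and
#'   optionally `ks`): all cross-genome homolog pairs, orthologs and
#'   paralogs alike.
#' @param genes_a,genes_b gene tables of the two genomes.
#' @param min_block minimum chain length in pairs; default 5.
#' @param max_gap maximum rank gap on either axis; default 25.
#' @param tandem_max tandem-partner collapse window in gene ranks applied
#'   before chaining (see [collapse_tandem_partners()]); default 10,
#'   0 disables.
#' @return list of `synteny_block` objects, deterministic for fixed input.
#' @export
detect_blocks <- function(pairs, genes_a, genes_b, min_block = 5L, max_gap = 25L,
                          tandem_max = 10L) {
  ga <- unique(genes_a$genome_id); gb <- unique(genes_b$genome_id)
  if (nrow(pairs) == 0) return(list())
  pairs <- collapse_tandem_partners(pairs, genes_a, genes_b, tandem_max)
  ra <- gene_ranks(pairs$gene_a, genes_a, "homolog pair")
  rb <- gene_ranks(pairs$gene_b, genes_b, "homolog pair")
  ks <- if (!is.null(pairs$ks)) as.numeric(pairs$ks) else rep(NA_real_, nrow(pairs))
  dt <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b, ks = ks,
                   ca = ra$chrom, cb = rb$chrom, x = ra$rank, y = rb$rank,
                   stringsAsFactors = FALSE)
  blocks <- list()
  for (key in sort(unique(paste(dt$ca, dt$cb, sep = "\r")))) {
    cc <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- dt[dt$ca == cc[1] & dt$cb == cc[2], , drop = FALSE]
    sub <- sub[order(sub$x, sub$y), , drop = FALSE]
    chains <- chain_pairs(sub$x, sub$y, max_gap)
    for (ch in chains) {
      if (length(ch$idx) < min_block) next
      blocks[[length(blocks) + 1L]] <- synteny_block(
        block_id = sprintf("%s.%s__%s.%s__%03d", ga, cc[1], gb, cc[2],
                           length(blocks) + 1L),
        genome_a = ga, genome_b = gb, chrom_a = cc[1], chrom_b = cc[2],
        pairs = data.frame(gene_a = sub$gene_a[ch$idx],
                           gene_b = sub$gene_b[ch$idx],
                           ks = sub$ks[ch$idx], stringsAsFactors = FALSE),
        orientation = if (identical(ch$dir, -1L)) "inverted" else "same")
    }
  }
  # stable global ids
  for (i in seq_along(blocks)) {
    blocks[[i]]$block_id <- sub("__[0-9]+$", sprintf("__%03d", i),
                                blocks[[i]]$block_id)
  }
  blocks
}

# greedy chaining core; x sorted ascending (ties by y).  Returns list of
# chains, each list(idx = row indices in input order, dir = +1/-1/NA).
chain_pairs <- function(x, y, max_gap) {
  n <- length(x)
  chains <- list()
  open <- integer(0)  # indices into `chains` still extendable
  for (p in seq_len(n)) {
    # drop chains that can no longer be reached on the x axis
    if (length(open)) {
      lastx <- vapply(open, function(ci) chains[[ci]]$lx, 0)
      open <- open[x[p] - lastx <= max_gap]
    }
    best <- 0L; best_cost <- Inf
    for (ci in open) {
      ch <- chains[[ci]]
      dx <- x[p] - ch$lx
      dy <- y[p] - ch$ly
      if (dx < 1 || dx > max_gap) next
      ady <- abs(dy)
      if (ady < 1 || ady > max_gap) next
      if (!is.na(ch$dir) && sign(dy) != ch$dir) next
      cost <- dx + ady
      if (cost < best_cost) { best_cost <- cost; best <- ci }
    }
    if (best > 0L) {
      ch <- chains[[best]]
      dy <- y[p] - ch$ly
      if (is.na(ch$dir)) ch$dir <- as.integer(sign(dy))
      ch$idx <- c(ch$idx, p)
      ch$lx <- x[p]; ch$ly <- y[p]
      chains[[best]] <- ch
    } else {
      chains[[length(chains) + 1L]] <- list(idx = p, lx = x[p], ly = y[p],
                                            dir = NA_integer_)
      open <- c(open, length(chains))
    }
  }
  lapply(chains, function(ch) list(idx = ch$idx, dir = ch$dir))
}
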