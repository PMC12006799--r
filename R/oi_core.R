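# The Orthology Index.
#
# OI = n / m for a syntenic block, where m is the total number of syntenic
# gene pairs in the block and n is the number of those pairs pre-inferred as
# orthologs.  Orthologous blocks (tracing to a speciation) have OI near 1;
# out-paralogous blocks (tracing to a genome duplication predating the
# speciation) have OI near 0, so a single cutoff separates them.

#' Compute the Orthology Index of one block
#'
#' @param block a `synteny_block` with at least one pair.
#' @param orthology an [orthology_map()].
#' @return an `oi_annotation`: list with `block_id`, `m` (total pairs), `n`
#'   (pairs present in the orthology map) and `oi = n/m`.
#' @examples
#' b <- synteny_block("b1", "A", "B",
#'                    pairs = data.frame(gene_a = c("a1", "a2"),
#'                                       gene_b = c("b1", "b2")))
#' omap <- orthology_map("a1", "b1")
#' compute_oi(b, omap)$oi  # 0.5
#' @export
compute_oi <- function(block, orthology) {
  if (is.null(block$pairs) || nrow(block$pairs) < 1) {
    stop("cannot compute OI of an empty block (m = 0)")
  }
  m <- nrow(block$pairs)
  n <- sum(has_pair(orthology, block$pairs$gene_a, block$pairs$gene_b))
  structure(list(block_id = block$block_id, m = m, n = as.integer(n), oi = n / m),
            class = "oi_annotation")
}

#' Annotate blocks with OI, per-pair ortholog flags and median Ks
#'
#' Every block receives `oi`, `n` and a per-pair `is_ortholog` flag from the
#' orthology map.  If a `ks_map` is given, pair Ks values missing from the
#' block file are filled from it; `median_ks` is the median of the available
#' Ks values (NA when none).  The input list is not modified.
#'
#' @param blocks list of `synteny_block` objects.
#' @param orthology an [orthology_map()].
#' @param ks_map optional [read_ks_table()] result.
#' @return a new list of annotated blocks.
#' @export
annotate_blocks <- function(blocks, orthology, ks_map = NULL) {
  lapply(blocks, function(b) {
    flags <- has_pair(orthology, b$pairs$gene_a, b$pairs$gene_b)
    b$pairs$is_ortholog <- flags
    if (!is.null(ks_map)) {
      fill <- is.na(b$pairs$ks)
      if (any(fill)) {
        b$pairs$ks[fill] <- lookup_ks(ks_map, b$pairs$gene_a[fill], b$pairs$gene_b[fill])
      }
    }
    b$n <- as.integer(sum(flags))
    b$oi <- b$n / b$m
    ks <- b$pairs$ks[!is.na(b$pairs$ks)]
    b$median_ks <- if (length(ks)) stats::median(ks) else NA_real_
    b
  })
}

#' Filter blocks at an OI cutoff
#'
#' A block is retained iff `oi >= oi_cutoff` and `m >= min_pairs`: blocks
#' *below* the threshold are discarded, so a block exactly at the cutoff is
#' kept.  Input order is preserved and the input is not modified.
#'
#' @param blocks annotated blocks (see [annotate_blocks()]).
#' @param oi_cutoff retention threshold in `[0, 1]`; default 0.6.  0.5 is
#'   the documented permissive alternative.
#' @param min_pairs minimum block length in gene pairs; default 1 (no extra
#'   length filtering).
#' @return the retained blocks, in input order.
#' @export
filter_blocks <- function(blocks, oi_cutoff = 0.6, min_pairs = 1L) {
  if (!is.numeric(oi_cutoff) || length(oi_cutoff) != 1 ||
      is.na(oi_cutoff) || oi_cutoff < 0 || oi_cutoff > 1) {
    stop("oi_cutoff must be a single number in [0, 1]")
  }
  oi <- vapply(blocks, function(b) as.numeric(b$oi), 0)
  if (anyNA(oi)) stop("blocks must be annotated with annotate_blocks() before filtering")
  m <- vapply(blocks, `[[`, 0L, "m")
  blocks[oi >= oi_cutoff & m >= min_pairs]
}

#' OI distribution summary and noise statistic
#'
#' Histograms block OI values with half-open bins `[lo, hi)` (last bin
#' closed), both pair-weighted (each block contributes `m` to its bin) and
#' block-weighted.  The noise statistic is the cumulative proportion of
#' syntenic gene pairs whose block OI falls in `[0.3, 0.7)` — the dividing
#' range between the out-paralogy and orthology peaks; a block-weighted
#' variant is also reported.
#'
#' @param blocks annotated blocks (at least one).
#' @param bin_width histogram bin width on `[0, 1]`; default 0.05.
#' @return an `oi_distribution`: `bin_edges`, `pair_counts`, `block_counts`,
#'   `noise` (pair-weighted), `noise_blocks`, `total_pairs`, `total_blocks`.
#' @export
oi_distribution <- function(blocks, bin_width = 0.05) {
  if (length(blocks) < 1) stop("oi_distribution requires at least one block")
  oi <- vapply(blocks, function(b) as.numeric(b$oi), 0)
  if (anyNA(oi)) stop("blocks must be annotated with annotate_blocks() first")
  m <- vapply(blocks, `[[`, 0L, "m")
  edges <- seq(0, 1, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  nb <- length(edges) - 1L
  idx <- pmin(findInterval(oi, edges), nb)  # [lo, hi), last bin closed
  pair_counts <- vapply(seq_len(nb), function(k) sum(m[idx == k]), 0)
  block_counts <- vapply(seq_len(nb), function(k) sum(idx == k), 0)
  in_noise <- oi >= 0.3 & oi < 0.7
  structure(list(bin_edges = edges,
                 pair_counts = as.integer(pair_counts),
                 block_counts = as.integer(block_counts),
                 noise = sum(m[in_noise]) / sum(m),
                 noise_blocks = mean(in_noise),
                 total_pairs = sum(m), total_blocks = length(blocks)),
            class = "oi_distribution")
}

#' @export
print.oi_distribution <- function(x, ...) {
  cat(sprintf("<oi_distribution> %d blocks / %d pairs; noise[0.3,0.7) = %.4f (pair-weighted)\n",
              x$total_blocks, x$total_pairs, x$noise))
  invisible(x)
}

#' Extract syntenic orthologs from retained blocks
#'
#' Returns the union of *all* gene pairs of the retained (OI-filtered)
#' blocks — including pairs not pre-inferred as orthologs, which are rescued
#' as presumed orthologs by virtue of sitting inside an orthologous block.
#' A pair appearing in several retained blocks is emitted once, reported
#' with the maximum block OI over its supporting blocks (and the Ks of the
#' first block carrying a value).
#'
#' @param blocks retained blocks (already filtered).
#' @return `data.frame` with columns `gene_a`, `gene_b`, `oi`, `ks`,
#'   `is_ortholog` (the pre-inference flag), one row per distinct pair.
#' @export
extract_syntenic_orthologs <- function(blocks) {
  if (!length(blocks)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      oi = numeric(0), ks = numeric(0), is_ortholog = logical(0),
                      stringsAsFactors = FALSE))
  }
  dt <- data.table::rbindlist(lapply(blocks, function(b) {
    data.table::data.table(gene_a = pmin(b$pairs$gene_a, b$pairs$gene_b),
                           gene_b = pmax(b$pairs$gene_a, b$pairs$gene_b),
                           oi = b$oi, ks = b$pairs$ks,
                           is_ortholog = b$pairs$is_ortholog)
  }))
  gene_a <- gene_b <- oi <- ks <- is_ortholog <- NULL  # NSE notes
  out <- dt[, list(oi = max(oi), ks = ks[!is.na(ks)][1],
                   is_ortholog = any(is_ortholog %in% TRUE)),
            by = list(gene_a, gene_b)]
  data.frame(out, stringsAsFactors = FALSE)
}

#' Write a syntenic-ortholog pair list
#'
#' TSV `gene_a  gene_b  oi  ks` with fixed 4-decimal float formatting.
#'
#' @param pairs result of [extract_syntenic_orthologs()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pair_list <- function(pairs, path) {
  lines <- c("gene_a\tgene_b\toi\tks",
             if (nrow(pairs)) paste(pairs$gene_a, pairs$gene_b,
                                    fmt_num(pairs$oi), fmt_num(pairs$ks), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
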