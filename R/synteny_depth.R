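# Orthologous synteny depth and relative ploidy.
#
# Windows tile the gene-rank space of a reference genome (not base pairs),
# so intergenic length variation cannot bias depth.  A window's depth is the
# number of blocks whose reference-side gene-order interval overlaps it;
# block-level counting is robust to internal gene loss.  The modal depth of
# covered windows is the relative-ploidy estimate p: p = 1 is expected for
# one-to-one orthology, p = 2 after an unshared tetraploidy, and so on.

#' Compute a synteny-depth profile over gene-rank windows
#'
#' @param blocks syntenic blocks, each with one side in the reference
#'   genome (usually OI-filtered blocks for ploidy work).
#' @param genes gene table of the reference genome.
#' @param window_size window length in genes; default 50.  The last window
#'   of each chromosome may be short.
#' @param count `"blocks"` (default) counts overlapping blocks per window;
#'   `"pairs"` counts syntenic gene pairs whose reference gene is inside
#'   the window.
#' @return a `depth_profile`: `reference_genome`, `window_size`, `windows`
#'   (`data.frame` `chrom, window_start, window_end, depth` in gene ranks),
#'   `depth_histogram`, `modal_depth`, `covered_fraction`.
#' @export
compute_depth <- function(blocks, genes, window_size = 50L,
                          count = c("blocks", "pairs")) {
  count <- match.arg(count)
  stopifnot(window_size >= 1)
  ref <- unique(genes$genome_id)
  if (length(ref) != 1) stop("reference gene table must hold exactly one genome")
  # windows tile each chromosome's gene ranks 0..k-1
  chroms <- unique(genes$chrom)
  wins <- data.table::rbindlist(lapply(chroms, function(ch) {
    k <- sum(genes$chrom == ch)
    s <- seq(0L, k - 1L, by = window_size)
    data.table::data.table(chrom = ch, window_start = s,
                           window_end = pmin(s + window_size - 1L, k - 1L))
  }))
  wins <- data.frame(wins, stringsAsFactors = FALSE)
  depth <- integer(nrow(wins))
  for (b in blocks) {
    side <- if (identical(b$genome_a, ref)) "gene_a"
            else if (identical(b$genome_b, ref)) "gene_b"
            else stop("block ", b$block_id, " does not involve reference genome ", ref)
    r <- gene_ranks(b$pairs[[side]], genes, paste0("block ", b$block_id))
    ch <- r$chrom[1]
    if (count == "blocks") {
      lo <- min(r$rank); hi <- max(r$rank)
      hit <- wins$chrom == ch & wins$window_start <= hi & wins$window_end >= lo
      depth[hit] <- depth[hit] + 1L
    } else {
      w <- which(wins$chrom == ch)
      idx <- findInterval(r$rank, wins$window_start[w])
      tab <- tabulate(idx, nbins = length(w))
      depth[w] <- depth[w] + tab
    }
  }
  wins$depth <- depth
  hist <- table(factor(depth, levels = 0:max(c(depth, 0L))))
  structure(list(reference_genome = ref, window_size = as.integer(window_size),
                 windows = wins,
                 depth_histogram = hist,
                 modal_depth = modal_depth_of(depth),
                 covered_fraction = if (nrow(wins)) mean(depth >= 1) else 0),
            class = "depth_profile")
}

# modal depth over covered (depth >= 1) windows; ties broken toward the
# smaller depth with a warning; 0 iff no window is covered.
modal_depth_of <- function(depth) {
  d <- depth[depth >= 1]
  if (!length(d)) return(0L)
  tab <- table(d)
  best <- as.integer(names(tab)[tab == max(tab)])
  if (length(best) > 1) {
    warning("modal synteny depth is tied between {",
            paste(best, collapse = ", "), "}; using the smallest")
  }
  min(best)
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> ref=%s  %d windows of %d genes  modal depth=%d  covered=%.1f%%\n",
              x$reference_genome, nrow(x$windows), x$window_size,
              x$modal_depth, 100 * x$covered_fraction))
  invisible(x)
}

#' Estimate relative ploidy from a depth profile
#'
#' The relative ploidy p is the modal synteny depth among covered windows of
#' a profile computed from OI-filtered (orthologous) blocks.  p = 1 means
#' one-to-one orthology with the reference; p > 1 indicates one or more
#' polyploidization events since the divergence from the reference (p = 2
#' suggests tetraploidy, p = 3 hexaploidy).  p = 0 only when no window is
#' covered.
#'
#' @param profile a [compute_depth()] result.
#' @param min_covered_fraction below this fraction of covered windows a
#'   low-coverage warning is attached; default 0.5.
#' @return integer p, with attribute `low_coverage` (logical).
#' @export
estimate_relative_ploidy <- function(profile, min_covered_fraction = 0.5) {
  p <- profile$modal_depth
  low <- profile$covered_fraction < min_covered_fraction
  if (low) {
    warning(sprintf(
      "only %.1f%% of windows have synteny depth >= 1; ploidy estimate p=%d is low-confidence",
      100 * profile$covered_fraction, p))
  }
  structure(as.integer(p), low_coverage = low)
}

#' Synteny-depth ratio between two genomes
#'
#' Given depth profiles of the same block set referenced on each genome in
#' turn, returns `(p relative to A, p relative to B)`.  After OI filtering a
#' shared WGD yields 1:1 (orthology is one-to-one) whereas lineage-specific
#' WGDs yield 2:2 — the pattern that discriminates the two hypotheses.
#'
#' @param profile_ab depth profile with genome A as reference.
#' @param profile_ba depth profile with genome B as reference.
#' @return named integer vector of length 2.
#' @export
depth_ratio <- function(profile_ab, profile_ba) {
  c(p_a = as.integer(estimate_relative_ploidy(profile_ab)),
    p_b = as.integer(estimate_relative_ploidy(profile_ba)))
}

#' Write a depth profile as TSV
#'
#' Writes `chrom  window_start_gene  window_end_gene  depth`, plus a second
#' file `<path>.hist.tsv` with the depth histogram.
#'
#' @param profile a `depth_profile`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_depth_profile <- function(profile, path) {
  w <- profile$windows
  writeLines(c("chrom\twindow_start_gene\twindow_end_gene\tdepth",
               paste(w$chrom, w$window_start, w$window_end, w$depth, sep = "\t")),
             path)
  h <- profile$depth_histogram
  writeLines(c("depth\tn_windows", paste(names(h), as.integer(h), sep = "\t")),
             paste0(path, ".hist.tsv"))
  invisible(path)
}
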