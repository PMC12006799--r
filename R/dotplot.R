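# Diagnostic dot plots: homologous gene pairs on cumulative gene-rank
# coordinates, colored by block OI or pair Ks, with the matching value
# histogram and the two per-genome synteny-depth panels.

#' Assemble dot-plot data
#'
#' One point per block pair.  Coordinates are cumulative gene ranks: a
#' gene's per-chromosome `order_index` offset by the sizes of the preceding
#' chromosomes (chromosomes ordered by descending gene count unless an
#' explicit order is supplied).  In `oi` mode a pair's color value is its
#' block's OI; in `ks` mode it is the pair's Ks (missing Ks flags the point
#' as missing-color).
#'
#' @param blocks annotated blocks (see [annotate_blocks()]).
#' @param genes_x,genes_y gene tables of the two genomes (x and y axis).
#' @param color_mode `"oi"` or `"ks"`.
#' @param oi_cutoff used to flag each point as retained (block OI at or
#'   above the cutoff); default 0.6.
#' @param chrom_order_x,chrom_order_y optional explicit chromosome orders.
#' @return a `dot_data`: `points` (`x, y, color_value, retained`),
#'   `offsets_x`, `offsets_y` (named cumulative chromosome boundaries),
#'   `color_mode`, axis sizes and genome labels.
#' @export
assemble_dot_data <- function(blocks, genes_x, genes_y,
                              color_mode = c("oi", "ks"), oi_cutoff = 0.6,
                              chrom_order_x = NULL, chrom_order_y = NULL) {
  color_mode <- match.arg(color_mode)
  offs_x <- chrom_offsets(genes_x, chrom_order_x)
  offs_y <- chrom_offsets(genes_y, chrom_order_y)
  gx <- unique(genes_x$genome_id); gy <- unique(genes_y$genome_id)
  pts <- data.table::rbindlist(lapply(blocks, function(b) {
    if (identical(b$genome_a, gx)) {
      ax <- b$pairs$gene_a; ay <- b$pairs$gene_b
    } else if (identical(b$genome_b, gx)) {
      ax <- b$pairs$gene_b; ay <- b$pairs$gene_a
    } else stop("block ", b$block_id, " does not involve genome ", gx)
    rx <- gene_ranks(ax, genes_x, paste0("block ", b$block_id))
    ry <- gene_ranks(ay, genes_y, paste0("block ", b$block_id))
    data.table::data.table(
      x = offs_x[rx$chrom] + rx$rank,
      y = offs_y[ry$chrom] + ry$rank,
      color_value = if (color_mode == "oi") rep(as.numeric(b$oi), b$m)
                    else as.numeric(b$pairs$ks),
      retained = if (is.na(b$oi)) NA else b$oi >= oi_cutoff)
  }))
  structure(list(points = data.frame(pts),
                 offsets_x = offs_x, offsets_y = offs_y,
                 size_x = nrow(genes_x), size_y = nrow(genes_y),
                 genome_x = gx, genome_y = gy,
                 color_mode = color_mode),
            class = "dot_data")
}

# cumulative rank offset of each chromosome; default order = descending
# gene count, ties by chromosome name
chrom_offsets <- function(genes, chrom_order = NULL) {
  sizes <- table(genes$chrom)
  if (is.null(chrom_order)) {
    chrom_order <- names(sizes)[order(-as.integer(sizes), names(sizes))]
  }
  sizes <- as.integer(sizes[chrom_order])
  setNames(cumsum(c(0L, sizes[-length(sizes)])), chrom_order)
}

#' Render the four-panel synteny diagnostic figure
#'
#' Deterministic layout: the main dot panel, the color-value histogram, and
#' the two synteny-depth panels (one per genome).  The color map runs from
#' cool (value 0) to warm (maximum value); Ks values are clipped at
#' `ks_max` so the deep-divergence tail does not flatten the scale.
#' Points with missing color values are drawn grey.  Chromosome boundaries
#' are drawn as grid lines.  Output carries no timestamps, so rendering the
#' same input twice gives byte-identical SVG.
#'
#' @param dotdata an [assemble_dot_data()] result.
#' @param depth_x,depth_y [compute_depth()] profiles referenced on the x
#'   and y genomes (computed from the same block set).
#' @param histogram an [oi_distribution()] on the same blocks (used in
#'   `oi` mode; in `ks` mode the histogram is computed from point values).
#' @param path output file.
#' @param format `"svg"`, `"png"` or `"pdf"`.
#' @param ks_max Ks color clip; default 3.
#' @param retained_only drop non-retained points before plotting.
#' @return the path, invisibly.
#' @export
render_dotplot <- function(dotdata, depth_x = NULL, depth_y = NULL,
                           histogram = NULL, path,
                           format = c("svg", "png", "pdf"),
                           ks_max = 3, retained_only = FALSE) {
  format <- match.arg(format)
  switch(format,
         svg = svg(path, width = 9, height = 7),
         png = png(path, width = 1350, height = 1050, res = 150),
         pdf = pdf(path, width = 9, height = 7))
  on.exit(dev.off(), add = TRUE)
  layout(matrix(c(1, 2, 1, 3, 1, 4), nrow = 3, byrow = TRUE),
         widths = c(2.2, 1), heights = c(1, 1, 1))
  pal <- colorRampPalette(c("#2c7bb6", "#abd9e9", "#fdae61", "#d7191c"))(101)
  pts <- dotdata$points
  if (retained_only) pts <- pts[pts$retained %in% TRUE, , drop = FALSE]
  vmax <- if (dotdata$color_mode == "oi") 1 else ks_max
  val <- pmin(pts$color_value, vmax)
  col <- ifelse(is.na(val), "grey70", pal[pmax(1L, ceiling(100 * val / vmax))])
  par(mar = c(4, 4, 2, 1))
  plot.new()
  plot.window(xlim = c(0, dotdata$size_x), ylim = c(0, dotdata$size_y),
              xaxs = "i", yaxs = "i")
  box()
  abline(v = dotdata$offsets_x[-1], h = dotdata$offsets_y[-1],
         col = "grey80", lwd = 0.5)
  points(pts$x, pts$y, pch = ".", col = col, cex = 1.5)
  title(xlab = dotdata$genome_x, ylab = dotdata$genome_y,
        main = sprintf("homologous gene pairs (%s-colored)", dotdata$color_mode))
  par(mar = c(4, 4, 2, 1))
  if (dotdata$color_mode == "oi" && !is.null(histogram)) {
    mids <- (head(histogram$bin_edges, -1) + tail(histogram$bin_edges, -1)) / 2
    barplot(histogram$pair_counts, names.arg = fmt_axis(mids), space = 0,
            col = pal[pmax(1L, ceiling(100 * mids))], border = NA, las = 2,
            xlab = "OI", ylab = "gene pairs", main = "OI histogram",
            cex.names = 0.5)
  } else {
    v <- val[!is.na(val)]
    br <- seq(0, vmax, length.out = 21)
    cnt <- tabulate(pmin(findInterval(v, br), 20L), nbins = 20L)
    mids <- (head(br, -1) + tail(br, -1)) / 2
    barplot(cnt, names.arg = fmt_axis(mids), space = 0,
            col = pal[pmax(1L, ceiling(100 * mids / vmax))], border = NA, las = 2,
            xlab = "Ks", ylab = "gene pairs", main = "Ks histogram",
            cex.names = 0.5)
  }
  for (dp in list(depth_x, depth_y)) {
    par(mar = c(4, 4, 2, 1))
    if (is.null(dp)) { plot.new(); next }
    h <- dp$depth_histogram
    barplot(as.integer(h), names.arg = names(h), col = "grey40", border = NA,
            xlab = "synteny depth", ylab = "windows",
            main = sprintf("depth rel. %s (%d-gene windows)",
                           dp$reference_genome, dp$window_size))
  }
  invisible(path)
}

fmt_axis <- function(x) formatC(x, format = "f", digits = 2)
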