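# Syntenic blocks: the core container, plus readers for four on-disk
# dialects (canonical, MCScanX collinearity, WGDI-style block CSV, JCVI
# anchors) and the canonical writer.
#
# A block is an ordered run of cross-genome gene pairs on one chromosome
# pair.  Within-block gene order follows the file; when gene tables are
# supplied at parse time, monotonicity of the first genome's gene ranks is
# checked and violations are kept with a warning (detector outputs contain
# minor order noise and the OI does not depend on within-block order).

#' Construct a syntenic block
#'
#' @param block_id block label, unique within a collection.
#' @param genome_a,genome_b genome labels of the two sides.
#' @param chrom_a,chrom_b chromosome labels (may be `NA` when the source
#'   dialect does not encode them).
#' @param pairs `data.frame` with columns `gene_a`, `gene_b` and optionally
#'   `ks` (non-negative numeric) and `is_ortholog` (logical).
#' @param orientation `"same"` or `"inverted"`.
#' @param oi,n,median_ks annotation slots filled by [annotate_blocks()].
#' @return an object of class `synteny_block`.  `m` (the number of syntenic
#'   gene pairs) always equals `nrow(pairs)`.
#' @export
synteny_block <- function(block_id, genome_a, genome_b, chrom_a = NA_character_,
                          chrom_b = NA_character_, pairs,
                          orientation = c("same", "inverted"),
                          oi = NA_real_, n = NA_integer_, median_ks = NA_real_) {
  orientation <- match.arg(orientation)
  stopifnot(is.data.frame(pairs), all(c("gene_a", "gene_b") %in% names(pairs)))
  if (nrow(pairs) < 1) stop("a syntenic block must contain at least one gene pair")
  if (is.null(pairs$ks)) pairs$ks <- NA_real_
  if (is.null(pairs$is_ortholog)) pairs$is_ortholog <- NA
  pairs <- data.frame(gene_a = as.character(pairs$gene_a),
                      gene_b = as.character(pairs$gene_b),
                      ks = as.numeric(pairs$ks),
                      is_ortholog = as.logical(pairs$is_ortholog),
                      stringsAsFactors = FALSE)
  structure(list(block_id = as.character(block_id),
                 genome_a = genome_a, genome_b = genome_b,
                 chrom_a = chrom_a, chrom_b = chrom_b,
                 orientation = orientation,
                 pairs = pairs, m = nrow(pairs),
                 oi = oi, n = n, median_ks = median_ks),
            class = "synteny_block")
}

#' @export
print.synteny_block <- function(x, ...) {
  cat(sprintf("<synteny_block %s> %s:%s vs %s:%s  %s  m=%d  oi=%s  median_ks=%s\n",
              x$block_id, x$genome_a, x$chrom_a, x$genome_b, x$chrom_b,
              x$orientation, x$m,
              ifelse(is.na(x$oi), "NA", sprintf("%.4f", x$oi)),
              ifelse(is.na(x$median_ks), "NA", sprintf("%.4f", x$median_ks))))
  invisible(x)
}

#' Number of gene pairs in a block
#' @param block a `synteny_block`.
#' @return integer count of gene pairs (`m`).
#' @export
n_pairs <- function(block) block$m

#' Summarize a list of blocks as a data.frame
#'
#' @param blocks list of `synteny_block` objects.
#' @return one row per block with ids, genome/chromosome pair, orientation,
#'   `m`, `n`, `oi` and `median_ks`.
#' @export
blocks_summary <- function(blocks) {
  data.frame(block_id = vapply(blocks, `[[`, "", "block_id"),
             genome_a = vapply(blocks, `[[`, "", "genome_a"),
             genome_b = vapply(blocks, `[[`, "", "genome_b"),
             chrom_a = vapply(blocks, function(b) as.character(b$chrom_a), ""),
             chrom_b = vapply(blocks, function(b) as.character(b$chrom_b), ""),
             orientation = vapply(blocks, `[[`, "", "orientation"),
             m = vapply(blocks, `[[`, 0L, "m"),
             n = vapply(blocks, function(b) as.integer(b$n), 0L),
             oi = vapply(blocks, function(b) as.numeric(b$oi), 0),
             median_ks = vapply(blocks, function(b) as.numeric(b$median_ks), 0),
             stringsAsFactors = FALSE)
}

fmt_num <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 4))

#' Write syntenic blocks in the canonical dialect
#'
#' The canonical format is line-oriented and bit-stable for fixed input (no
#' timestamps; floats fixed to 4 decimals): a file header line, then per
#' block a `#block` header
#' `#block <id> <genomeA> <genomeB> <chromA> <chromB> <orientation> <n_pairs> <oi> <median_ks>`
#' followed by one `geneA<TAB>geneB<TAB>ks<TAB>is_ortholog(0/1)` line per
#' pair (`NA` for absent values).  Reading the file back with
#' [read_synteny_blocks()] round-trips to equal blocks.
#'
#' @param blocks list of `synteny_block` objects (annotated or not).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  out <- character(1 + sum(vapply(blocks, function(b) b$m + 1L, 0L)))
  out[1] <- "# canonical-blocks v1"
  k <- 1L
  for (b in blocks) {
    k <- k + 1L
    out[k] <- paste("#block", b$block_id, b$genome_a, b$genome_b,
                    ifelse(is.na(b$chrom_a), "NA", b$chrom_a),
                    ifelse(is.na(b$chrom_b), "NA", b$chrom_b),
                    b$orientation, b$m, fmt_num(b$oi), fmt_num(b$median_ks))
    p <- b$pairs
    io <- ifelse(is.na(p$is_ortholog), "NA", ifelse(p$is_ortholog, "1", "0"))
    out[k + seq_len(b$m)] <- paste(p$gene_a, p$gene_b, fmt_num(p$ks), io, sep = "\t")
    k <- k + b$m
  }
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write blocks to ", path)
  invisible(path)
}

#' Read syntenic blocks
#'
#' Parses syntenic blocks from one of four dialects:
#' \describe{
#'   \item{`canonical`}{this package's own format, see [write_blocks()].}
#'   \item{`mcscanx`}{MCScanX collinearity files: `## Alignment` headers
#'     (`score=`, `e_value=`, `N=`, `chrA&chrB`, `plus|minus`) followed by
#'     tab-separated pair lines.}
#'   \item{`wgdi`}{a WGDI-style block table: CSV with header
#'     `id,chr1,chr2,block1,block2,ks` where `block1`/`block2` are
#'     `;`-separated gene-id lists and `ks` a `;`-separated value list.}
#'   \item{`anchors`}{JCVI anchors: blocks separated by `###` lines, 2-3
#'     tab-separated columns per pair.  A file with no separators is one
#'     block.}
#' }
#' Pair order is preserved from the file.  When gene tables are supplied the
#' chromosome pair is resolved for dialects that do not encode it and
#' within-block monotonicity of gene order is checked: a violating block is
#' retained with a warning, its orientation inferred from the majority
#' direction.
#'
#' @param path input file.
#' @param dialect one of `"canonical"`, `"mcscanx"`, `"wgdi"`, `"anchors"`.
#' @param genome_ids length-2 character, labels of the two genomes in the
#'   order of the file's columns (dialects other than canonical do not
#'   record genome labels).
#' @param genes_a,genes_b optional gene tables for the two genomes.
#' @return list of `synteny_block` objects.
#' @export
read_synteny_blocks <- function(path,
                                dialect = c("canonical", "mcscanx", "wgdi", "anchors"),
                                genome_ids = c("A", "B"),
                                genes_a = NULL, genes_b = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("block file not found: ", path)
  raw <- switch(dialect,
                canonical = parse_blocks_canonical(path),
                mcscanx = parse_blocks_mcscanx(path),
                wgdi = parse_blocks_wgdi(path),
                anchors = parse_blocks_anchors(path))
  blocks <- lapply(raw, function(r) {
    ga <- r$genome_a %||% genome_ids[1]
    gb <- r$genome_b %||% genome_ids[2]
    b <- synteny_block(r$block_id, ga, gb,
                       chrom_a = r$chrom_a %||% NA_character_,
                       chrom_b = r$chrom_b %||% NA_character_,
                       pairs = r$pairs,
                       orientation = r$orientation %||% "same",
                       oi = r$oi %||% NA_real_, n = r$n %||% NA_integer_,
                       median_ks = r$median_ks %||% NA_real_)
    finalize_block(b, genes_a, genes_b, orientation_known = !is.null(r$orientation))
  })
  blocks
}

# Resolve chromosomes from gene tables when absent, check monotonicity,
# infer orientation from the majority pair direction when unknown.
finalize_block <- function(b, genes_a, genes_b, orientation_known) {
  if (is.null(genes_a) || is.null(genes_b)) return(b)
  ra <- gene_ranks(b$pairs$gene_a, genes_a, paste0("block ", b$block_id))
  rb <- gene_ranks(b$pairs$gene_b, genes_b, paste0("block ", b$block_id))
  if (is.na(b$chrom_a)) b$chrom_a <- ra$chrom[1]
  if (is.na(b$chrom_b)) b$chrom_b <- rb$chrom[1]
  if (b$m >= 2) {
    dx <- diff(ra$rank)
    dy <- diff(rb$rank)
    if (all(dx < 0)) { # file stored the block right-to-left; re-anchor on genome A
      b$pairs <- b$pairs[rev(seq_len(b$m)), , drop = FALSE]
      rownames(b$pairs) <- NULL
      dx <- -rev(dx); dy <- -rev(dy)
    }
    up <- sum(dy > 0) >= sum(dy < 0)
    if (!orientation_known) b$orientation <- if (up) "same" else "inverted"
    mono_x <- all(dx > 0)
    mono_y <- if (b$orientation == "same") all(dy > 0) else all(dy < 0)
    if (!mono_x || !mono_y) {
      b$orientation <- if (up) "same" else "inverted"
      warning("block ", b$block_id,
              " violates gene-order monotonicity; retained with orientation '",
              b$orientation, "'")
    }
  }
  b
}

parse_blocks_canonical <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#block ", lines)
  blocks <- vector("list", length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  num_or_na <- function(x) suppressWarnings(as.numeric(ifelse(x == "NA", NA, x)))
  for (i in seq_along(hdr)) {
    f <- strsplit(sub("^#block ", "", lines[hdr[i]]), " ", fixed = TRUE)[[1]]
    if (length(f) < 7) stop("malformed #block header at line ", hdr[i])
    body <- lines[seq(hdr[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[!startsWith(body, "#")]
    pf <- strsplit(body, "\t", fixed = TRUE)
    pairs <- data.frame(
      gene_a = vapply(pf, `[`, "", 1),
      gene_b = vapply(pf, `[`, "", 2),
      ks = num_or_na(vapply(pf, function(x) if (length(x) >= 3) x[3] else "NA", "")),
      is_ortholog = as.logical(num_or_na(
        vapply(pf, function(x) if (length(x) >= 4) x[4] else "NA", ""))),
      stringsAsFactors = FALSE)
    blocks[[i]] <- list(block_id = f[1], genome_a = f[2], genome_b = f[3],
                        chrom_a = if (f[4] == "NA") NA_character_ else f[4],
                        chrom_b = if (f[5] == "NA") NA_character_ else f[5],
                        orientation = f[6], pairs = pairs,
                        oi = if (length(f) >= 8) num_or_na(f[8]) else NA_real_,
                        median_ks = if (length(f) >= 9) num_or_na(f[9]) else NA_real_)
  }
  blocks
}

parse_blocks_mcscanx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^## Alignment", lines)
  if (!length(hdr)) stop("no '## Alignment' headers found in mcscanx file ", path)
  bounds <- c(hdr, length(lines) + 1L)
  blocks <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    h <- lines[hdr[i]]
    id <- sub("^## Alignment ([^:]+):.*$", "\\1", h)
    chroms <- regmatches(h, regexpr("[^ =]+&[^ =]+", h))
    cc <- if (length(chroms)) strsplit(chroms, "&", fixed = TRUE)[[1]] else c(NA, NA)
    orient <- if (grepl("minus", h)) "inverted" else "same"
    body <- lines[seq(hdr[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[nzchar(body) & !startsWith(body, "#")]
    pf <- strsplit(body, "\t", fixed = TRUE)
    pairs <- data.frame(gene_a = vapply(pf, `[`, "", 2),
                        gene_b = vapply(pf, `[`, "", 3),
                        stringsAsFactors = FALSE)
    blocks[[i]] <- list(block_id = id, chrom_a = cc[1], chrom_b = cc[2],
                        orientation = orient, pairs = pairs)
  }
  blocks
}

parse_blocks_wgdi <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "chr1", "chr2", "block1", "block2")
  if (!all(need %in% names(df))) {
    stop("wgdi block table must have columns ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    ga <- strsplit(df$block1[i], ";", fixed = TRUE)[[1]]
    gb <- strsplit(df$block2[i], ";", fixed = TRUE)[[1]]
    if (length(ga) != length(gb)) {
      stop("wgdi block ", df$id[i], ": block1 and block2 lengths differ")
    }
    ks <- rep(NA_real_, length(ga))
    if (!is.null(df$ks) && nzchar(df$ks[i])) {
      kv <- strsplit(df$ks[i], ";", fixed = TRUE)[[1]]
      ks <- suppressWarnings(as.numeric(ifelse(kv == "NA", NA, kv)))
    }
    list(block_id = df$id[i], chrom_a = df$chr1[i], chrom_b = df$chr2[i],
         pairs = data.frame(gene_a = ga, gene_b = gb, ks = ks,
                            stringsAsFactors = FALSE))
  })
}

parse_blocks_anchors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  grp <- cumsum(startsWith(lines, "###"))
  keep <- !startsWith(lines, "#")
  if (!any(keep)) return(list())
  grp <- grp[keep]; lines <- lines[keep]
  out <- list()
  for (g in unique(grp)) {
    body <- lines[grp == g]
    pf <- strsplit(body, "\t", fixed = TRUE)
    short <- which(vapply(pf, length, 0L) < 2)
    if (length(short)) stop("anchors file: pair line with fewer than 2 columns")
    pairs <- data.frame(gene_a = vapply(pf, `[`, "", 1),
                        gene_b = vapply(pf, `[`, "", 2),
                        stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- list(block_id = paste0("block", length(out) + 1L),
                                    pairs = pairs)
  }
  out
}
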