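# Gene-position tables.
#
# Columns: genome_id, chrom, start, end, strand, gene_id, order_index.
# Coordinates are 1-based inclusive; order_index is the 0-based rank of the
# gene along its chromosome by start coordinate, with ties broken by gene_id
# so the ranking is deterministic.

GENE_TABLE_COLS <- c("genome_id", "chrom", "start", "end", "strand",
                     "gene_id", "order_index")

empty_gene_table <- function(genome_id = character(0)) {
  data.frame(genome_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             gene_id = character(0), order_index = integer(0),
             stringsAsFactors = FALSE)
}

normalize_strand <- function(s) {
  s <- as.character(s)
  s[is.na(s) | !(s %in% c("+", "-"))] <- "unknown"
  s
}

# Recompute order_index: per chromosome, 0-based rank by start coordinate,
# equal starts broken by gene_id lexicographic order (C collation).
assign_order_index <- function(df) {
  if (nrow(df) == 0) {
    df$order_index <- integer(0)
    return(df)
  }
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  df$order_index <- NA_integer_
  for (ch in unique(df$chrom)) {
    idx <- which(df$chrom == ch)
    ord <- idx[order(df$start[idx], df$gene_id[idx])]
    df$order_index[ord] <- seq_along(ord) - 1L
  }
  df <- df[order(df$chrom, df$order_index), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a gene-position table
#'
#' Reads a TSV of gene positions (`chrom  start  end  gene_id  [strand]`,
#' with or without a header line) and returns a gene table with a
#' deterministic 0-based `order_index` per chromosome: genes are ranked by
#' start coordinate, ties broken by `gene_id`.  Coordinates are interpreted
#' as 1-based inclusive.
#'
#' @param path path to the TSV file.
#' @param genome_id label attached to every record; gene ids must be unique
#'   within one genome.
#' @return a `data.frame` with columns `genome_id, chrom, start, end, strand,
#'   gene_id, order_index`, sorted by chromosome and order index.
#' @examples
#' tf <- tempfile()
#' writeLines(c("chr1\t100\t900\tg2\t+", "chr1\t50\t500\tg1\t-"), tf)
#' read_gene_table(tf, "A")
#' @export
read_gene_table <- function(path, genome_id) {
  stopifnot(is.character(path), length(path) == 1L,
            is.character(genome_id), length(genome_id) == 1L)
  if (!file.exists(path)) stop("gene table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_gene_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  offset <- 0L
  if (is.na(suppressWarnings(as.numeric(fields[[1]][2])))) {
    # header line
    fields <- fields[-1]
    offset <- 1L
    if (length(fields) == 0) return(empty_gene_table())
  }
  n <- length(fields)
  get <- function(k) vapply(fields, function(f) if (length(f) >= k) f[k] else NA_character_,
                            character(1))
  chrom <- get(1); start_c <- get(2); end_c <- get(3); gid <- get(4); strand <- get(5)
  if (anyNA(gid)) {
    stop("gene table line ", which(is.na(gid))[1] + offset,
         ": expected at least 4 tab-separated columns")
  }
  start <- suppressWarnings(as.numeric(start_c))
  end <- suppressWarnings(as.numeric(end_c))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("gene table line ", bad[1] + offset, ": non-numeric coordinate (",
         start_c[bad[1]], ", ", end_c[bad[1]], ")")
  }
  if (any(start > end)) {
    i <- which(start > end)[1]
    stop("gene table line ", i + offset, ": start > end for gene ", gid[i])
  }
  dup <- gid[duplicated(gid)]
  if (length(dup)) stop("duplicate gene_id in genome ", genome_id, ": ", dup[1])
  df <- data.frame(genome_id = genome_id, chrom = chrom,
                   start = as.integer(start), end = as.integer(end),
                   strand = normalize_strand(strand), gene_id = gid,
                   stringsAsFactors = FALSE)
  assign_order_index(df)
}

#' Write a gene-position table
#'
#' Writes the TSV format consumed by [read_gene_table()] (header line plus
#' `chrom start end gene_id strand` columns).
#'
#' @param genes a gene table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  lines <- c("chrom\tstart\tend\tgene_id\tstrand",
             if (nrow(genes)) paste(genes$chrom, genes$start, genes$end,
                                    genes$gene_id, genes$strand, sep = "\t"))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write gene table to ", path)
  invisible(path)
}

# rank lookup used by depth / dot-plot / chaining code; hard error on
# unknown genes, naming the first offender.
gene_ranks <- function(gene_ids, genes, what = "gene") {
  i <- match(gene_ids, genes$gene_id)
  if (anyNA(i)) {
    stop(what, " references unknown gene: ", gene_ids[which(is.na(i))[1]],
         " (not in gene table of ", genes$genome_id[1] %||% "?", ")")
  }
  list(chrom = genes$chrom[i], rank = genes$order_index[i])
}
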