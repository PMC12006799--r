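# Ortholog-pair maps and Ks tables.
#
# An orthology map is the set of cross-genome gene pairs pre-inferred as
# orthologs by an external tool (OrthoFinder-style or plain pair lists).
# Membership is symmetric and duplicate/flipped pairs collapse to one entry.

#' Construct an orthology map from gene-id pair vectors
#'
#' @param gene_a,gene_b character vectors of equal length; pair identity is
#'   orientation-free, so `(a,b)` and `(b,a)` are the same pair.
#' @param source free-text provenance label.
#' @return an object of class `orthology_map`.
#' @export
orthology_map <- function(gene_a, gene_b, source = "pairs") {
  stopifnot(length(gene_a) == length(gene_b))
  gene_a <- as.character(gene_a); gene_b <- as.character(gene_b)
  if (any(gene_a == gene_b)) {
    i <- which(gene_a == gene_b)[1]
    stop("self-pair in orthology input: ", gene_a[i])
  }
  structure(list(keys = unique(pair_key(gene_a, gene_b)), source = source),
            class = "orthology_map")
}

#' @export
print.orthology_map <- function(x, ...) {
  cat(sprintf("<orthology_map> %d pairs (source: %s)\n", length(x$keys), x$source))
  invisible(x)
}

#' Number of pairs in an orthology map
#' @param map an `orthology_map`.
#' @return integer.
#' @export
n_ortholog_pairs <- function(map) length(map$keys)

#' Symmetric membership query
#'
#' @param map an `orthology_map`.
#' @param gene_a,gene_b equal-length character vectors.
#' @return logical vector; `has_pair(map, a, b)` equals `has_pair(map, b, a)`.
#' @export
has_pair <- function(map, gene_a, gene_b) {
  pair_key(gene_a, gene_b) %chin% map$keys
}

#' Read ortholog pairs
#'
#' Two dialects are supported: `pairs` is a headerless two-column TSV of
#' gene ids; `orthofinder` is the per-row many-to-many layout of
#' OrthoFinder's Orthologues files (header line, then an orthogroup column
#' followed by two comma-separated gene-id list columns).  Many-to-many rows
#' are expanded to the Cartesian product of the two lists; duplicates and
#' flipped orientations collapse.
#'
#' @param path input file.
#' @param dialect `"pairs"` or `"orthofinder"`.
#' @return an `orthology_map`.
#' @export
read_ortholog_pairs <- function(path, dialect = c("pairs", "orthofinder")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("ortholog file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (dialect == "pairs") {
    if (!length(lines)) return(orthology_map(character(0), character(0), "pairs"))
    f <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(vapply(f, length, 0L) < 2)
    if (length(short)) {
      stop("ortholog pairs file line ", short[1], ": expected two columns")
    }
    orthology_map(vapply(f, `[`, "", 1), vapply(f, `[`, "", 2), "pairs")
  } else {
    if (length(lines) <= 1) return(orthology_map(character(0), character(0), "orthofinder"))
    f <- strsplit(lines[-1], "\t", fixed = TRUE)  # drop header line
    short <- which(vapply(f, length, 0L) < 3)
    if (length(short)) {
      stop("orthofinder file line ", short[1] + 1L, ": expected >= 3 columns")
    }
    ga <- gb <- vector("list", length(f))
    for (i in seq_along(f)) {
      la <- strsplit(f[[i]][2], ",[ ]*")[[1]]
      lb <- strsplit(f[[i]][3], ",[ ]*")[[1]]
      ga[[i]] <- rep(la, each = length(lb))
      gb[[i]] <- rep(lb, times = length(la))
    }
    orthology_map(unlist(ga), unlist(gb), "orthofinder")
  }
}

#' Read a per-pair Ks table
#'
#' Expects a TSV with two gene-id columns followed by one or more numeric
#' columns (WGDI `-ks` layout); by default the last numeric column is used.
#' Literal `NA`/empty Ks fields are treated as missing and the row is
#' skipped; any other non-numeric value, or a negative value, is a hard
#' error with the line number.  Lookup is symmetric.
#'
#' @param path input file.
#' @param ks_column optional column name or index of the Ks column.
#' @return an object of class `ks_map`.
#' @export
read_ks_table <- function(path, ks_column = NULL) {
  if (!file.exists(path)) stop("Ks table not found: ", path)
  df <- data.table::fread(path, header = "auto", sep = "\t",
                          colClasses = "character", data.table = FALSE)
  if (nrow(df) == 0) {
    return(structure(list(keys = character(0), ks = numeric(0)), class = "ks_map"))
  }
  if (ncol(df) < 3) stop("Ks table must have two gene-id columns and >= 1 Ks column")
  has_header <- !identical(names(df), paste0("V", seq_len(ncol(df))))
  offset <- if (has_header) 1L else 0L
  if (is.null(ks_column)) {
    numericish <- vapply(df[, -(1:2), drop = FALSE], function(col) {
      col <- col[!(col %in% c("NA", ""))]
      length(col) == 0 || !anyNA(suppressWarnings(as.numeric(col)))
    }, TRUE)
    # default: the last numeric column; if none parses cleanly, take the
    # last column so the per-value check can report the offending line
    ks_column <- if (any(numericish)) names(df)[-(1:2)][max(which(numericish))]
                 else names(df)[ncol(df)]
  }
  col <- if (is.numeric(ks_column)) df[[ks_column]] else df[[as.character(ks_column)]]
  if (is.null(col)) stop("Ks column not found: ", ks_column)
  missing <- col %in% c("NA", "")
  ks <- suppressWarnings(as.numeric(col))
  bad <- which(!missing & is.na(ks))
  if (length(bad)) {
    stop("Ks table line ", bad[1] + offset, ": non-numeric Ks value '", col[bad[1]], "'")
  }
  neg <- which(!missing & ks < 0)
  if (length(neg)) {
    stop("Ks table line ", neg[1] + offset, ": negative Ks value ", ks[neg[1]])
  }
  keep <- !missing
  keys <- pair_key(df[[1]][keep], df[[2]][keep])
  first <- !duplicated(keys)
  structure(list(keys = keys[first], ks = ks[keep][first]), class = "ks_map")
}

#' @export
print.ks_map <- function(x, ...) {
  cat(sprintf("<ks_map> %d pairs\n", length(x$keys)))
  invisible(x)
}

#' Symmetric Ks lookup
#'
#' @param map a `ks_map`.
#' @param gene_a,gene_b equal-length character vectors.
#' @return numeric vector; `NA` for absent pairs (never zero).
#' @export
lookup_ks <- function(map, gene_a, gene_b) {
  map$ks[data.table::chmatch(pair_key(gene_a, gene_b), map$keys)]
}
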