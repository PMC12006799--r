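# Syntenic orthogroups (SOGs): cluster post-processing, taxon-occupancy
# filtering, outgroup attachment and per-SOG sequence export.

#' Build SOGs from an MCL partition
#'
#' One SOG per cluster spanning at least two genomes; single-genome
#' clusters are excluded (their count is reported in the `singletons`
#' attribute).  A SOG is `single_copy` iff every represented genome holds
#' exactly one member; taxon occupancy is the fraction of the genome
#' roster represented.  SOG ids are assigned deterministically by the
#' sorted member gene ids.
#'
#' @param partition an [mcl()] result.
#' @param genomes the full genome roster; defaults to the genomes present
#'   in the partition.
#' @return a list of `sog` objects (`sog_id`, `members` as a
#'   genome -> gene-id list, `copy_profile`, `class`, `taxon_occupancy`),
#'   with attribute `singletons`.
#' @export
make_sogs <- function(partition, genomes = NULL) {
  nodes <- partition$nodes
  genome_of <- setNames(nodes$genome_id, nodes$gene_id)
  if (is.null(genomes)) genomes <- sort(unique(nodes$genome_id))
  clusters <- split(names(partition$membership), partition$membership)
  clusters <- lapply(clusters, sort)
  # deterministic order: by sorted member ids (i.e. by smallest member)
  clusters <- clusters[order(vapply(clusters, `[`, "", 1))]
  singletons <- 0L
  sogs <- list()
  for (cl in clusters) {
    gg <- genome_of[cl]
    if (length(unique(gg)) < 2) { singletons <- singletons + 1L; next }
    members <- split(unname(cl), gg)
    profile <- vapply(members, length, 0L)
    sogs[[length(sogs) + 1L]] <- structure(
      list(sog_id = sprintf("SOG%05d", length(sogs) + 1L),
           members = members,
           copy_profile = profile,
           class = if (all(profile == 1L)) "single_copy" else "multi_copy",
           taxon_occupancy = length(members) / length(genomes)),
      class = "sog")
  }
  attr(sogs, "singletons") <- singletons
  sogs
}

#' @export
print.sog <- function(x, ...) {
  cat(sprintf("<sog %s> %s, %d genes over %d genomes (occupancy %.2f)\n",
              x$sog_id, x$class, sum(x$copy_profile), length(x$members),
              x$taxon_occupancy))
  invisible(x)
}

#' Filter SOGs by missing-taxon fraction and copy class
#'
#' Retains SOGs with `(1 - taxon_occupancy) <= max_missing` (the boundary
#' is kept) whose class matches `mode`.  The retained counts per class are
#' attached as attribute `counts`.
#'
#' @param sogs list of `sog` objects.
#' @param max_missing maximum tolerated fraction of missing taxa in
#'   `[0, 1)`; default 0.4.
#' @param mode `"both"` (default), `"single"` or `"multi"`.
#' @return the retained subset, in input order.
#' @export
filter_sogs <- function(sogs, max_missing = 0.4, mode = c("both", "single", "multi")) {
  mode <- match.arg(mode)
  if (!is.numeric(max_missing) || length(max_missing) != 1 ||
      is.na(max_missing) || max_missing < 0 || max_missing >= 1) {
    stop("max_missing must be a single number in [0, 1)")
  }
  occ <- vapply(sogs, `[[`, 0, "taxon_occupancy")
  cls <- vapply(sogs, `[[`, "", "class")
  keep <- (1 - occ) <= max_missing &
    switch(mode, both = TRUE, single = cls == "single_copy", multi = cls == "multi_copy")
  out <- sogs[keep]
  attr(out, "counts") <- c(single_copy = sum(cls[keep] == "single_copy"),
                           multi_copy = sum(cls[keep] == "multi_copy"))
  out
}

#' Attach outgroup genes to SOGs
#'
#' Outgroups lacking the WGDs shared by the ingroup are clustered after the
#' ingroup: each outgroup gene is attached to the SOG holding its
#' syntenic-ortholog partner(s).  When its partners span several SOGs the
#' gene goes to the SOG with the most supporting pairs, ties broken by the
#' highest summed block OI, then by lexicographic `sog_id`.  Outgroup
#' membership never alters the single/multi classification or occupancy of
#' the ingroup SOGs.
#'
#' @param sogs ingroup SOGs from [make_sogs()].
#' @param outgroup_blocks OI-filtered, annotated blocks between outgroup
#'   and ingroup genomes.
#' @return the augmented SOGs, with attribute `unattached` listing
#'   outgroup genes whose partners belong to no SOG.
#' @export
attach_outgroup <- function(sogs, outgroup_blocks) {
  blocks <- flatten_blocks(outgroup_blocks)
  ingroup <- unique(unlist(lapply(sogs, function(s) names(s$members))))
  sog_of <- new.env(parent = emptyenv())
  for (i in seq_along(sogs)) {
    for (g in unlist(sogs[[i]]$members)) assign(g, i, envir = sog_of)
  }
  links <- data.table::rbindlist(lapply(blocks, function(b) {
    a_in <- b$genome_a %in% ingroup
    b_in <- b$genome_b %in% ingroup
    if (a_in && b_in) {
      stop("block ", b$block_id, " joins two ingroup genomes (", b$genome_a,
           ", ", b$genome_b, "); outgroup genome already in sogs?")
    }
    if (!a_in && !b_in) {
      stop("block ", b$block_id, " involves no ingroup genome")
    }
    data.table::data.table(
      og_gene = if (a_in) b$pairs$gene_b else b$pairs$gene_a,
      og_genome = if (a_in) b$genome_b else b$genome_a,
      in_gene = if (a_in) b$pairs$gene_a else b$pairs$gene_b,
      w = as.numeric(b$oi))
  }))
  unattached <- character(0)
  if (nrow(links)) {
    links$sog <- vapply(links$in_gene, function(g) {
      if (exists(g, envir = sog_of, inherits = FALSE)) get(g, envir = sog_of) else NA_integer_
    }, 0L)
    og_gene <- og_genome <- w <- sog <- NULL
    for (gene in sort(unique(links$og_gene))) {
      sub <- links[links$og_gene == gene & !is.na(links$sog), ]
      if (!nrow(sub)) { unattached <- c(unattached, gene); next }
      tal <- sub[, list(n = .N, sw = sum(w)), by = list(sog, og_genome)]
      tal$sog_id <- vapply(tal$sog, function(i) sogs[[i]]$sog_id, "")
      data.table::setorder(tal, -n, -sw, sog_id)
      i <- tal$sog[1]; gname <- tal$og_genome[1]
      sogs[[i]]$members[[gname]] <- sort(c(sogs[[i]]$members[[gname]], gene))
    }
  }
  attr(sogs, "unattached") <- unattached
  sogs
}

#' Read a SOG table
#'
#' @param path TSV `sog_id  genome_id  gene_id` written by [write_sogs()].
#' @return list of `sog` objects (occupancy relative to the genomes present
#'   in the file).
#' @export
read_sogs <- function(path) {
  df <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = "character", data.table = FALSE)
  genomes <- sort(unique(df$genome_id))
  sogs <- list()
  for (id in sort(unique(df$sog_id))) {
    sub <- df[df$sog_id == id, , drop = FALSE]
    members <- split(sub$gene_id, sub$genome_id)
    members <- lapply(members, sort)
    profile <- vapply(members, length, 0L)
    sogs[[length(sogs) + 1L]] <- structure(
      list(sog_id = id, members = members, copy_profile = profile,
           class = if (all(profile == 1L)) "single_copy" else "multi_copy",
           taxon_occupancy = length(members) / length(genomes)),
      class = "sog")
  }
  sogs
}

#' Write a SOG table
#'
#' TSV `sog_id  genome_id  gene_id`, one row per member gene, sorted for
#' bit-stable output.
#'
#' @param sogs list of `sog` objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sogs <- function(sogs, path) {
  rows <- character(0)
  for (s in sogs) {
    for (g in sort(names(s$members))) {
      rows <- c(rows, paste(s$sog_id, g, sort(s$members[[g]]), sep = "\t"))
    }
  }
  ok <- tryCatch({ writeLines(c("sog_id\tgenome_id\tgene_id", rows), path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write SOG table to ", path)
  invisible(path)
}

#' Export per-SOG sequence bundles
#'
#' Writes one FASTA per SOG with records named `genome_id|gene_id`.
#' Missing sequences are reported in the returned data.frame (and in
#' `missing_sequences.txt` inside `dir`), never fatal.
#'
#' @param sogs list of `sog` objects.
#' @param sequences named character vector mapping `gene_id` to sequence.
#' @param dir output directory, created if needed.
#' @return invisibly, a data.frame `sog_id, n_written, n_missing`.
#' @export
export_sog_sequences <- function(sogs, sequences, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  report <- data.frame(sog_id = character(0), n_written = integer(0),
                       n_missing = integer(0), stringsAsFactors = FALSE)
  missing_lines <- character(0)
  for (s in sogs) {
    rec <- character(0)
    n_miss <- 0L
    for (g in sort(names(s$members))) {
      for (gene in s$members[[g]]) {
        seq <- if (gene %in% names(sequences)) sequences[[gene]] else NA_character_
        if (is.null(seq) || is.na(seq)) {
          n_miss <- n_miss + 1L
          missing_lines <- c(missing_lines, paste(s$sog_id, g, gene, sep = "\t"))
        } else {
          rec <- c(rec, paste0(">", g, "|", gene),
                   gsub(sprintf("(.{%d})", 60L), "\\1\n", seq, perl = TRUE))
        }
      }
    }
    if (length(rec)) {
      writeLines(sub("\n$", "", rec), file.path(dir, paste0(s$sog_id, ".fasta")))
    }
    report <- rbind(report, data.frame(sog_id = s$sog_id,
                                       n_written = as.integer(length(rec) / 2L),
                                       n_missing = n_miss,
                                       stringsAsFactors = FALSE))
  }
  if (length(missing_lines)) {
    writeLines(c("sog_id\tgenome_id\tgene_id", missing_lines),
               file.path(dir, "missing_sequences.txt"))
  }
  invisible(report)
}
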