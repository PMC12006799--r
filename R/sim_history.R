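# Shared-WGD gene-order simulator.
#
# Simulates the five-taxon pseudo-species design used for benchmarking:
# an ancestor of n genes evolves along the tree
#   (((A1:t, B1:t):dT, (A2:t, B2:t):dT):t0, O:dT+2t):root
# where the inner duplication node is a whole-genome duplication (WGD) in
# the "shared" scenario (subgenomes A1/A2 and B1/B2 treated as
# pseudo-species), and dT is the time lag, in substitutions per site,
# between the WGD and the A/B speciation.  In the "specific" scenario the
# order of the two inner nodes is swapped: speciation first, then one
# independent WGD per lineage.  Along each branch, Poisson-distributed
# event counts (rate x fold x branch length x genome size) of gene loss,
# inversion, transposition, tandem duplication and origination are applied
# in randomized order; gene identity is tracked through every event so
# truth labels are exact.
#
# Sequences are never evolved: the Ks analog of a pair is its expected
# divergence (total path length between the two tips) times multiplicative
# gamma noise (shape 4, mean 1).

#' Simulation configuration
#'
#' @param n_genes ancestral gene count (benchmark default 500; the original
#'   full-scale design uses 5000).
#' @param n_chromosomes ancestral chromosome count; default 5.
#' @param delta_t time lag between WGD and speciation, substitutions/site.
#' @param post_speciation_t terminal branch length; default 0.2.
#' @param pre_t stem branch above the first inner node; default 0.2.
#' @param fold multiplier on all rearrangement rates (1, 10, 100, 1000 in
#'   the benchmark grid).
#' @param rates per-gene per-(substitution/site) base event rates, a named
#'   vector with entries `loss`, `inversion`, `transposition`,
#'   `duplication`, `origination`.
#' @param segment_mean mean length (genes) of inverted/transposed
#'   segments, geometric-distributed; default 5.
#' @param scenario `"shared"` (WGD before speciation) or `"specific"`
#'   (speciation before two independent WGDs).
#' @param include_outgroup simulate the outgroup O; default TRUE.
#' @param ks_noise_shape gamma shape of the multiplicative Ks noise;
#'   default 4.
#' @param fp_rate,fn_rate optional overrides of the orthology-call error
#'   model (single probabilities or functions of delta_t); see
#'   [emulate_orthology_calls()].
#' @param seed optional seed applied by [simulate_history()].
#' @return a `sim_config`.
#' @export
sim_config <- function(n_genes = 500L, n_chromosomes = 5L, delta_t = 0.2,
                       post_speciation_t = 0.2, pre_t = 0.2, fold = 1,
                       rates = c(loss = 1e-4, inversion = 3e-4,
                                 transposition = 3e-4, duplication = 2e-5,
                                 origination = 2e-5),
                       segment_mean = 5, scenario = c("shared", "specific"),
                       include_outgroup = TRUE, ks_noise_shape = 4,
                       fp_rate = NULL, fn_rate = NULL, seed = NULL) {
  scenario <- match.arg(scenario)
  need <- c("loss", "inversion", "transposition", "duplication", "origination")
  if (!all(need %in% names(rates))) {
    stop("rates must be named with: ", paste(need, collapse = ", "))
  }
  if (any(rates < 0)) stop("event rates must be >= 0")
  if (!is.numeric(delta_t) || delta_t <= 0) stop("delta_t must be > 0")
  if (fold < 1) stop("fold must be >= 1")
  tip_path <- pre_t + delta_t + post_speciation_t
  expected_survivors <- n_genes * exp(-rates[["loss"]] * fold * tip_path)
  if (expected_survivors < 10) {
    stop("loss rate x fold x branch length leaves < 10 expected surviving genes; ",
         "use a smaller fold or loss rate")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_chromosomes = as.integer(n_chromosomes),
                 delta_t = delta_t, post_speciation_t = post_speciation_t,
                 pre_t = pre_t, fold = fold, rates = rates,
                 segment_mean = segment_mean, scenario = scenario,
                 include_outgroup = include_outgroup,
                 ks_noise_shape = ks_noise_shape,
                 fp_rate = fp_rate, fn_rate = fn_rate, seed = seed),
            class = "sim_config")
}

# --- internal genome representation --------------------------------------
# data.frame rows in chromosomal order, grouped by the integer `chrom`
# column: gid (globally unique lineage id), fam (ancestral family id),
# anc (gene id at the speciation node, NA before it), strand, orig
# (originated after the root ancestor).

new_ancestor <- function(cfg, counter) {
  n <- cfg$n_genes
  sizes <- diff(round(seq(0, n, length.out = cfg$n_chromosomes + 1L)))
  data.frame(chrom = rep(seq_len(cfg$n_chromosomes), sizes),
             gid = seq_len(n), fam = seq_len(n), anc = NA_character_,
             strand = "+", orig = FALSE, stringsAsFactors = FALSE)
}

next_gid <- function(counter, k = 1L) {
  v <- counter$gid + seq_len(k)
  counter$gid <- counter$gid + k
  v
}

seg_len <- function(mean_len) 1L + stats::rgeom(1L, 1 / mean_len)

evolve_branch <- function(g, len, cfg, counter) {
  rates <- cfg$rates * cfg$fold
  types <- names(rates)
  counts <- stats::rpois(length(rates), rates * len * nrow(g))
  events <- sample(rep(types, counts))
  for (ev in events) {
    if (nrow(g) < 2 && ev != "origination") next
    g <- switch(ev,
                loss = g[-sample.int(nrow(g), 1L), , drop = FALSE],
                inversion = op_inversion(g, cfg$segment_mean),
                transposition = op_transposition(g, cfg$segment_mean),
                duplication = op_duplication(g, counter),
                origination = op_origination(g, counter))
  }
  rownames(g) <- NULL
  g
}

op_inversion <- function(g, mean_len) {
  i <- sample.int(nrow(g), 1L)
  ch <- g$chrom[i]
  hi <- max(which(g$chrom == ch))
  j <- min(i + seg_len(mean_len) - 1L, hi)
  seg <- g[i:j, , drop = FALSE]
  seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
  seg$strand <- ifelse(seg$strand == "+", "-", "+")
  g[i:j, ] <- seg
  g
}

op_transposition <- function(g, mean_len) {
  i <- sample.int(nrow(g), 1L)
  ch <- g$chrom[i]
  hi <- max(which(g$chrom == ch))
  j <- min(i + seg_len(mean_len) - 1L, hi)
  seg <- g[i:j, , drop = FALSE]
  rest <- g[-(i:j), , drop = FALSE]
  if (nrow(rest) == 0) return(g)
  at <- sample.int(nrow(rest) + 1L, 1L)  # insert before row `at` of rest
  seg$chrom <- if (at > nrow(rest)) rest$chrom[nrow(rest)] else rest$chrom[at]
  out <- rbind(rest[seq_len(at - 1L), , drop = FALSE], seg,
               rest[seq(at, length.out = nrow(rest) - at + 1L), , drop = FALSE])
  out[order(factor(out$chrom, levels = unique(out$chrom))), , drop = FALSE]
}

op_duplication <- function(g, counter) {
  i <- sample.int(nrow(g), 1L)
  copy <- g[i, , drop = FALSE]
  copy$gid <- next_gid(counter)
  rbind(g[seq_len(i), , drop = FALSE], copy,
        g[seq(i + 1L, length.out = nrow(g) - i), , drop = FALSE])
}

op_origination <- function(g, counter) {
  gid <- next_gid(counter)
  at <- sample.int(nrow(g) + 1L, 1L)
  ch <- if (nrow(g) == 0) 1L else if (at > nrow(g)) g$chrom[nrow(g)] else g$chrom[at]
  new <- data.frame(chrom = ch, gid = gid, fam = -gid, anc = NA_character_,
                    strand = "+", orig = TRUE, stringsAsFactors = FALSE)
  rbind(g[seq_len(at - 1L), , drop = FALSE], new,
        g[seq(at, length.out = nrow(g) - at + 1L), , drop = FALSE])
}

# mark the speciation node: genes present now are the ancestors whose
# descendants on the two sides are orthologs.  The tag keeps ancestor ids
# distinct across independent speciation markings (one per WGD subgenome
# lineage in the shared scenario).
mark_speciation <- function(g, tag) { g$anc <- paste0(tag, ".", g$gid); g }

# export a simulated genome as a gene table (synthetic coordinates:
# 1 kb gene starts spaced by gene rank)
as_gene_table <- function(g, label) {
  if (nrow(g) == 0) return(empty_gene_table())
  rank <- stats::ave(seq_len(nrow(g)), g$chrom, FUN = seq_along) - 1L
  df <- data.frame(genome_id = label,
                   chrom = sprintf("chr%02d", g$chrom),
                   start = rank * 1000L + 1L,
                   end = rank * 1000L + 601L,
                   strand = g$strand,
                   gene_id = sprintf("%s_g%06d", label, g$gid),
                   order_index = rank,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$order_index), , drop = FALSE]
}

#' Simulate a shared- or specific-WGD history
#'
#' Runs the event simulator over the five-taxon design and returns the
#' genomes plus the exact truth labels of every surviving cross-taxon
#' homolog pair between the A side and the B side: a pair is a *true
#' ortholog* iff the two genes descend from the same gene at the A/B
#' speciation node, and a *true out-paralog* otherwise (its coalescence
#' predates the speciation — the WGD, or an earlier duplication).  The two
#' sets are disjoint and every surviving A-vs-B homolog pair is in exactly
#' one.
#'
#' @param config a [sim_config()].
#' @return a `truth_set`: `config`, `genomes` (named list of gene tables
#'   for A1, A2, B1, B2 and optionally O), `pairs` (`data.frame` with
#'   `gene_a, gene_b, genome_a, genome_b, class, divergence, ks,
#'   originated, key`), `true_orthologs` / `true_outparalogs` (key
#'   vectors, originated pairs excluded), and `outgroup_pairs`.
#' @export
simulate_history <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  counter <- new.env(parent = emptyenv())
  counter$gid <- config$n_genes
  anc <- new_ancestor(config, counter)
  dT <- config$delta_t; t1 <- config$post_speciation_t
  sims <- list()
  if (config$scenario == "shared") {
    stem <- evolve_branch(anc, config$pre_t, config, counter)
    # WGD: two subgenome lineages, then speciation of each into A and B
    for (lineage in c(1L, 2L)) {
      L <- evolve_branch(stem, dT, config, counter)
      L <- mark_speciation(L, lineage)
      sims[[paste0("A", lineage)]] <- evolve_branch(L, t1, config, counter)
      sims[[paste0("B", lineage)]] <- evolve_branch(L, t1, config, counter)
    }
    div_orth <- 2 * t1
    div_para <- 2 * (t1 + dT)
  } else {
    # speciation first, then one independent WGD per lineage
    stem <- evolve_branch(anc, config$pre_t, config, counter)
    stem <- mark_speciation(stem, "s")
    for (side in c("A", "B")) {
      L <- evolve_branch(stem, dT, config, counter)
      for (copy in c(1L, 2L)) {
        sims[[paste0(side, copy)]] <- evolve_branch(L, t1, config, counter)
      }
    }
    div_orth <- 2 * (t1 + dT)
    div_para <- 2 * (t1 + dT + config$pre_t)
  }
  if (config$include_outgroup) {
    sims[["O"]] <- evolve_branch(anc, dT + 2 * t1, config, counter)
  }
  genomes <- lapply(names(sims), function(nm) as_gene_table(sims[[nm]], nm))
  names(genomes) <- names(sims)
  # A-vs-B homolog pairs with truth labels
  pairs <- list()
  for (ga in c("A1", "A2")) {
    for (gb in c("B1", "B2")) {
      pairs[[paste(ga, gb)]] <- truth_pairs(sims[[ga]], sims[[gb]], ga, gb,
                                            div_orth, div_para, config)
    }
  }
  pairs <- data.frame(data.table::rbindlist(pairs), stringsAsFactors = FALSE)
  outgroup_pairs <- NULL
  if (config$include_outgroup) {
    og <- list()
    div_og <- 2 * (config$pre_t + dT + t1)  # tip depth x2 through the root
    for (gi in setdiff(names(sims), "O")) {
      og[[gi]] <- truth_pairs(sims[["O"]], sims[[gi]], "O", gi,
                              div_og, div_og, config, outgroup = TRUE)
    }
    outgroup_pairs <- data.frame(data.table::rbindlist(og), stringsAsFactors = FALSE)
  }
  structure(list(config = config, genomes = genomes, pairs = pairs,
                 true_orthologs = pairs$key[pairs$class == "ortholog" & !pairs$originated],
                 true_outparalogs = pairs$key[pairs$class == "outparalog" & !pairs$originated],
                 outgroup_pairs = outgroup_pairs),
            class = "truth_set")
}

# all same-family cross pairs of two simulated genomes, labeled
truth_pairs <- function(sa, sb, la, lb, div_orth, div_para, cfg, outgroup = FALSE) {
  da <- data.table::data.table(fam = sa$fam, gid_a = sa$gid, anc_a = sa$anc,
                               orig_a = sa$orig)
  db <- data.table::data.table(fam = sb$fam, gid_b = sb$gid, anc_b = sb$anc,
                               orig_b = sb$orig)
  j <- merge(da, db, by = "fam", allow.cartesian = TRUE)
  if (nrow(j) == 0) {
    out <- data.table::data.table(gene_a = character(0), gene_b = character(0),
                                  genome_a = character(0), genome_b = character(0),
                                  class = character(0), divergence = numeric(0),
                                  ks = numeric(0), originated = logical(0))
    out$key <- character(0)
    return(out)
  }
  orth <- if (outgroup) rep(TRUE, nrow(j)) else
    (!is.na(j$anc_a) & !is.na(j$anc_b) & j$anc_a == j$anc_b)
  div <- ifelse(orth, div_orth, div_para)
  ks <- div * stats::rgamma(nrow(j), shape = cfg$ks_noise_shape,
                            rate = cfg$ks_noise_shape)
  ga <- sprintf("%s_g%06d", la, j$gid_a)
  gb <- sprintf("%s_g%06d", lb, j$gid_b)
  out <- data.table::data.table(gene_a = ga, gene_b = gb,
                                genome_a = la, genome_b = lb,
                                class = ifelse(orth, "ortholog", "outparalog"),
                                divergence = div, ks = ks,
                                originated = j$orig_a | j$orig_b)
  out$key <- pair_key(ga, gb)
  out
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %s scenario, delta_t=%.3g, fold=%g: %s genomes; %d orthologs, %d out-paralogs\n",
              x$config$scenario, x$config$delta_t, x$config$fold,
              paste(names(x$genomes), collapse = ","),
              length(x$true_orthologs), length(x$true_outparalogs)))
  invisible(x)
}

#' Merge pseudo-species into composite genomes
#'
#' Combines subgenome pseudo-species (e.g. A1 + A2) into one composite
#' genome per group, prefixing chromosome names with the source
#' pseudo-species, and relabels the truth pairs accordingly.  This turns
#' the four-pseudo-species benchmark layout into the two-genome layout of
#' a real tetraploid-vs-tetraploid comparison (dot plots, depth ratios).
#'
#' @param truth a [simulate_history()] result.
#' @param groups named list mapping new genome labels to pseudo-species
#'   vectors; default `list(A = c("A1","A2"), B = c("B1","B2"))`.
#' @return list with `genomes` (named list of merged gene tables) and
#'   `pairs` (truth pairs between the two groups, genome columns
#'   relabeled).
#' @export
merge_pseudo_genomes <- function(truth,
                                 groups = list(A = c("A1", "A2"), B = c("B1", "B2"))) {
  stopifnot(length(groups) == 2)
  genomes <- lapply(names(groups), function(nm) {
    parts <- lapply(groups[[nm]], function(lbl) {
      g <- truth$genomes[[lbl]]
      g$genome_id <- nm
      g$chrom <- paste(lbl, g$chrom, sep = "_")
      g
    })
    df <- do.call(rbind, parts)
    df <- df[order(df$chrom, df$order_index), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(genomes) <- names(groups)
  relabel <- setNames(rep(names(groups), lengths(groups)), unlist(groups))
  p <- truth$pairs
  keep <- p$genome_a %in% names(relabel) & p$genome_b %in% names(relabel) &
    relabel[p$genome_a] != relabel[p$genome_b]
  p <- p[keep, , drop = FALSE]
  p$genome_a <- unname(relabel[p$genome_a])
  p$genome_b <- unname(relabel[p$genome_b])
  list(genomes = genomes, pairs = p)
}
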