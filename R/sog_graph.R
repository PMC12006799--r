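# The orthologous syntenic graph and Markov clustering.
#
# Nodes are genes tagged with their genome; edges connect syntenic-ortholog
# gene pairs from OI-filtered blocks across all genome pairs, weighted by
# the maximum supporting block OI.  Clusters of this graph are syntenic
# orthogroups (SOGs): the clustering breaks weak links (stray cross-cluster
# edges) and bridges unexpectedly disrupted links (missing within-cluster
# edges) via the graph's transitive structure.
#
# The Markov Cluster (MCL) loop is implemented here from first principles:
# self-loops, column normalization, then alternating expansion (matrix
# power) and inflation (entrywise power + renormalization) with pruning,
# until the matrix change falls below tolerance.  Clusters are read from
# the limit matrix as the connected row/column groups of its support, which
# merges overlapping attractor systems deterministically.

#' Build the orthologous syntenic graph
#'
#' @param block_sets OI-filtered, annotated blocks: either a flat list of
#'   `synteny_block` objects or a list of such lists (one per genome pair).
#' @param weight_mode `"oi"` (edge weight = maximum block OI over the
#'   blocks supporting the pair) or `"unit"` (all weights 1).
#' @return a `syntenic_graph`: list with `nodes` (`gene_id`, `genome_id`)
#'   and `edges` (`gene_a`, `gene_b`, `weight`), one edge per distinct pair.
#' @export
build_graph <- function(block_sets, weight_mode = c("oi", "unit")) {
  weight_mode <- match.arg(weight_mode)
  blocks <- flatten_blocks(block_sets)
  if (!length(blocks)) {
    return(structure(list(nodes = data.frame(gene_id = character(0),
                                             genome_id = character(0),
                                             stringsAsFactors = FALSE),
                          edges = data.frame(gene_a = character(0),
                                             gene_b = character(0),
                                             weight = numeric(0),
                                             stringsAsFactors = FALSE)),
                     class = "syntenic_graph"))
  }
  dt <- data.table::rbindlist(lapply(blocks, function(b) {
    if (identical(b$genome_a, b$genome_b)) {
      stop("within-genome pair in block ", b$block_id,
           " (", b$genome_a, "): the syntenic graph admits only cross-genome edges")
    }
    data.table::data.table(gene_a = pmin(b$pairs$gene_a, b$pairs$gene_b),
                           gene_b = pmax(b$pairs$gene_a, b$pairs$gene_b),
                           genome_a = ifelse(b$pairs$gene_a <= b$pairs$gene_b,
                                             b$genome_a, b$genome_b),
                           genome_b = ifelse(b$pairs$gene_a <= b$pairs$gene_b,
                                             b$genome_b, b$genome_a),
                           w = if (weight_mode == "oi") as.numeric(b$oi) else 1)
  }))
  if (weight_mode == "oi" && anyNA(dt$w)) {
    stop("blocks must be annotated with OI before graph construction (or use weight_mode='unit')")
  }
  gene_a <- gene_b <- w <- NULL
  edges <- dt[, list(weight = max(w)), by = list(gene_a, gene_b)]
  nodes <- unique(data.table::data.table(
    gene_id = c(dt$gene_a, dt$gene_b),
    genome_id = c(dt$genome_a, dt$genome_b)))
  if (anyDuplicated(nodes$gene_id)) {
    g <- nodes$gene_id[duplicated(nodes$gene_id)][1]
    stop("gene ", g, " is tagged with more than one genome")
  }
  data.table::setorder(nodes, gene_id)
  data.table::setorder(edges, gene_a, gene_b)
  structure(list(nodes = data.frame(nodes, stringsAsFactors = FALSE),
                 edges = data.frame(edges, stringsAsFactors = FALSE)),
            class = "syntenic_graph")
}

flatten_blocks <- function(x) {
  if (inherits(x, "synteny_block")) return(list(x))
  if (!is.list(x)) stop("expected a list of synteny blocks")
  out <- list()
  for (el in x) {
    if (inherits(el, "synteny_block")) out[[length(out) + 1L]] <- el
    else out <- c(out, flatten_blocks(el))
  }
  out
}

#' @export
print.syntenic_graph <- function(x, ...) {
  cat(sprintf("<syntenic_graph> %d genes over %d genomes, %d edges\n",
              nrow(x$nodes), length(unique(x$nodes$genome_id)), nrow(x$edges)))
  invisible(x)
}

#' Markov clustering of the syntenic graph
#'
#' A from-scratch Markov Cluster (MCL) implementation.  Self-loops are
#' added with weight equal to each node's maximum incident edge weight
#' (1 for isolated nodes), the matrix is column-normalized, and the loop
#' alternates expansion (`expansion`-th matrix power) with inflation
#' (entrywise `inflation`-th power followed by column renormalization),
#' pruning entries below `prune` (a column's largest entry is never
#' pruned), until the largest entry change drops below `tol` or `max_iter`
#' is reached.  Non-convergence returns the current interpretation with a
#' warning, never an error.  Clusters are the connected components of the
#' limit matrix's support, so disconnected input components are never
#' merged and the partition is deterministic for a fixed input.
#'
#' Connected components are clustered independently, which is exact (the
#' transition matrix is block-diagonal) and keeps the dense per-component
#' matrices small.
#'
#' @param graph a [build_graph()] result.
#' @param inflation inflation exponent, must be > 1; default 1.5, the
#'   convention of orthogroup-clustering tools.
#' @param expansion matrix-power exponent; default 2.
#' @param max_iter iteration cap; default 100.
#' @param tol convergence threshold on the max entry change; default 1e-6.
#' @param prune entries below this are zeroed each iteration; default 1e-5.
#' @return an `mcl_partition`: `membership` (named integer vector, cluster
#'   ids numbered by the lexicographically smallest member), `nodes` (the
#'   graph's node table), `n_iter`, `converged`.
#' @export
mcl <- function(graph, inflation = 1.5, expansion = 2L, max_iter = 100L,
                tol = 1e-6, prune = 1e-5) {
  if (!is.numeric(inflation) || inflation <= 1) stop("inflation must be > 1")
  ids <- sort(graph$nodes$gene_id)
  nn <- length(ids)
  membership <- setNames(integer(nn), ids)
  if (nn == 0) {
    return(structure(list(membership = membership, nodes = graph$nodes,
                          n_iter = 0L, converged = TRUE), class = "mcl_partition"))
  }
  ia <- match(graph$edges$gene_a, ids)
  ib <- match(graph$edges$gene_b, ids)
  comp <- graph_components(nn, ia, ib)
  n_iter <- 0L; converged <- TRUE
  next_cluster <- 0L
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) == 1) {
      next_cluster <- next_cluster + 1L
      membership[members] <- next_cluster
      next
    }
    sel <- ia %in% members & ib %in% members
    li <- match(ia[sel], members); lj <- match(ib[sel], members)
    W <- matrix(0, length(members), length(members))
    W[cbind(li, lj)] <- graph$edges$weight[sel]
    W[cbind(lj, li)] <- graph$edges$weight[sel]
    res <- mcl_dense(W, inflation, expansion, max_iter, tol, prune)
    n_iter <- max(n_iter, res$n_iter)
    converged <- converged && res$converged
    for (cl in res$clusters) {
      next_cluster <- next_cluster + 1L
      membership[members[cl]] <- next_cluster
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", max_iter,
            " iterations; returning the current interpretation")
  }
  # renumber clusters by their lexicographically smallest member
  mins <- tapply(names(membership), membership, min)
  map <- setNames(as.integer(rank(mins)), names(mins))
  membership[] <- map[as.character(membership)]
  structure(list(membership = membership, nodes = graph$nodes,
                 n_iter = n_iter, converged = converged),
            class = "mcl_partition")
}

# core MCL loop on one dense symmetric weight matrix
mcl_dense <- function(W, inflation, expansion, max_iter, tol, prune) {
  k <- nrow(W)
  diag(W) <- pmax(apply(W, 2, max), .Machine$double.eps)  # self-loop = max incident weight
  M <- sweep(W, 2, colSums(W), "/")
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    E <- M
    for (e in seq_len(expansion - 1L)) E <- E %*% M
    I <- E^inflation
    # prune small entries but never a column's maximum
    cmax <- apply(I, 2, max)
    I[I < prune & I < rep(cmax, each = k)] <- 0
    I <- sweep(I, 2, colSums(I), "/")
    delta <- max(abs(I - M))
    M <- I
    if (delta < tol) { converged <- TRUE; break }
  }
  # clusters = connected components of the limit support (attractor
  # systems together with their basins)
  nz <- which(M > 0, arr.ind = TRUE)
  off <- nz[nz[, 1] != nz[, 2], , drop = FALSE]
  comp <- graph_components(k, off[, 1], off[, 2])
  clusters <- split(seq_len(k), comp)
  names(clusters) <- NULL
  list(clusters = clusters, n_iter = iter, converged = converged)
}

# connected components of an undirected graph given as edge endpoint
# indices; plain union-find, deterministic
graph_components <- function(n, i, j) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(i)) {
    ri <- find(i[k]); rj <- find(j[k])
    if (ri != rj) parent[min(ri, rj)] <- max(ri, rj)
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}
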