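# Orthology-call error emulation and assembly/annotation degradation.

#' Default orthology-inference error rates as a function of delta_t
#'
#' Tabulated emulation of the accuracy of modern orthology-inference tools
#' on the shared-WGD design: when the WGD-speciation time lag is small the
#' out-paralog copies are nearly as similar as the orthologs and roughly
#' 15% of calls are hidden paralogs; by delta_t = 0.5 the two coalescence
#' depths are easy to separate and the error decays to about 1%.  The
#' false-negative rate mirrors the false-positive rate.  Linear
#' interpolation between the anchors (0.05, 0.15), (0.1, 0.10),
#' (0.2, 0.05), (0.5, 0.01); constant outside.
#'
#' @param delta_t numeric vector of time lags (substitutions/site).
#' @return `data.frame` with columns `fp` and `fn`.
#' @export
default_error_rates <- function(delta_t) {
  fp <- stats::approx(x = c(0.05, 0.1, 0.2, 0.5),
                      y = c(0.15, 0.10, 0.05, 0.01),
                      xout = delta_t, rule = 2)$y
  data.frame(fp = fp, fn = fp)
}

resolve_rate <- function(rate, delta_t, default) {
  v <- if (is.null(rate)) default
       else if (is.function(rate)) rate(delta_t)
       else rate
  if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
    stop("error rates must be single probabilities in [0, 1]")
  }
  v
}

#' Emulate imperfect orthology inference
#'
#' Produces the pre-inferred ortholog set an external tool would hand to
#' the OI pipeline: each true ortholog pair is called with probability
#' `1 - fn`, each true out-paralog pair is miscalled ortholog with
#' probability `fp` (independently per pair).  Outgroup-vs-ingroup
#' ortholog pairs are called with probability `1 - fn` as well.  Rates
#' default to [default_error_rates()] at the configuration's `delta_t`;
#' `fp_rate` / `fn_rate` in the configuration (numbers or functions of
#' delta_t) override them.
#'
#' @param truth a [simulate_history()] result.
#' @param fp,fn optional direct overrides.
#' @return an [orthology_map()] with source `"emulated"`.
#' @export
emulate_orthology_calls <- function(truth, fp = NULL, fn = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  cfg <- truth$config
  def <- default_error_rates(cfg$delta_t)
  fp <- resolve_rate(fp %||% cfg$fp_rate, cfg$delta_t, def$fp)
  fn <- resolve_rate(fn %||% cfg$fn_rate, cfg$delta_t, def$fn)
  p <- truth$pairs
  called <- (p$class == "ortholog" & stats::runif(nrow(p)) <= 1 - fn) |
            (p$class == "outparalog" & stats::runif(nrow(p)) <= fp)
  keys <- p$key[called]
  if (!is.null(truth$outgroup_pairs) && nrow(truth$outgroup_pairs)) {
    og <- truth$outgroup_pairs
    keys <- c(keys, og$key[stats::runif(nrow(og)) <= 1 - fn])
  }
  structure(list(keys = unique(keys), source = "emulated"),
            class = "orthology_map")
}

genes_n50 <- function(sizes) {
  s <- sort(sizes, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Fragment a genome assembly to a target relative N50
#'
#' Cuts chromosomes at random gene-rank breakpoints until the contig N50
#' (measured in genes) drops to at most `relative_n50` times the original
#' N50.  Gene content is unchanged; order indices are recomputed per
#' contig.  Emulates assembly-continuity degradation for robustness tests.
#'
#' @param genes a gene table.
#' @param relative_n50 target ratio in `(0, 1]`; 1 returns the genome
#'   unchanged.
#' @return a gene table with fragmented chromosome labels
#'   (`<chrom>_f<k>`).
#' @export
fragment_assembly <- function(genes, relative_n50) {
  if (!is.numeric(relative_n50) || length(relative_n50) != 1 ||
      is.na(relative_n50) || relative_n50 <= 0 || relative_n50 > 1) {
    stop("relative_n50 must be in (0, 1]")
  }
  contig <- genes$chrom
  n50_0 <- genes_n50(table(contig))
  target <- relative_n50 * n50_0
  frag <- 0L
  while (genes_n50(table(contig)) > target) {
    sizes <- table(contig)
    big <- names(sizes)[sizes >= 2]
    if (!length(big)) break
    pick <- sample(big, 1L, prob = as.integer(sizes[big]))
    rows <- which(contig == pick)
    cut <- sample.int(length(rows) - 1L, 1L)  # break after rank `cut`
    frag <- frag + 1L
    contig[rows[seq(cut + 1L, length(rows))]] <- paste0(pick, "_f", frag)
  }
  out <- genes
  out$chrom <- contig
  # order within each contig follows the original order_index
  out <- out[order(match(genes$chrom, unique(genes$chrom)), genes$order_index), ,
             drop = FALSE]
  out$order_index <- stats::ave(seq_len(nrow(out)), out$chrom, FUN = seq_along) - 1L
  out <- out[order(out$chrom, out$order_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Randomly subsample a genome annotation
#'
#' Retains each gene independently with probability `fraction` and
#' recomputes order indices, emulating incomplete annotation.  The removed
#' genes are reported so truth sets can be restricted to the retained
#' universe.
#'
#' @param genes a gene table.
#' @param fraction retention probability in `(0, 1]`.
#' @return list with `genes` (the reduced table) and `removed` (character
#'   vector of removed gene ids); together they partition the input.
#' @export
subsample_annotation <- function(genes, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      is.na(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  keep <- stats::runif(nrow(genes)) <= fraction
  out <- genes[keep, , drop = FALSE]
  out$order_index <- stats::ave(seq_len(nrow(out)), out$chrom, FUN = seq_along) - 1L
  out <- out[order(out$chrom, out$order_index), , drop = FALSE]
  rownames(out) <- NULL
  list(genes = out, removed = genes$gene_id[!keep])
}
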