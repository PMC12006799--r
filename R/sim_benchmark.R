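# Benchmark harness: simulate -> emulate orthology calls -> detect blocks
# -> annotate OI -> filter -> extract syntenic orthologs -> score against
# the simulation truth with precision / recall / F1.

#' Score called syntenic orthologs against the simulation truth
#'
#' Counts are restricted to A-vs-B comparisons; pairs involving originated
#' (novel) genes are excluded from all three counts.  `tp` = called pairs
#' that are true orthologs, `fp` = called pairs that are true
#' out-paralogs, `fn` = true orthologs not called.  Precision
#' `tp/(tp+fp)`, recall `tp/(tp+fn)` and `F1 = 2PR/(P+R)` use the
#' convention 0 when the denominator is 0.
#'
#' @param called the call set: an `orthology_map`, a character vector of
#'   pair keys, or a `data.frame` with `gene_a`/`gene_b`.
#' @param truth a [simulate_history()] result.
#' @return a `confusion_counts`: `tp, fp, fn, precision, recall, f1`.
#' @export
evaluate <- function(called, truth) {
  keys <- if (inherits(called, "orthology_map")) called$keys
          else if (is.character(called)) called
          else if (is.data.frame(called)) pair_key(called$gene_a, called$gene_b)
          else stop("unsupported 'called' type")
  keys <- unique(keys)
  orth <- truth$true_orthologs
  outp <- truth$true_outparalogs
  tp <- sum(keys %chin% orth)
  fp <- sum(keys %chin% outp)
  fn <- length(orth) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 precision = precision, recall = recall, f1 = f1),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d FN=%d  P=%.4f R=%.4f F1=%.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

# one replicate: returns the annotated blocks plus evaluations
run_replicate <- function(cfg, oi_cutoffs, min_block, max_gap) {
  truth <- simulate_history(cfg)
  omap <- emulate_orthology_calls(truth)
  combos <- expand.grid(a = c("A1", "A2"), b = c("B1", "B2"),
                        stringsAsFactors = FALSE)
  blocks <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- truth$pairs[truth$pairs$genome_a == combos$a[i] &
                       truth$pairs$genome_b == combos$b[i], , drop = FALSE]
    blocks <- c(blocks, detect_blocks(sub, truth$genomes[[combos$a[i]]],
                                      truth$genomes[[combos$b[i]]],
                                      min_block = min_block, max_gap = max_gap))
  }
  blocks <- annotate_blocks(blocks, omap)
  noise <- if (length(blocks)) oi_distribution(blocks)$noise else NA_real_
  raw <- evaluate(omap, truth)
  rows <- lapply(oi_cutoffs, function(cut) {
    kept <- filter_blocks(blocks, oi_cutoff = cut)
    ev <- evaluate(extract_syntenic_orthologs(kept), truth)
    data.frame(cutoff = cut, tp = ev$tp, fp = ev$fp, fn = ev$fn,
               precision = ev$precision, recall = ev$recall, f1 = ev$f1,
               raw_precision = raw$precision, raw_recall = raw$recall,
               noise = noise, n_blocks = length(blocks),
               mean_block_size = if (length(blocks))
                 mean(vapply(blocks, `[[`, 0L, "m")) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the simulation benchmark over a condition grid
#'
#' For every (delta_t, fold, replicate): simulate the shared-WGD history,
#' emulate imperfect orthology calls, detect collinear blocks from all
#' A-vs-B homolog pairs, annotate block OI, filter at each cutoff, extract
#' syntenic orthologs and score them against the truth.  Per-replicate
#' seeds are derived deterministically from the master seed, so the whole
#' table is reproducible bit for bit.
#'
#' @param delta_t_grid time lags to test (substitutions/site).
#' @param fold_grid rearrangement-rate multipliers; default 1.
#' @param replicates replicates per condition; default 20.
#' @param oi_cutoffs OI cutoffs to score; default 0.6.
#' @param seed master seed.
#' @param n_genes,n_chromosomes ancestral genome size; defaults 500 / 5.
#' @param min_block,max_gap block-detector parameters; defaults 5 / 25.
#' @param scenario passed to [sim_config()].
#' @param ... further arguments to [sim_config()].
#' @return a `data.frame`, one row per (delta_t, fold, replicate, cutoff),
#'   with confusion counts, precision/recall/F1, the raw (unfiltered)
#'   emulated-call precision/recall, the OI-noise statistic and block
#'   statistics.
#' @export
run_benchmark <- function(delta_t_grid, fold_grid = 1, replicates = 20L,
                          oi_cutoffs = 0.6, seed = 1L,
                          n_genes = 500L, n_chromosomes = 5L,
                          min_block = 5L, max_gap = 25L,
                          scenario = "shared", ...) {
  conditions <- expand.grid(delta_t = delta_t_grid, fold = fold_grid)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 nrow(conditions) * replicates),
                      nrow = nrow(conditions))
  out <- list()
  for (ci in seq_len(nrow(conditions))) {
    for (r in seq_len(replicates)) {
      cfg <- sim_config(n_genes = n_genes, n_chromosomes = n_chromosomes,
                        delta_t = conditions$delta_t[ci],
                        fold = conditions$fold[ci],
                        scenario = scenario, seed = rep_seeds[ci, r], ...)
      res <- run_replicate(cfg, oi_cutoffs, min_block, max_gap)
      res <- cbind(data.frame(delta_t = conditions$delta_t[ci],
                              fold = conditions$fold[ci], replicate = r),
                   res)
      out[[length(out) + 1L]] <- res
    }
  }
  results <- do.call(rbind, out)
  rownames(results) <- NULL
  results
}

#' Summarize benchmark results per condition
#'
#' Medians and percentile 95% intervals of precision, recall and F1 per
#' (delta_t, fold, cutoff), plus median raw-call precision, OI noise and
#' block size.
#'
#' @param results a [run_benchmark()] table.
#' @return a `data.frame`, one row per condition and cutoff.
#' @export
summarize_benchmark <- function(results) {
  sp <- split(results, list(results$delta_t, results$fold, results$cutoff),
              drop = TRUE)
  rows <- lapply(sp, function(s) {
    q <- function(v, p) unname(stats::quantile(v, p, na.rm = TRUE))
    data.frame(delta_t = s$delta_t[1], fold = s$fold[1], cutoff = s$cutoff[1],
               n_replicates = nrow(s),
               precision_median = stats::median(s$precision),
               precision_lo = q(s$precision, 0.025),
               precision_hi = q(s$precision, 0.975),
               recall_median = stats::median(s$recall),
               recall_lo = q(s$recall, 0.025),
               recall_hi = q(s$recall, 0.975),
               f1_median = stats::median(s$f1),
               raw_precision_median = stats::median(s$raw_precision),
               raw_recall_median = stats::median(s$raw_recall),
               noise_median = stats::median(s$noise),
               mean_block_size = mean(s$mean_block_size, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fold, out$delta_t, out$cutoff), , drop = FALSE]
  rownames(out) <- NULL
  out
}
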