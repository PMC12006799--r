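# shared-WGD simulator, error emulation, block chaining, scoring

no_event_config <- function(n = 50, ...) {
  sim_config(n_genes = n, n_chromosomes = 2,
             rates = c(loss = 0, inversion = 0, transposition = 0,
                       duplication = 0, origination = 0), ...)
}

test_that("with all event rates zero the four pseudo-genomes are identical in content", {
  truth <- simulate_history(no_event_config(n = 40, delta_t = 0.3, seed = 1))
  sizes <- vapply(truth$genomes, nrow, 0L)
  expect_true(all(sizes == 40L))
  strip <- function(g) sub("^[A-Z0-9]+_", "", g$gene_id)
  expect_identical(strip(truth$genomes$A1), strip(truth$genomes$B2))
  # orthologs live in the same-subgenome comparisons only: 2 x n pairs
  expect_identical(length(truth$true_orthologs), 2L * 40L)
  expect_identical(length(truth$true_outparalogs), 2L * 40L)
  # disjoint truth sets covering every surviving homolog pair
  expect_identical(intersect(truth$true_orthologs, truth$true_outparalogs),
                   character(0))
  expect_identical(length(truth$true_orthologs) + length(truth$true_outparalogs),
                   nrow(truth$pairs))
})

test_that("the same seed reproduces the identical truth set", {
  cfg <- sim_config(n_genes = 120, delta_t = 0.1, fold = 100, seed = 99)
  t1 <- simulate_history(cfg)
  t2 <- simulate_history(cfg)
  expect_identical(t1$pairs, t2$pairs)
  expect_identical(t1$genomes, t2$genomes)
})

test_that("ortholog survival under loss matches the closed-form expectation", {
  # loss only; per-branch survival ~ exp(-r x L).  A pair survives the
  # shared stem and delta_t branch once and its two terminal branches:
  # E = 2n x exp(-r x (pre + dT + 2 x t1))
  r <- 0.5
  cfg <- sim_config(n_genes = 500, delta_t = 0.2, seed = 31,
                    rates = c(loss = r, inversion = 0, transposition = 0,
                              duplication = 0, origination = 0))
  truth <- simulate_history(cfg)
  p_surv <- exp(-r * (0.2 + 0.2 + 2 * 0.2))
  expected <- 2 * 500 * p_surv
  bounds <- qbinom(c(0.005, 0.995), 2L * 500L, p_surv)
  got <- length(truth$true_orthologs)
  expect_gte(got, bounds[1])
  expect_lte(got, bounds[2])
  expect_lt(abs(got - expected) / expected, 0.2)
})

test_that("a loss regime expected to strand fewer than 10 genes is rejected", {
  expect_error(sim_config(n_genes = 100, delta_t = 1,
                          rates = c(loss = 10, inversion = 0, transposition = 0,
                                    duplication = 0, origination = 0)),
               "smaller fold")
})

test_that("error emulator degenerate cases reproduce the truth sets exactly", {
  truth <- simulate_history(no_event_config(n = 60, delta_t = 0.2,
                                            include_outgroup = FALSE, seed = 2))
  perfect <- emulate_orthology_calls(truth, fp = 0, fn = 0)
  expect_identical(sort(perfect$keys), sort(truth$true_orthologs))
  flipped <- emulate_orthology_calls(truth, fp = 1, fn = 1)
  expect_identical(sort(flipped$keys), sort(truth$true_outparalogs))
  expect_error(emulate_orthology_calls(truth, fp = 1.2), "\\[0, 1\\]")
})

test_that("realized error rates sit inside 3-sigma binomial bounds", {
  truth <- simulate_history(no_event_config(n = 2500, delta_t = 0.2,
                                            include_outgroup = FALSE, seed = 3))
  set.seed(17)
  omap <- emulate_orthology_calls(truth, fp = 0.15, fn = 0.15)
  n_orth <- length(truth$true_orthologs)     # 5000 true pairs per class
  n_outp <- length(truth$true_outparalogs)
  called_orth <- sum(truth$true_orthologs %in% omap$keys)
  called_outp <- sum(truth$true_outparalogs %in% omap$keys)
  for (obs in list(c(called_orth, n_orth, 0.85), c(called_outp, n_outp, 0.15))) {
    sd3 <- 3 * sqrt(obs[2] * obs[3] * (1 - obs[3]))
    expect_lt(abs(obs[1] - obs[2] * obs[3]), sd3)
  }
})

test_that("the default error model decays from 0.15 at small delta_t to 0.01 at 0.5+", {
  expect_equal(default_error_rates(0.01)$fp, 0.15)
  expect_equal(default_error_rates(0.05)$fp, 0.15)
  expect_equal(default_error_rates(0.5)$fp, 0.01)
  expect_equal(default_error_rates(1)$fp, 0.01)
  r <- default_error_rates(c(0.05, 0.1, 0.3, 0.6))
  expect_true(all(diff(r$fp) <= 0))
  expect_identical(r$fp, r$fn)
})

test_that("perfectly collinear pairs chain into one block; a large gap splits them", {
  ga <- mk_genes("A", c(c1 = 100))
  gb <- mk_genes("B", c(d1 = 100))
  pairs <- data.frame(gene_a = ga$gene_id[1:10], gene_b = gb$gene_id[1:10])
  blocks <- detect_blocks(pairs, ga, gb)
  expect_length(blocks, 1)
  expect_identical(n_pairs(blocks[[1]]), 10L)
  expect_identical(blocks[[1]]$orientation, "same")

  far <- data.frame(gene_a = ga$gene_id[c(1:6, 40:45)],
                    gene_b = gb$gene_id[c(1:6, 40:45)])
  split2 <- detect_blocks(far, ga, gb, min_block = 5, max_gap = 25)
  expect_length(split2, 2)

  inv <- data.frame(gene_a = ga$gene_id[1:8], gene_b = gb$gene_id[8:1])
  expect_identical(detect_blocks(inv, ga, gb)[[1]]$orientation, "inverted")
})

test_that("chaining matches the exhaustive oracle on random instances", {
  ga <- mk_genes("A", c(c1 = 120, c2 = 80))
  gb <- mk_genes("B", c(d1 = 120, d2 = 80))
  for (seed in 1:8) {
    set.seed(400 + seed)
    n <- sample(50:200, 1)
    ia <- sample(nrow(ga), n, replace = TRUE)
    ib <- sample(nrow(gb), n, replace = TRUE)
    pairs <- unique(data.frame(gene_a = ga$gene_id[ia], gene_b = gb$gene_id[ib],
                               stringsAsFactors = FALSE))
    got <- detect_blocks(pairs, ga, gb, min_block = 3, max_gap = 20)
    # oracle: chain the tandem-collapsed pairs per chromosome pair,
    # keep >= 3, compare pair sets
    pairs <- collapse_tandem_partners(pairs, ga, gb)
    ra <- data.frame(ch = ga$chrom[match(pairs$gene_a, ga$gene_id)],
                     x = ga$order_index[match(pairs$gene_a, ga$gene_id)])
    rb <- data.frame(ch = gb$chrom[match(pairs$gene_b, gb$gene_id)],
                     y = gb$order_index[match(pairs$gene_b, gb$gene_id)])
    want <- list()
    for (ca in unique(ra$ch)) for (cb in unique(rb$ch)) {
      sel <- which(ra$ch == ca & rb$ch == cb)
      if (!length(sel)) next
      for (chain in chain_oracle(ra$x[sel], rb$y[sel], max_gap = 20)) {
        if (length(chain) >= 3) {
          want[[length(want) + 1]] <- sort(paste(pairs$gene_a[sel][chain],
                                                 pairs$gene_b[sel][chain]))
        }
      }
    }
    got_sets <- lapply(got, function(b) sort(paste(b$pairs$gene_a, b$pairs$gene_b)))
    key <- function(l) sort(vapply(l, paste, "", collapse = "|"))
    expect_identical(key(got_sets), key(want))
  }
})

test_that("fragmentation hits the target N50, conserves genes; bad targets error", {
  genes <- mk_genes("A", c(c1 = 100))
  expect_identical(fragment_assembly(genes, 1), genes)
  set.seed(9)
  for (rn in c(0.9, 0.5, 0.2, 0.05)) {
    frag <- fragment_assembly(genes, rn)
    expect_identical(sort(frag$gene_id), sort(genes$gene_id))  # content unchanged
    expect_lte(synorth:::genes_n50(table(frag$chrom)), rn * 100)
    # order indices are a contiguous 0..k-1 run per contig
    for (ch in unique(frag$chrom)) {
      oi <- sort(frag$order_index[frag$chrom == ch])
      expect_identical(oi, seq_along(oi) - 1L)
    }
  }
  expect_error(fragment_assembly(genes, 1.5), "\\(0, 1\\]")
  expect_error(fragment_assembly(genes, 0), "\\(0, 1\\]")
})

test_that("subsampling is a partition, binomial in size, identity at fraction 1", {
  genes <- mk_genes("A", c(c1 = 600, c2 = 400))
  expect_identical(subsample_annotation(genes, 1)$genes, genes)
  set.seed(11)
  sub <- subsample_annotation(genes, 0.5)
  expect_identical(sort(c(sub$genes$gene_id, sub$removed)), sort(genes$gene_id))
  sd3 <- 3 * sqrt(1000 * 0.25)
  expect_lt(abs(nrow(sub$genes) - 500), sd3)
  expect_error(subsample_annotation(genes, 0), "\\(0, 1\\]")
})

test_that("confusion counts follow the definitions, with 0-denominator conventions", {
  truth <- list(true_orthologs = sprintf("o%02d", 1:10),
                true_outparalogs = sprintf("p%02d", 1:10))
  called <- c(sprintf("o%02d", 1:9), "p01")
  ev <- evaluate(called, truth)
  expect_identical(c(ev$tp, ev$fp, ev$fn), c(9L, 1L, 1L))
  expect_equal(ev$precision, 0.9)
  expect_equal(ev$recall, 0.9)
  expect_equal(ev$f1, 0.9)

  perfect <- evaluate(truth$true_orthologs, truth)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))

  nothing <- evaluate(character(0), truth)
  expect_equal(c(nothing$precision, nothing$recall, nothing$f1), c(0, 0, 0))
})

test_that("pairs involving originated genes are excluded from scoring", {
  cfg <- sim_config(n_genes = 80, n_chromosomes = 2, delta_t = 0.2, seed = 12,
                    rates = c(loss = 0, inversion = 0, transposition = 0,
                              duplication = 0, origination = 0.05),
                    include_outgroup = FALSE)
  truth <- simulate_history(cfg)
  expect_gt(sum(truth$pairs$originated), 0)
  expect_false(any(truth$pairs$key[truth$pairs$originated] %in%
                   c(truth$true_orthologs, truth$true_outparalogs)))
})

test_that("run_benchmark wiring: one row per condition x replicate x cutoff, reproducible", {
  res <- run_benchmark(delta_t_grid = 0.2, replicates = 1, seed = 5,
                       oi_cutoffs = c(0.5, 0.6), n_genes = 150,
                       n_chromosomes = 2)
  expect_identical(nrow(res), 2L)
  expect_identical(res$cutoff, c(0.5, 0.6))
  res2 <- run_benchmark(delta_t_grid = 0.2, replicates = 1, seed = 5,
                        oi_cutoffs = c(0.5, 0.6), n_genes = 150,
                        n_chromosomes = 2)
  expect_identical(res, res2)
  sm <- summarize_benchmark(res)
  expect_identical(nrow(sm), 2L)
  expect_identical(sm$n_replicates, c(1L, 1L))
})

test_that("at default rearrangement rates the benchmark recovers near-perfect orthologs", {
  res <- run_benchmark(delta_t_grid = c(0.05, 0.2, 1), fold_grid = 1,
                       replicates = 20, oi_cutoffs = 0.6, seed = 1234,
                       n_genes = 500)
  sm <- summarize_benchmark(res)
  expect_identical(nrow(sm), 3L)
  expect_true(all(sm$precision_median >= 0.99))
  expect_true(all(sm$recall_median >= 0.99))
  # OI polarization at the default (fold = 1) conditions: the dividing
  # range [0.3, 0.7) holds under 5% of the pair mass at every condition
  expect_true(all(sm$noise_median < 0.05))
  # the filter's entire point: it must not be worse than the raw calls
  expect_true(all(sm$precision_median >= sm$raw_precision_median))
})

test_that("median recall degrades monotonically as rearrangement rates scale up", {
  res <- run_benchmark(delta_t_grid = 0.2, fold_grid = c(1, 10, 100, 1000),
                       replicates = 20, oi_cutoffs = 0.6, seed = 77,
                       n_genes = 500)
  sm <- summarize_benchmark(res)
  sm <- sm[order(sm$fold), ]
  expect_identical(sm$fold, c(1, 10, 100, 1000))
  expect_true(all(diff(sm$recall_median) <= 1e-9))
})

test_that("tandem-duplicate partners collapse to the best pair before chaining", {
  ga <- mk_genes("A", c(c1 = 40))
  gb <- mk_genes("B", c(d1 = 40))
  # gene b5 has two partners 1 rank apart: the tandem copy (high Ks) drops
  pairs <- data.frame(gene_a = ga$gene_id[c(5, 6, 20)],
                      gene_b = gb$gene_id[c(5, 5, 20)],
                      ks = c(0.4, 2.4, 0.4), stringsAsFactors = FALSE)
  out <- collapse_tandem_partners(pairs, ga, gb)
  expect_identical(nrow(out), 2L)
  expect_identical(out$gene_a[1], ga$gene_id[5])
  # partners far apart on the chromosome are both kept (not a tandem array)
  far <- data.frame(gene_a = ga$gene_id[c(5, 30)], gene_b = gb$gene_id[c(5, 5)],
                    ks = c(0.4, 2.4), stringsAsFactors = FALSE)
  expect_identical(nrow(collapse_tandem_partners(far, ga, gb)), 2L)
  # without Ks the smaller rank wins
  noks <- data.frame(gene_a = ga$gene_id[c(6, 5)], gene_b = gb$gene_id[c(5, 5)],
                     stringsAsFactors = FALSE)
  expect_identical(collapse_tandem_partners(noks, ga, gb)$gene_a, ga$gene_id[5])
  # tandem_max = 0 disables the collapse
  expect_identical(nrow(collapse_tandem_partners(pairs, ga, gb, tandem_max = 0)), 3L)
})
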