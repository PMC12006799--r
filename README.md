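# synorth — orthologous synteny identification with the Orthology Index

Comparative genomics in plants (and other polyploidy-rich lineages)
constantly runs into the same confound: a synteny search between two
genomes that share an ancestral whole-genome duplication (WGD) returns both
*orthologous* blocks (tracing to the speciation) and *out-paralogous*
blocks (tracing to the WGD).  Ks cutoffs separate them only when
substitution rates cooperate; depth-quota filters need the WGD history to
be known in advance.  `synorth` implements the **Orthology Index**, which
needs neither: for a syntenic block with *m* gene pairs of which *n* were
independently pre-inferred as orthologs (by OrthoFinder or any comparable
tool),

    OI = n / m,   OI in [0, 1]

Orthologous blocks concentrate ortholog calls (OI near 1), out-paralogous
blocks receive only scattered false positives (OI near 0), and a single
cutoff (default 0.6) separates the two modes across lineages without
per-species tuning.

The package is aimed at researchers doing plant comparative genomics and
phylogenomics: it reads the block formats of the common synteny detectors
(MCScanX, WGDI, JCVI anchors) and ortholog lists (two-column or
OrthoFinder-style), filters blocks at an OI cutoff, extracts syntenic
ortholog pairs, profiles synteny depth for relative-ploidy inference,
clusters syntenic orthologs into syntenic orthogroups (SOGs) with a
from-scratch Markov Cluster implementation, draws the four-panel
diagnostic dot plot, and ships a self-contained shared-WGD gene-order
simulator with a precision/recall/F1 benchmark harness.

## Worked example

```r
library(synorth)

## the canonical worked example: 80 syntenic pairs, 72 pre-inferred orthologs
ga <- sprintf("pop_%03d", 1:80); gb <- sprintf("sal_%03d", 1:80)
block <- synteny_block("b1", "poplar", "willow", "chr01", "chr01",
                       pairs = data.frame(gene_a = ga, gene_b = gb))
orth  <- orthology_map(ga[1:72], gb[1:72])
compute_oi(block, orth)$oi
#> [1] 0.9

## a full simulated pipeline: shared WGD, time lag 0.2 subst/site
cfg   <- sim_config(n_genes = 500, delta_t = 0.2, fold = 1000, seed = 7)
truth <- simulate_history(cfg)
omap  <- emulate_orthology_calls(truth)
blocks <- list()
for (ga in c("A1", "A2")) for (gb in c("B1", "B2")) {
  sub <- truth$pairs[truth$pairs$genome_a == ga & truth$pairs$genome_b == gb, ]
  blocks <- c(blocks, detect_blocks(sub, truth$genomes[[ga]], truth$genomes[[gb]]))
}
ann  <- annotate_blocks(blocks, omap)
oi_distribution(ann)
#> <oi_distribution> 111 blocks / 979 pairs; noise[0.3,0.7) = 0.0215 (pair-weighted)
kept <- filter_blocks(ann, oi_cutoff = 0.6)
evaluate(extract_syntenic_orthologs(kept), truth)
#> <confusion_counts> TP=581 FP=1 FN=339  P=0.9983 R=0.6315 F1=0.7736
```

The OI histogram is polarized (2% of pair mass falls in the dividing
range [0.3, 0.7)), and filtering at 0.6 yields near-perfect precision even
in this heavy-rearrangement regime (1000-fold rates, blocks of ~10 genes);
the lost recall is pairs whose blocks were shattered below the 5-pair
detection floor, not misclassified blocks.

A command-line entry point is installed as `exec/soi`:

```sh
soi filter --blocks blocks.collinearity --dialect mcscanx \
    --orthologs orthologues.tsv --ortholog-dialect orthofinder \
    --cutoff 0.6 -o orthologous_blocks.tsv
soi dotplot --blocks blocks.tsv --genes-x A.tsv --genes-y B.tsv \
    --orthologs pairs.tsv --color oi -o plot.svg
soi simulate --delta-t 0.05,0.2,1 --fold 1000 --replicates 20 \
    --seed 1 --out-dir bench/
```

See the methods vignette (`vignettes/orthology-index.Rmd`) for the model,
parameter rationale and the simulator's scope.

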