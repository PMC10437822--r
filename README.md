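# hiertax

Hierarchical, alignment-free, marker-free taxonomic classification of
genomes and metagenome-assembled genomes (MAGs), with an explicit
*partial classification* option for genomes that cannot be confidently
placed at the species level.

Binned MAGs often lack the single-copy marker genes that alignment-based
classifiers rely on, and flat classifiers that must emit a species call
produce confidently wrong answers for genomes whose taxa are missing from
the reference. `hiertax` instead descends a GTDB-style taxonomy one rank
at a time and is allowed to stop: the output for each genome is a
classification path with a per-rank status — `complete`, at most one
`uncertain`, then `unattempted` — and a numerical confidence at every
predicted rank. It is aimed at microbiome researchers who want
compositional (k-mer) evidence for, or against, tentative taxonomic
assignments.

## Method

* **Features.** Each sequence becomes its order-k Frequency Chaos Game
  Representation FCGR_k: a 4^k vector of k-mer frequencies (default
  k = 7), normalised by sequence length excluding the separator `O` and
  ambiguous `N`. Contigs are pseudo-concatenated with `O` so no k-mer
  spans a contig junction.
* **Local classifiers.** Every parent taxon with ≥ 2 children gets a
  quadratic-kernel SVM (one-vs-one) with Platt-calibrated posteriors; the
  confidence of a prediction is the maximum posterior. A single-child
  parent gets a *novelty* classifier — 10% of its training items are
  relabelled as an artificial outlier taxon — whose outlier verdict stops
  the descent.
* **Stopping thresholds (STP).** For every (parent, child) pair, a
  threshold `T = max(a, b) − v` is learned from five-fold cross-validated
  training confidences, where `a` is the smallest candidate threshold at
  which the constrained accuracy of the retained records exceeds a target
  (default 90%), `b` is the mean confidence of the correct records and
  `v` (default 0.05) a variability allowance. A query proceeds past a
  rank iff its confidence ≥ T for the predicted child.
* **Metrics.** Per rank `tr_j`: constrained accuracy CA_g, absolute
  accuracy AA_g, complete classification rate CR_g, and the weighted
  accuracy WA_g whose per-genome weight is 1 for a correct complete
  classification, 0 for nothing correct below the root, and otherwise
  `max{0, (1/j)(p − (min{h, j} − p)/2)}` with `p` the deepest correct
  rank and `h` the path length.

A deterministic synthetic-corpus generator (hierarchically perturbed
order-1 Markov emitters) makes the whole pipeline testable without any
downloads. See `vignettes/hiertax-methods.Rmd` for the full model
description and design rationale.

## Worked example

Train on a small synthetic corpus (8 species, 2 phyla × 2 genera × 2
species), classify the training genomes and a genome from a held-out
*novel* genus:

```r
library(hiertax)

spec   <- synthetic_spec(genome_len = 50000L, seed = 1L)
corpus <- make_corpus(spec, novel_genus = TRUE)
cfg    <- hiertax_config(k = 4L,
                         sampling = sampling_config(n_fragments = 4L,
                                                    fragment_len = 10000L,
                                                    n_replicates = 10L,
                                                    min_contig_len = 1000L),
                         seed = 2L)
fit <- hiertax_train(corpus$genomes[names(corpus$lineages)],
                     corpus$lineages, cfg)
fit
#> Hierarchical FCGR/QSVM taxonomic classifier
#>   k = 4 (256 features); 8 training genomes, 80 items
#>   7 multi-child and 0 single-child (novelty) node models
#>   14 stopping thresholds over ranks: Domain > Phylum > Genus > Species

predict(fit, corpus$genomes[names(corpus$lineages)][1:2])
#> S1_1_1_1_g1: Domain D1 (confidence 100%) -> Phylum P1_1 (confidence 98%)
#>   -> Genus G1_1_1 (confidence 96%) -> Species S1_1_1_1 (confidence 91%)
#> S1_1_1_2_g1: Domain D1 (confidence 100%) -> Phylum P1_1 (confidence 97%)
#>   -> Genus G1_1_1 (confidence 95%) -> Species S1_1_1_2 (confidence 92%)

predict(fit, corpus$heldout)
#> Snovel1_g1: Domain D1 (confidence 100%) -> Phylum P1_1 (confidence 54%) (uncertain)
```

The two known genomes descend to their correct species with high
confidence at every rank. The novel-genus genome is *partially*
classified: its phylum-level confidence (0.54) falls below the learned
stopping threshold for that parent–child pair, so the path ends in an
explicit `uncertain` step instead of a wrong species call. Scoring the
training genomes against their reference lineages:

```r
evaluate_paths(predict(fit, corpus$genomes[names(corpus$lineages)]),
               corpus$truth)
#> Per-rank classification performance (genome level):
#>     rank CA AA WA CR n_complete n_correct n_total n_excluded
#>   Domain  1  1  1  1          8         8       8          0
#>   Phylum  1  1  1  1          8         8       8          0
#>    Genus  1  1  1  1          8         8       8          0
#>  Species  1  1  1  1          8         8       8          0
```

All four metrics are 1 at every rank: every genome is completely and
correctly classified down to species. The learned thresholds are
auditable (`fit$thresholds`): per pair, the grid minimum `a`, the mean
correct confidence `b` and `T = max(a, b) − 0.05`.

## Command line

```sh
inst/cli/hiertax synth    --out fixture/ --seed 3
inst/cli/hiertax train    --fasta-dir fixture/train --lineages fixture/lineages.tsv \
                          --out model.rds --k 7 --seed 5
inst/cli/hiertax classify --model model.rds --fasta-dir queries/ --out results.tsv
inst/cli/hiertax evaluate --results results.tsv --truth fixture/truth.tsv --out report.tsv
```

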