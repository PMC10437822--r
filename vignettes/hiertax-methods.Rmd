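---
title: "Methods: hierarchical alignment-free classification with stopping thresholds"
author: "hiertax authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical alignment-free classification with stopping thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Metagenome-assembled genomes (MAGs) routinely lack the marker genes that
alignment-based taxonomic classifiers depend on, and forcing every genome to
a species call produces confidently wrong answers for genomes from taxa that
are absent from the reference. `hiertax` addresses both issues with an
alignment-free, marker-free hierarchical classifier that is allowed to *stop
early*: a genome that cannot be placed confidently at some rank receives a
partial classification path ending in an explicit "uncertain" step, instead
of a forced (and likely wrong) complete path.

## Features: chaos-game k-mer frequencies

Every sequence is represented by its order-$k$ Frequency Chaos Game
Representation (FCGR$_k$): the $2^k \times 2^k$ grid of k-mer counts,
flattened to a vector of length $4^k$ and divided by the sequence length
excluding the symbols `O` and `N`. Contigs are *pseudo-concatenated* —
joined with a single separator symbol `O` — so that no artificial k-mer
spanning a contig junction is ever counted; any window containing `O` or
`N` is skipped. The default is $k = 7$ (16,384 features) for genome-scale
corpora; the test suite and the bundled benchmark use $k \in \{2,3,4\}$,
where the synthetic signal is already separable and runtimes stay in
seconds.

The CGR corner convention is A=(0,0), C=(0,1), G=(1,1), T=(1,0), with a
k-mer's first symbol selecting the coarsest quadrant, and cells flattened
row-major. No published convention is canonical; any fixed bijection gives
classification-equivalent features (a permutation of coordinates, which the
kernel treats identically — a property the test suite checks directly), so
the convention is documented rather than configurable. Counting is strand
specific: CGR signatures are orientation-sensitive and no
reverse-complement canonicalisation is applied. Feature vectors are kept
dense for all supported $k \le 12$; even at the top of that range a vector
is ~130 MB transient memory, which we consider acceptable for a tool that
processes one genome at a time, so no sparse representation is used.

## Hierarchically structured local classification

One classifier lives at every parent taxon of the (GTDB-style) taxonomy:

* **Multi-child parents** get a quadratic-kernel (degree-2 polynomial)
  support vector machine, decomposed one-vs-one, trained on all items of
  the parent's subtree labelled by child. Two confidence routes mirror the
  two phases:
  * *training route*: stratified five-fold cross-validation; an item's
    confidence is the maximum over children of the softmax of its
    per-child decision-score sums. These out-of-fold records feed
    threshold selection (below).
  * *classification route*: per-pair Platt sigmoids are fitted on the
    cross-validated decision scores, and pairwise probabilities are
    coupled into a posterior by normalised averaging
    ($p_i \propto \sum_{j \ne i} r_{ij}$). The confidence of a prediction
    is the maximum posterior, which always lies in $[1/C, 1]$.
* **Single-child parents** get a *novelty* classifier: a uniformly random
  10% of the items is relabelled as an artificial "outlier taxon" and a
  binary quadratic-kernel SVM separates original from outlier. Its
  confidence is the logistic $1/(1+e^{-s})$ of the signed decision score
  toward the predicted side. The logistic map is our concrete choice for
  turning a signed decision distance into a probability; it is the
  simplest monotone map with value 0.5 on the boundary, and it is isolated
  in one function should a different normalisation be preferred.

Features enter the SVM as raw frequencies (they are already
length-normalised); the kernel is $(\gamma\, u\cdot v + 1)^2$ with
$\gamma = 4^k$ so that typical inner products of frequency vectors are
$O(1)$, and cost $C = 1$. Softmax-on-score-sums was chosen for the
cross-validation route because score sums are the natural one-vs-one
aggregate; the choice is isolated behind one function.

### Where a generic package ends and this package begins

The SVMs themselves are fitted by `e1071::svm` (libsvm), as any
practitioner would. Everything that makes the method what it is — FCGR
feature extraction, the two-route confidence machinery, per-pair Platt
calibration and coupling, the stopping-threshold algorithm, the descent
semantics and the evaluation metrics — is implemented in this package.

## Stopping thresholds (the STP rule)

For every (parent, child) pair, the cross-validated records whose
*predicted* child is that child determine one stopping threshold

$$T = \max(a, b) - v,$$

where $a$ is the smallest candidate threshold (grid $0, 0.01, \ldots, 1$)
at which the *constrained accuracy* — the accuracy among records retained
at that threshold — strictly exceeds the accuracy target (default 0.90),
$b$ is the mean confidence of the correctly classified records, and $v$ is
a variability allowance (default 0.05) that slackens the threshold against
sampling noise in the training confidences. Fallbacks are conservative:
$a = 1$ when no grid point attains the target and $b = 0$ when no record
is correct, so a pair with no usable evidence almost always yields
"uncertain". $T$ is not clamped: negative values simply mean "never stop
here", and values above $1 - v$ can only arise through $b$ and remain
reachable since confidences can equal 1. Records are grouped by
*predicted* child rather than true child because at classification time
only the prediction is known — the threshold gates exactly those events;
the grid, the target and $v$ are all configurable (`stp_config()`).

At classification time a query genome is featurised whole (pseudo-
concatenated, no fragment sampling) and descends from the root. At a
multi-child node it proceeds *iff* its confidence is greater than or equal
to $T(\text{parent}, \text{predicted child})$; at a single-child node iff
the novelty classifier predicts the original taxon. Stopping marks the
rank "uncertain" and all lower ranks "unattempted", so every path is a run
of `complete`, then at most one `uncertain`, then `unattempted` — an
invariant enforced by `validate_path()` on every constructed path. Ties
between equal posteriors resolve to the lexicographically first child.

A root whose corpus contains a single first-rank taxon (e.g. all-bacterial
training sets) is *collapsed* by default: the universally shared taxon is
assigned with confidence 1, because that rank offers no contrast to learn
from, and a novelty classifier trained against a random relabelling of its
own distribution would add noise, not protection. Set
`root_single_child = "novelty"` to train one anyway; mid-tree single-child
parents always get novelty classifiers.

## Evaluation metrics for partial paths

For rank index $j$ (root $= 0$), with $n$ eligible test genomes:

* $CA_g$ (constrained accuracy): correct-down-to-$j$ genomes / completely
  classified-at-$j$ genomes (NA when the denominator is 0);
* $AA_g$ (absolute accuracy): correct-down-to-$j$ genomes / $n$;
* $CR_g$ (complete classification rate): completely classified-at-$j$
  genomes / $n$;
* $WA_g$ (weighted accuracy): mean per-genome weight, where a genome
  correct down to $j$ has weight 1, a genome correct down to nothing below
  the root has weight 0, and otherwise, with $p$ the deepest rank with a
  correct classification down to it and $h$ the path length,
  $$w = \max\left\{0,\; \tfrac1j\left(p - \tfrac12(\min\{h, j\} - p)\right)\right\}.$$

"Correct down to $j$" requires a complete classification at $j$ *and*
agreement with the reference at every rank up to and including $j$. The
path length $h$ counts complete steps only by default; whether the
uncertain step's predicted taxon should count is genuinely ambiguous, so
`h_includes_uncertain = TRUE` switches the convention (it can only lower
weights of partially wrong paths). Genomes whose reference lineage is
truncated above a rank (e.g. unnamed species) are excluded from that
rank's denominators and reported in `n_excluded`.

## The synthetic benchmark generator

`synthetic_spec()` defines a corpus in which each species emits DNA from
an order-1 Markov model obtained by hierarchically perturbing a root
model: each child's transition matrix is the parent's mixed with fresh
Dirichlet noise scaled by the rank's divergence parameter, floored at 0.01
per entry (ergodicity) and renormalised. Order-1 emissions — rather than
i.i.d. bases — make $k \ge 2$ features informative without letting $k = 1$
trivially separate everything, emulating the oligonucleotide-signature
structure that compositional classifiers exploit. What the generator does
*not* emulate: real GC/codon structure, repeats, mobile elements,
contamination and uneven assembly quality; passing the benchmark therefore
demonstrates the machinery (feature extraction, calibration, thresholds,
descent, metrics) at realistic problem shapes, not classification accuracy
on real MAGs.

Defaults (`synthetic_spec()`): four ranks (Domain, Phylum, Genus,
Species), children 1/2/2/2 giving 8 species, genomes of 500 kb, one
genome per species, divergence 0.25 at every rank. A uniform per-rank
divergence still yields the taxonomic property that matters — similarity
decreases with tree distance, because perturbations accumulate along
paths. 0.25 makes sibling species clearly separable at 400 kb of sequence
while leaving a genuinely novel genus ambiguous between known genera —
the regime the stopping thresholds exist for. `novel_genus = TRUE` adds a
ninth species inside a new genus under the first phylum, branching off the
phylum's actual emission model; it is always excluded from training and
exercises the partial-classification path.

Representative-fragment sampling draws $n$ non-overlapping 100 kb
fragments via the gap construction: $n$ sorted offsets are drawn uniformly
from the slack $L - nf$ and shifted by multiples of $f$. This is exactly
uniform over sorted placements, $O(n)$, and degenerates gracefully to the
unique tiling when $L = nf$ (where naive rejection sampling would almost
never terminate). Genomes shorter than the requested fragments fall back
to $\lfloor L/f \rfloor$ fragments, then to the whole genome, then are
skipped with a typed condition — data are never silently inflated.
Class balancing (documented substitute for unpublished details of the
original procedure) downsamples majority children to at most 10× the
minority and upsamples tiny children to 5 items by cyclic duplication.

## Numerical and reproducibility choices

* All randomness flows from explicit seeds: corpus generation, fragment
  sampling, fold assignment, the novelty relabelling, and balancing;
  node-level seeds derive from the master seed plus the node's breadth-
  first position. Two runs with identical inputs and seeds produce
  byte-identical results and threshold files (checked in the test suite).
* Platt sigmoids are fitted by a damped Newton iteration on the
  regularised targets $(N_+ + 1)/(N_+ + 2)$ and $1/(N_- + 2)$, which stays
  finite even on perfectly separated cross-validation scores.
* Candidate-threshold grids produced by `seq()` are snapped to 10 decimals
  so that a confidence of exactly 0.70 is retained at candidate 0.70.
* Degenerate sequences (effective length $< k$) yield an all-zero flagged
  vector; in a batch they become per-genome error records rather than
  aborting the run.
* Cross-validation folds are stratified; fold counts are reduced (with a
  message) when a class has fewer items than folds.

## Problem sizes in the bundled experiments

The packaged benchmark trains on 8 species × 20 representative fragments
(4 × 100 kb each) at $k = 4$, classifies 5 fresh fragments per species
and 20 fragments of the held-out novel genus, and completes in roughly a
minute on one core; unit tests use 30 kb genomes and $k \in \{2,3\}$.
These sizes were chosen so the full distribution of behaviours (complete
paths, uncertain stops, novelty rejections) appears at desk scale.

## Known limitations

* Accuracy numbers on the synthetic benchmark say nothing quantitative
  about real MAG corpora; the generator's signal is cleaner than real
  compositional signal.
* The one-vs-one score-sum softmax and the normalised-averaging coupling
  are sensible conventions, not canonical; both are isolated behind single
  functions.
* Read-level classification, reverse-complement canonical k-mers, and
  resuming descent from a user-supplied starting rank are out of scope.
* Training keeps all node feature matrices in memory; corpora far beyond
  the benchmark scale would need an on-disk feature cache.
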