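# Per-parent-node training-set construction: contig filtering,
# representative-genomic-fragment sampling, replication and class
# balancing.

#' Sampling configuration for training-set construction
#'
#' @param min_contig_len contigs shorter than this are discarded (bp).
#' @param n_fragments non-overlapping fragments per representative genomic
#'   fragment.
#' @param fragment_len fragment length (bp).
#' @param n_replicates representative genomic fragments sampled per genome.
#' @param mode `"fragments"`: each training item is a pseudo-concatenation
#'   of `n_fragments` random non-overlapping fragments, drawn
#'   `n_replicates` times per genome.  `"contigs"`: each contig of at least
#'   `min_contig_len` bp is an item.
#' @return Object of class `sampling_config`.
#' @export
sampling_config <- function(min_contig_len = 5000L, n_fragments = 4L,
                            fragment_len = 100000L, n_replicates = 20L,
                            mode = c("fragments", "contigs")) {
  mode <- match.arg(mode)
  stopifnot(min_contig_len >= 1, n_fragments >= 1, fragment_len >= 1,
            n_replicates >= 1)
  structure(list(min_contig_len = as.integer(min_contig_len),
                 n_fragments = as.integer(n_fragments),
                 fragment_len = as.integer(fragment_len),
                 n_replicates = as.integer(n_replicates),
                 mode = mode),
            class = "sampling_config")
}

#' Discard short contigs
#'
#' Keeps contigs of length at least `min_len` bp ("shorter than" semantics:
#' a contig of exactly `min_len` is kept); order is preserved.
#'
#' @param contigs character vector of contig sequences.
#' @param min_len minimum length in bp.
#' @return Filtered character vector (possibly empty).
#' @export
filter_contigs <- function(contigs, min_len = 5000L) {
  contigs[nchar(contigs) >= min_len]
}

# Uniform non-overlapping interval starts via the gap construction: sample
# n sorted offsets in [0, L - n*f] and shift the i-th by (i-1)*f.  Exactly
# uniform over sorted placements, O(n), and forced (seed-independent) when
# L == n*f.  0-based half-open coordinates.
.sample_disjoint_starts <- function(L, n, f) {
  slack <- L - n * f
  stopifnot(slack >= 0)
  offs <- sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
  offs + (seq_len(n) - 1L) * f
}

#' Sample a representative genomic fragment
#'
#' Draws `n_fragments` pairwise non-overlapping substrings of
#' `fragment_len` bp uniformly at random from a (pseudo-concatenated)
#' genome and joins them with `"O"`.  If the genome is too short for the
#' requested fragments, `floor(L / fragment_len)` fragments are used; if
#' even one fragment does not fit, the whole genome is used when it is at
#' least `min_contig_len` bp, otherwise the genome is skipped (error of
#' class `hiertax_skip`).
#'
#' @param genome a single sequence string (already pseudo-concatenated if
#'   assembled from contigs).
#' @param cfg a [sampling_config()].
#' @return A single sequence string; the 0-based half-open source intervals
#'   are attached as attribute `"intervals"`.
#' @export
sample_representative_fragment <- function(genome, cfg = sampling_config()) {
  L <- nchar(genome)
  n <- min(cfg$n_fragments, L %/% cfg$fragment_len)
  if (n == 0L) {
    if (L >= cfg$min_contig_len)
      return(structure(genome, intervals = cbind(start = 0L, end = L)))
    stop(structure(class = c("hiertax_skip", "error", "condition"),
                   list(message = sprintf(
                     "genome of %d bp too short for one fragment", L),
                     call = sys.call())))
  }
  starts <- .sample_disjoint_starts(L, n, cfg$fragment_len)
  frags <- substring(genome, starts + 1L, starts + cfg$fragment_len)
  structure(pseudo_concatenate(frags),
            intervals = cbind(start = starts, end = starts + cfg$fragment_len))
}

#' Replicate representative-fragment sampling
#'
#' Repeats [sample_representative_fragment()] `n_replicates` times; each
#' replicate is an independent draw (non-overlap is enforced within, not
#' across, replicates).
#'
#' @param genome a single sequence string.
#' @param cfg a [sampling_config()].
#' @return List of sequence strings of length `cfg$n_replicates`.
#' @export
replicate_fragments <- function(genome, cfg = sampling_config()) {
  lapply(seq_len(cfg$n_replicates), function(i)
    sample_representative_fragment(genome, cfg))
}

#' Assemble the training set of one parent taxon
#'
#' Collects the feature vectors of all training items whose genome's
#' lineage passes through `parent`, labelled by the child of `parent` on
#' that lineage.  Genomes whose lineage is truncated above the child rank
#' are excluded (count reported via attribute `"n_excluded"`).
#'
#' @param taxonomy a `hiertax_taxonomy`.
#' @param parent_id node id of the parent taxon.
#' @param features numeric matrix of item feature vectors.
#' @param item_genome genome id per row of `features`.
#' @param lineages named list: genome id -> lineage.
#' @return Object of class `node_dataset`: list with `parent_id`, `x`
#'   (feature matrix), `labels` (child taxon per item) and `provenance`.
#' @export
assemble_node_dataset <- function(taxonomy, parent_id, features, item_genome,
                                  lineages) {
  kids <- taxonomy_children(taxonomy, parent_id)
  if (length(kids) == 0L)
    stop("node ", taxonomy_node_name(taxonomy, parent_id),
         " has no children", call. = FALSE)
  child_rank <- taxonomy$nodes$rank[match(kids[1], taxonomy$nodes$id)]
  parent_lineage <- taxonomy_lineage(taxonomy, parent_id)

  under_parent <- vapply(lineages, function(lin)
    length(lin) >= length(parent_lineage) &&
      identical(unname(lin[seq_along(parent_lineage)]),
                unname(parent_lineage)), logical(1))
  has_child_rank <- vapply(lineages, function(lin)
    child_rank %in% names(lin), logical(1))
  use <- under_parent & has_child_rank
  n_excluded <- sum(under_parent & !has_child_rank)

  keep_genomes <- names(lineages)[use]
  rows <- which(item_genome %in% keep_genomes)
  labels <- vapply(item_genome[rows], function(g)
    lineages[[g]][[child_rank]], character(1))
  structure(list(parent_id = parent_id,
                 x = features[rows, , drop = FALSE],
                 labels = unname(labels),
                 provenance = data.frame(genome = item_genome[rows],
                                         row = rows,
                                         stringsAsFactors = FALSE)),
            class = "node_dataset", n_excluded = n_excluded)
}

#' Balance child-class sizes of a node dataset
#'
#' Majority children are downsampled (uniformly, without replacement) to at
#' most `max_ratio` times the minority count; children with fewer than
#' `min_count` items are then upsampled to `min_count` by cyclic
#' duplication.  A child with at least one item never ends up empty.
#'
#' @param dataset a `node_dataset`.
#' @param max_ratio maximum majority/minority size ratio after
#'   downsampling.
#' @param min_count minimum items per child after upsampling.
#' @return A rebalanced `node_dataset`.
#' @export
balance_classes <- function(dataset, max_ratio = 10, min_count = 5L) {
  counts <- table(dataset$labels)
  cap <- max_ratio * min(counts)
  keep <- integer(0)
  for (cl in sort(names(counts))) {
    idx <- which(dataset$labels == cl)
    if (length(idx) > cap) idx <- sort(sample(idx, cap))
    if (length(idx) < min_count)
      idx <- idx[1L + (seq_len(min_count) - 1L) %% length(idx)]
    keep <- c(keep, idx)
  }
  structure(list(parent_id = dataset$parent_id,
                 x = dataset$x[keep, , drop = FALSE],
                 labels = dataset$labels[keep],
                 provenance = dataset$provenance[keep, , drop = FALSE]),
            class = "node_dataset")
}
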