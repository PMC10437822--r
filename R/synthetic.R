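# Deterministic synthetic corpora for benchmarking.
#
# Species emit DNA from order-1 Markov models obtained by hierarchically
# perturbing a root model: each child's transition matrix is the parent's,
# mixed with fresh Dirichlet noise scaled by a per-rank divergence.  Sibling
# taxa deep in the tree therefore share most of their compositional signal,
# while distant taxa differ more -- the oligonucleotide-signature structure
# that FCGR-based classification exploits.  Order-1 emissions (rather than
# i.i.d. bases) make k >= 2 features informative without letting k = 1
# trivially separate everything.

#' Specification of a synthetic benchmark corpus
#'
#' @param ranks ordered non-root rank names (3-7).
#' @param n_children children per node at each rank (recycled over ranks).
#'   The default `c(1, 2, 2, 2)` gives 1 domain, 2 phyla, 4 genera and 8
#'   species.
#' @param genome_len genome length in bp.
#' @param divergence per-rank perturbation magnitude in `[0, 1]` applied to
#'   transition probabilities at each split (recycled).  0 means children
#'   inherit the parent model unchanged.
#' @param n_genomes_per_species genomes emitted per species.
#' @param n_contigs number of contigs each genome is split into (1 = single
#'   sequence).
#' @param seed integer seed; every downstream draw is a pure function of
#'   (spec, seed).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(ranks = c("Domain", "Phylum", "Genus", "Species"),
                           n_children = c(1L, 2L, 2L, 2L),
                           genome_len = 500000L,
                           divergence = 0.25,
                           n_genomes_per_species = 1L,
                           n_contigs = 1L,
                           seed = 1L) {
  stopifnot(length(ranks) >= 3L, length(ranks) <= 7L, genome_len >= 1,
            n_genomes_per_species >= 1L, n_contigs >= 1L)
  n_children <- rep_len(as.integer(n_children), length(ranks))
  divergence <- rep_len(as.numeric(divergence), length(ranks))
  stopifnot(all(n_children >= 1L), all(divergence >= 0), all(divergence <= 1))
  structure(list(ranks = ranks, n_children = n_children,
                 genome_len = as.integer(genome_len),
                 divergence = divergence,
                 n_genomes_per_species = as.integer(n_genomes_per_species),
                 n_contigs = as.integer(n_contigs),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# new emission model = parent mixed with Dirichlet noise, floored at 0.01
# per entry for ergodicity, rows renormalised
.perturb_model <- function(parent, d) {
  m <- parent
  for (i in 1:4) {
    noise <- stats::rgamma(4, shape = 1)   # Dirichlet(1,1,1,1)
    noise <- noise / sum(noise)
    row <- (1 - d) * parent[i, ] + d * noise
    row <- pmax(row, 0.01)
    m[i, ] <- row / sum(row)
  }
  m
}

.stationary_dist <- function(trans) {
  v <- rep(0.25, 4)
  for (i in 1:50) v <- as.numeric(v %*% trans)
  v / sum(v)
}

#' Generate per-taxon emission models for a synthetic taxonomy
#'
#' Walks the taxonomy implied by `spec` depth-first; the root model is a
#' mildly jittered uniform matrix, and every child model is the parent's
#' perturbed by Dirichlet noise scaled by that rank's divergence.
#'
#' @param spec a [synthetic_spec()].
#' @param novel_genus also create one extra genus (single species) under the
#'   first phylum-level taxon, named with suffix `"novel"`, for held-out
#'   novelty experiments.
#' @return List with `lineages` (one named character vector per species),
#'   `models` (transition matrix per species, keyed by species name) and
#'   `taxa` (all taxon names by rank).
#' @export
generate_models <- function(spec, novel_genus = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  root <- matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                             c("A", "C", "G", "T")))
  root <- .perturb_model(root, 0.05)   # mild jitter off uniform
  nr <- length(spec$ranks)
  lineages <- list(); models <- list(); node_models <- list()

  recurse <- function(model, level, prefix, lineage) {
    node_models[[paste(lineage, collapse = ";")]] <<- model
    if (level > nr) {
      sp <- lineage[[nr]]
      lineages[[length(lineages) + 1L]] <<- lineage
      models[[sp]] <<- model
      return(invisible())
    }
    for (ci in seq_len(spec$n_children[level])) {
      nm <- sprintf("%s%d", paste0(substr(spec$ranks[level], 1, 1), prefix), ci)
      child <- .perturb_model(model, spec$divergence[level])
      lin <- c(lineage, stats::setNames(nm, spec$ranks[level]))
      recurse(child, level + 1L, sprintf("%s%d_", prefix, ci), lin)
    }
  }
  recurse(root, 1L, "", character(0))

  if (novel_genus) {
    # an extra genus-level taxon under the first child at every rank above
    # the genus; one species inside it; never included in training corpora
    genus_level <- nr - 1L
    lin <- lineages[[1]][seq_len(genus_level - 1L)]
    # branch off the actual ancestor model of the first lineage at the rank
    # just above the genus, with its own deterministic seed
    set.seed(spec$seed + 7919L)
    model <- node_models[[paste(lin, collapse = ";")]]
    gname <- sprintf("%snovel", substr(spec$ranks[genus_level], 1, 1))
    sname <- sprintf("%snovel1", substr(spec$ranks[nr], 1, 1))
    smodel <- .perturb_model(.perturb_model(model, spec$divergence[genus_level]),
                             spec$divergence[nr])
    nl <- c(lin, stats::setNames(gname, spec$ranks[genus_level]),
            stats::setNames(sname, spec$ranks[nr]))
    lineages[[length(lineages) + 1L]] <- nl
    models[[sname]] <- smodel
  }

  taxa <- lapply(stats::setNames(seq_len(nr), spec$ranks), function(lv)
    unique(vapply(lineages, `[[`, character(1), lv)))
  list(lineages = lineages, models = models, taxa = taxa)
}

#' Sample a genome from an emission model
#'
#' Order-1 Markov sampling started from the model's stationary
#' distribution; optionally split into contigs of roughly equal length.
#'
#' @param model 4x4 row-stochastic transition matrix.
#' @param length genome length in bp.
#' @param n_contigs number of contigs to split the genome into.
#' @return Character vector of contig sequences (length `n_contigs`).
#' @export
generate_genome <- function(model, length, n_contigs = 1L) {
  stopifnot(is.matrix(model), all(dim(model) == c(4L, 4L)),
            all(abs(rowSums(model) - 1) < 1e-8), length >= 1)
  u <- stats::runif(length)
  seq <- .markov_chain_cpp(model, .stationary_dist(model), u)
  if (n_contigs <= 1L) return(seq)
  cuts <- unique(round(seq_len(n_contigs - 1L) * length / n_contigs))
  starts <- c(1L, cuts + 1L); ends <- c(cuts, length)
  substring(seq, starts, ends)
}

#' Generate a complete synthetic corpus in memory
#'
#' @param spec a [synthetic_spec()].
#' @param hold_out character vector of genus- or species-level taxon names
#'   whose genomes are excluded from the training corpus (they appear only
#'   in the `heldout` slot and in `truth`).
#' @param novel_genus passed to [generate_models()]; when TRUE the extra
#'   novel genus is always held out.
#' @return List with `genomes` (named list: genome id -> character vector of
#'   contigs), `lineages` (training lineage per genome id), `heldout`
#'   (genomes excluded from training), `truth` (lineage per genome id for
#'   every genome incl. held-out), `models`, and `spec`.
#' @export
make_corpus <- function(spec, hold_out = character(0), novel_genus = FALSE) {
  gm <- generate_models(spec, novel_genus = novel_genus)
  nr <- length(spec$ranks)
  genus_rank <- spec$ranks[nr - 1L]
  species_rank <- spec$ranks[nr]
  if (novel_genus)
    hold_out <- union(hold_out, grep("novel$", gm$taxa[[genus_rank]],
                                     value = TRUE))
  unknown <- setdiff(hold_out,
                     c(gm$taxa[[genus_rank]], gm$taxa[[species_rank]]))
  if (length(unknown))
    stop("hold_out names unknown taxa: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  genomes <- list(); lineages <- list(); truth <- list(); heldout <- character(0)
  set.seed(spec$seed + 1L)
  for (lin in gm$lineages) {
    sp <- lin[[species_rank]]
    held <- sp %in% hold_out || lin[[genus_rank]] %in% hold_out
    for (g in seq_len(spec$n_genomes_per_species)) {
      gid <- sprintf("%s_g%d", sp, g)
      genomes[[gid]] <- generate_genome(gm$models[[sp]], spec$genome_len,
                                        spec$n_contigs)
      truth[[gid]] <- lin
      if (held) heldout <- c(heldout, gid) else lineages[[gid]] <- lin
    }
  }
  list(genomes = genomes, lineages = lineages,
       heldout = genomes[heldout], truth = truth,
       models = gm$models, spec = spec)
}

#' Write a synthetic corpus to disk as FASTA + TSV fixtures
#'
#' Produces the on-disk layout the trainer and the command-line interface
#' consume: `train/` FASTA per training genome, `heldout/` FASTA per
#' held-out genome, `lineages.tsv` (training genomes only), `truth.tsv`
#' (all genomes) and a `manifest.tsv` recording the spec and seed.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created).
#' @param hold_out,novel_genus see [make_corpus()].
#' @return The corpus list, invisibly, with `dir` attached.
#' @export
make_fixture <- function(spec, dir, hold_out = character(0),
                         novel_genus = FALSE) {
  corpus <- make_corpus(spec, hold_out = hold_out, novel_genus = novel_genus)
  dir.create(file.path(dir, "train"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "heldout"), recursive = TRUE, showWarnings = FALSE)
  for (gid in names(corpus$genomes)) {
    sub <- if (gid %in% names(corpus$heldout)) "heldout" else "train"
    write_fasta(stats::setNames(corpus$genomes[[gid]],
                                sprintf("%s_contig%d", gid,
                                        seq_along(corpus$genomes[[gid]]))),
                file.path(dir, sub, paste0(gid, ".fasta")))
  }
  write_lineage_tsv(corpus$lineages, file.path(dir, "lineages.tsv"))
  write_lineage_tsv(corpus$truth, file.path(dir, "truth.tsv"))
  manifest <- data.frame(
    key = c("seed", "ranks", "n_children", "genome_len", "divergence",
            "n_genomes_per_species", "n_contigs", "held_out"),
    value = c(spec$seed, paste(spec$ranks, collapse = ","),
              paste(spec$n_children, collapse = ","), spec$genome_len,
              paste(spec$divergence, collapse = ","),
              spec$n_genomes_per_species, spec$n_contigs,
              paste(names(corpus$heldout), collapse = ",")),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  attr(corpus, "dir") <- dir
  invisible(corpus)
}
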