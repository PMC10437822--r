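# A 3-rank taxonomy (2 children per node) and a stubbed node predictor let
# the descent semantics be tested in isolation from the SVMs.

stub_taxonomy <- function() {
  lins <- list()
  for (p in 1:2) for (c_ in 1:2) for (o in 1:2)
    lins[[length(lins) + 1]] <- c(Phylum = sprintf("P%d", p),
                                  Class = sprintf("C%d_%d", p, c_),
                                  Order = sprintf("O%d_%d_%d", p, c_, o))
  build_taxonomy(lins)
}

# run the descent with a fixed confidence per rank, always taking the
# lexicographically first child
descend_with <- function(tax, confs, thresholds) {
  i <- 0
  node_predict <- function(pid, kids) {
    i <<- i + 1
    kid_names <- sort(tax$nodes$name[match(kids, tax$nodes$id)])
    list(child = kid_names[1], confidence = confs[i], outlier = FALSE)
  }
  hiertax:::.descend(tax, node_predict, thresholds)
}

# threshold table assigning one T per rank to every (parent, child) pair
thresholds_for <- function(tax, T_by_rank) {
  rows <- list()
  for (pid in hiertax:::taxonomy_internal_ids(tax)) {
    kids <- hiertax:::taxonomy_children(tax, pid)
    if (length(kids) < 2) next
    rank <- tax$nodes$rank[match(kids[1], tax$nodes$id)]
    for (k in kids)
      rows[[length(rows) + 1]] <- data.frame(
        parent = tax$nodes$name[match(pid, tax$nodes$id)], parent_id = pid,
        child = tax$nodes$name[match(k, tax$nodes$id)],
        a = NA_real_, b = NA_real_, T = T_by_rank[[rank]], n_records = 0L)
  }
  do.call(rbind, rows)
}

# fast naive k-mer oracle: dictionary lookup of substring windows, with the
# dictionary built from the brute-force CGR cell mapping
oracle_kmer_dict <- function(k) {
  kmers <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)), 1,
                 paste, collapse = "")
  stats::setNames(vapply(kmers, oracle_cgr_index, integer(1)), kmers)
}

oracle_count_dict <- function(seq, k, dict) {
  s <- toupper(seq)
  n <- nchar(s)
  eff <- n - nchar(gsub("[^ON]", "", s))
  counts <- integer(4L^k)
  if (n >= k) {
    windows <- substring(s, 1:(n - k + 1L), k:n)
    ok <- !grepl("[ON]", windows)
    if (any(ok)) {
      idx <- dict[windows[ok]]
      counts <- tabulate(idx + 1L, nbins = 4L^k)
    }
  }
  list(counts = counts,
       values = if (eff > 0) counts / eff else counts * 0,
       effective_length = eff)
}
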