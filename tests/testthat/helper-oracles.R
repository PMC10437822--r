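# Independent oracles and small fixture builders shared across test files.

# Brute-force CGR cell of a k-mer: walk the symbols, first symbol selects
# the coarsest quadrant; corners A=(0,0), C=(0,1), G=(1,1), T=(1,0);
# row-major flat index y * 2^k + x.
oracle_cgr_index <- function(kmer) {
  corners <- list(A = c(0L, 0L), C = c(0L, 1L), G = c(1L, 1L), T = c(1L, 0L))
  x <- 0L; y <- 0L
  for (ch in strsplit(kmer, "")[[1]]) {
    x <- 2L * x + corners[[ch]][1]
    y <- 2L * y + corners[[ch]][2]
  }
  k <- nchar(kmer)
  as.integer(y * 2^k + x)
}

# Naive dictionary k-mer counter: enumerate windows one by one, skip any
# containing O or N, normalise by length excluding O/N.
oracle_count_kmers <- function(seq, k) {
  s <- strsplit(toupper(seq), "")[[1]]
  acgt <- s %in% c("A", "C", "G", "T")
  eff <- sum(acgt)
  counts <- integer(4L^k)
  if (length(s) >= k) {
    for (i in seq_len(length(s) - k + 1L)) {
      if (all(acgt[i:(i + k - 1L)])) {
        idx <- oracle_cgr_index(paste(s[i:(i + k - 1L)], collapse = ""))
        counts[idx + 1L] <- counts[idx + 1L] + 1L
      }
    }
  }
  list(counts = counts,
       values = if (eff > 0) counts / eff else counts * 0,
       effective_length = eff)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force stopping-threshold selection straight from the definitions.
oracle_pick_threshold <- function(records, grid, target, variability) {
  a <- 1
  for (t in grid) {
    keep <- records$confidence >= t
    if (any(keep) &&
        mean(records$predicted[keep] == records$truth[keep]) > target) {
      a <- t
      break
    }
  }
  correct <- records$predicted == records$truth
  b <- if (any(correct)) mean(records$confidence[correct]) else 0
  max(a, b) - variability
}

random_records <- function(n, classes = c("A", "B", "C")) {
  data.frame(truth = sample(classes, n, replace = TRUE),
             predicted = sample(classes, n, replace = TRUE),
             confidence = round(stats::runif(n), 3),
             stringsAsFactors = FALSE)
}

# A random classification path over `ranks` respecting the run structure,
# plus a random truth lineage over the same taxa.  Used by the metrics
# oracle tests.
random_path_and_truth <- function(id, ranks, n_taxa_per_rank = 3L) {
  nr <- length(ranks)
  taxa <- lapply(seq_len(nr), function(j)
    sprintf("%s_t%d", ranks[j], seq_len(n_taxa_per_rank)))
  stop_at <- sample(0:nr, 1)            # complete steps before stopping
  has_uncertain <- stop_at < nr && stats::runif(1) < 0.7
  status <- rep("unattempted", nr)
  if (stop_at > 0) status[1:stop_at] <- "complete"
  if (has_uncertain) status[stop_at + 1L] <- "uncertain"
  attempted <- status != "unattempted"
  taxon <- ifelse(attempted,
                  vapply(seq_len(nr), function(j) sample(taxa[[j]], 1),
                         character(1)),
                  NA_character_)
  conf <- ifelse(attempted, round(stats::runif(nr), 3), NA_real_)
  path <- classification_path(id, ranks, taxon, conf,
                              threshold = rep(NA_real_, nr), status = status)
  truth <- vapply(seq_len(nr), function(j) sample(taxa[[j]], 1), character(1))
  names(truth) <- ranks
  # half the time make the truth agree with the path prefix, so deep
  # correct classifications actually occur
  if (stats::runif(1) < 0.5 && stop_at > 0) {
    upto <- sample(stop_at, 1)
    truth[1:upto] <- taxon[1:upto]
  }
  list(path = path, truth = truth)
}

# Per-definition metrics recomputation, written independently of
# evaluate_paths: plain loops over the definitions of CA/AA/WA/CR.
oracle_metrics <- function(paths, truths, j) {
  n <- length(paths)
  complete <- correct <- logical(n)
  weights <- numeric(n)
  for (i in seq_len(n)) {
    st <- paths[[i]]$steps
    complete[i] <- st$status[j] == "complete"
    ok <- TRUE
    for (r in seq_len(j))
      ok <- ok && st$status[r] == "complete" &&
        identical(st$taxon[r], unname(truths[[i]][[st$rank[r]]]))
    correct[i] <- ok
    # deepest correct rank
    p <- 0L
    for (r in seq_len(nrow(st))) {
      good <- st$status[r] == "complete" &&
        identical(st$taxon[r], unname(truths[[i]][[st$rank[r]]]))
      if (good) p <- r else break
    }
    h <- sum(st$status == "complete")
    weights[i] <- if (p >= j) 1 else if (p == 0L) 0 else
      max(0, (p - (min(h, j) - p) / 2) / j)
  }
  list(CA = if (any(complete)) sum(correct) / sum(complete) else NA_real_,
       AA = mean(correct), WA = mean(weights), CR = mean(complete))
}

# Small, fast synthetic corpus for engine-level tests.
tiny_spec <- function(seed = 3L, ...) {
  synthetic_spec(genome_len = 30000L, seed = seed, ...)
}

tiny_config <- function(seed = 11L, k = 3L, ...) {
  hiertax_config(k = k,
                 sampling = sampling_config(n_fragments = 2L,
                                            fragment_len = 3000L,
                                            n_replicates = 6L,
                                            min_contig_len = 1000L),
                 seed = seed, ...)
}
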