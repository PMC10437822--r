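# FCGR k-mer frequency features.
#
# A DNA sequence is represented by its order-k Frequency Chaos Game
# Representation (FCGR_k): the 2^k x 2^k grid of k-mer counts flattened
# row-major into a vector of length 4^k.  Windows containing the contig
# separator "O" or the ambiguity symbol "N" are skipped, and counts are
# normalised by the sequence length excluding those symbols, so that
# sequences of different lengths are comparable.

# CGR corner convention (fixed across the package; any fixed bijection is
# classification-equivalent):
#   A = (0,0), C = (0,1), G = (1,1), T = (1,0)
# The first symbol of a k-mer selects the coarsest quadrant, the most recent
# (last) symbol the finest subdivision.  Cell (row = y, col = x) maps to the
# 0-based flat index y * 2^k + x.
.cgr_x <- c(A = 0L, C = 0L, G = 1L, T = 1L)
.cgr_y <- c(A = 0L, C = 1L, G = 1L, T = 0L)

#' k-mer specification for FCGR features
#'
#' Bundles the k-mer length with the fixed DNA alphabet and the symbols
#' excluded from counting: `O` (the pseudo-concatenation separator) and `N`
#' (ambiguous base).
#'
#' @param k k-mer length, an integer between 1 and 12.  The feature
#'   dimension is `4^k`; the package default for genome-scale classification
#'   is `k = 7`.
#' @return An object of class `kmer_spec`.
#' @export
kmer_spec <- function(k = 7L) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > 12L)
    stop("'k' must be a single integer in [1, 12]", call. = FALSE)
  structure(list(k = k, alphabet = c("A", "C", "G", "T"),
                 excluded = c("O", "N")),
            class = "kmer_spec")
}

#' @export
print.kmer_spec <- function(x, ...) {
  cat(sprintf("FCGR k-mer spec: k = %d (%d features), excluded symbols: %s\n",
              x$k, 4L^x$k, paste(x$excluded, collapse = ", ")))
  invisible(x)
}

#' Map k-mers to FCGR cell indices
#'
#' Bijection from k-mers over `{A,C,G,T}` to `[0, 4^k)` following the chaos
#' game representation with corners A=(0,0), C=(0,1), G=(1,1), T=(1,0) and
#' the most recent symbol giving the finest subdivision; cells are flattened
#' row-major (by the y coordinate).
#'
#' @param kmer character vector of k-mers, all of the same length.
#' @return Integer vector of 0-based indices in `[0, 4^k)`.
#' @export
kmer_index <- function(kmer) {
  if (length(kmer) == 0L) return(integer(0))
  k <- unique(nchar(kmer))
  if (length(k) != 1L)
    stop("all k-mers must have the same length", call. = FALSE)
  chars <- strsplit(kmer, "", fixed = TRUE)
  vapply(chars, function(s) {
    if (any(!s %in% names(.cgr_x)))
      stop("invalid character in k-mer: ",
           paste(setdiff(s, names(.cgr_x)), collapse = ","), call. = FALSE)
    w <- 2L^((k - 1L):0L)          # first symbol -> coarsest bit
    x <- sum(.cgr_x[s] * w)
    y <- sum(.cgr_y[s] * w)
    as.integer(y * 2L^k + x)
  }, integer(1))
}

#' Join contigs with the separator symbol "O"
#'
#' Pseudo-concatenation: contigs are joined by a single `"O"` so that no
#' artificial k-mers spanning contig junctions are ever counted.
#'
#' @param contigs non-empty character vector of DNA strings.
#' @return A single string of length `sum(nchar(contigs)) + length(contigs) - 1`.
#' @export
pseudo_concatenate <- function(contigs) {
  if (length(contigs) == 0L)
    stop("'contigs' must be non-empty", call. = FALSE)
  paste(contigs, collapse = "O")
}

#' Normalise a DNA string
#'
#' Uppercases and maps every character outside `{A,C,G,T,O,N}` (e.g. other
#' IUPAC ambiguity codes) to `N`.  The number of replaced characters is
#' attached as attribute `"n_mapped_to_N"`.
#'
#' @param seq a single DNA string.
#' @return The normalised string.
#' @export
normalize_seq <- function(seq) {
  s <- toupper(seq)
  bad <- gsub("[ACGTON]", "", s)
  n_bad <- nchar(bad)
  if (n_bad > 0L) s <- gsub("[^ACGTON]", "N", s)
  structure(s, n_mapped_to_N = n_bad)
}

# integer codes per character: 0..3 for ACGT, NA for O/N (and anything else)
.seq_codes <- function(seq) {
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  lut[utf8ToInt(seq) + 1L]
}

# per-base CGR bits, indexed by code 0..3 (A,C,G,T)
.cgr_x_code <- c(0L, 0L, 1L, 1L)
.cgr_y_code <- c(0L, 1L, 1L, 0L)

#' Count k-mers of a sequence into an FCGR frequency vector
#'
#' Every window of length `k` over `{A,C,G,T}` is counted at its CGR cell;
#' windows containing `O` or `N` are skipped.  Counts are normalised by the
#' effective length (sequence length excluding `O` and `N`), not by the
#' number of windows.
#'
#' @param seq a single DNA string (will be normalised; see
#'   [normalize_seq()]).
#' @param spec a [kmer_spec()] or an integer `k`.
#' @return An object of class `fcgr`: list with `values` (length `4^k`
#'   frequency vector), `counts`, `effective_length`, `kmer_total`, `k`, and
#'   `degenerate` (TRUE when `effective_length < k`, in which case `values`
#'   is all zeros).
#' @export
count_kmers <- function(seq, spec = kmer_spec(7L)) {
  if (!inherits(spec, "kmer_spec")) spec <- kmer_spec(spec)
  k <- spec$k
  s <- normalize_seq(seq)
  codes <- .seq_codes(as.character(s))
  n <- length(codes)
  ok <- !is.na(codes)
  eff_len <- sum(ok)
  dim_out <- 4L^k

  if (eff_len < k || n < k) {
    return(structure(list(values = numeric(dim_out),
                          counts = integer(dim_out),
                          effective_length = eff_len, kmer_total = 0L,
                          k = k, degenerate = TRUE),
                     class = "fcgr"))
  }

  nw <- n - k + 1L
  x <- integer(nw); y <- integer(nw); valid <- rep(TRUE, nw)
  codes0 <- codes
  codes0[!ok] <- 0L                     # placeholder, masked via `valid`
  for (t in seq_len(k)) {
    idx <- t:(t + nw - 1L)
    w <- 2L^(k - t)
    x <- x + .cgr_x_code[codes0[idx] + 1L] * w
    y <- y + .cgr_y_code[codes0[idx] + 1L] * w
    valid <- valid & ok[idx]
  }
  flat <- y[valid] * 2L^k + x[valid]
  counts <- tabulate(flat + 1L, nbins = dim_out)
  structure(list(values = counts / eff_len, counts = counts,
                 effective_length = eff_len, kmer_total = sum(counts),
                 k = k, degenerate = FALSE),
            class = "fcgr")
}

#' @export
print.fcgr <- function(x, ...) {
  cat(sprintf("FCGR_%d vector: %d cells, %d k-mers over effective length %d%s\n",
              x$k, length(x$values), x$kmer_total, x$effective_length,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' FCGR feature matrix for a set of sequences
#'
#' @param seqs character vector (or list) of DNA strings.
#' @param spec a [kmer_spec()] or integer `k`.
#' @return Numeric matrix, one row per sequence, `4^k` columns named by
#'   k-mer for `k <= 6`.  Attribute `"degenerate"` flags rows with
#'   effective length below `k` (all-zero rows).
#' @export
fcgr_matrix <- function(seqs, spec = kmer_spec(7L)) {
  if (!inherits(spec, "kmer_spec")) spec <- kmer_spec(spec)
  vecs <- lapply(seqs, count_kmers, spec = spec)
  m <- do.call(rbind, lapply(vecs, `[[`, "values"))
  rownames(m) <- names(seqs)
  if (spec$k <= 6L) {
    kmers <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), spec$k),
                               stringsAsFactors = FALSE)[, spec$k:1, drop = FALSE],
                   1L, paste, collapse = "")
    cn <- character(4L^spec$k)
    cn[kmer_index(kmers) + 1L] <- kmers
    colnames(m) <- cn
  }
  attr(m, "degenerate") <- unname(vapply(vecs, `[[`, logical(1),
                                         "degenerate"))
  attr(m, "k") <- spec$k
  m
}
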