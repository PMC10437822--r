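# Genome-level evaluation metrics for (partial) classification paths.
#
# At each non-root rank tr_j:
#   CA_g: correct-down-to-tr_j genomes / completely-classified-at-tr_j genomes
#   AA_g: correct-down-to-tr_j genomes / all genomes
#   WA_g: mean per-genome weight, where a genome correct down to tr_j gets
#         weight 1, a genome correct down to nothing below the root gets 0,
#         and a genome correct down to tr_p (0 < p < j) gets
#         max{0, (1/j)(p - (min{h, j} - p)/2)}, h its path length
#   CR_g: completely-classified-at-tr_j genomes / all genomes
# Genomes whose reference lineage is truncated above tr_j (e.g. unnamed
# species) are excluded from that rank's denominators.

#' Is a path correct down to a rank?
#'
#' TRUE iff the path is complete at rank index `j` and the predicted taxon
#' equals the reference taxon at every rank up to and including `j`.  By
#' definition every genome is correct down to the root (`j = 0`).
#'
#' @param path a `hiertax_path`.
#' @param truth reference lineage (named character vector, rank -> taxon).
#' @param j rank index (0 = root, 1 = first non-root rank, ...).
#' @return Logical.
#' @export
correct_down_to <- function(path, truth, j) {
  if (j == 0L) return(TRUE)
  st <- path$steps
  if (j > nrow(st)) return(FALSE)
  for (r in seq_len(j)) {
    if (st$status[r] != "complete") return(FALSE)
    i <- match(st$rank[r], names(truth))
    if (is.na(i) || is.na(truth[[i]])) return(FALSE)
    if (!identical(st$taxon[r], unname(truth[[i]]))) return(FALSE)
  }
  TRUE
}

# deepest rank index with correct classification down to it
.deepest_correct <- function(path, truth) {
  p <- 0L
  for (j in seq_len(nrow(path$steps))) {
    if (correct_down_to(path, truth, j)) p <- j else break
  }
  p
}

#' Weight of a genome's classification at a rank
#'
#' `1` when the genome is correct down to rank `j` (`p >= j`), `0` when it
#' is correct down to nothing below the root (`p = 0`), otherwise
#' `max(0, (1/j) * (p - (min(h, j) - p) / 2))`: correct partial depth earns
#' credit, predicted-but-wrong ranks after `p` are penalised at half
#' weight, and the result is clamped at 0.
#'
#' @param j rank index (>= 1).
#' @param p deepest rank index with a correct classification down to it.
#' @param h path length (number of ranks predicted).
#' @return Weight in `[0, 1]`.
#' @export
genome_weight <- function(j, p, h) {
  stopifnot(p >= 0, h >= 0, p <= h)
  if (j < 1) stop("'j' must be >= 1", call. = FALSE)
  if (p >= j) return(1)
  if (p == 0L) return(0)
  max(0, (p - (min(h, j) - p) / 2) / j)
}

#' Evaluate classification paths against reference lineages
#'
#' Computes CA_g, AA_g, WA_g and CR_g at every rank of the paths' rank
#' list.  Genomes whose reference lineage is truncated above a rank are
#' excluded from that rank's denominators (counted in `n_excluded`);
#' CA_g is `NA` at ranks where no genome is completely classified.
#'
#' @param paths list of `hiertax_path` objects.
#' @param truth named list: genome id -> reference lineage.
#' @param h_includes_uncertain should the path length `h` count the
#'   uncertain step's predicted taxon as well as the complete steps?
#' @return Object of class `hiertax_eval`: a data frame with one row per
#'   rank (`rank`, `CA`, `AA`, `WA`, `CR`, `n_complete`, `n_correct`,
#'   `n_total`, `n_excluded`) plus per-genome `records` (`genome_id`, `p`,
#'   `h`) as an attribute.
#' @export
evaluate_paths <- function(paths, truth, h_includes_uncertain = FALSE) {
  if (inherits(paths, "hiertax_paths")) paths <- unclass(paths)
  err <- vapply(paths, inherits, logical(1), "hiertax_error")
  if (any(err)) {
    warning(sum(err), " error record(s) excluded from evaluation")
    paths <- paths[!err]
  }
  stopifnot(length(paths) > 0L)
  ranks <- paths[[1]]$steps$rank
  recs <- lapply(paths, function(p) {
    tr <- truth[[p$genome_id]]
    if (is.null(tr))
      stop("no reference lineage for genome '", p$genome_id, "'",
           call. = FALSE)
    list(path = p, truth = tr,
         p = .deepest_correct(p, tr),
         h = path_length(p, include_uncertain = h_includes_uncertain))
  })
  out <- data.frame(rank = ranks, CA = NA_real_, AA = NA_real_,
                    WA = NA_real_, CR = NA_real_, n_complete = 0L,
                    n_correct = 0L, n_total = 0L, n_excluded = 0L,
                    stringsAsFactors = FALSE)
  for (j in seq_along(ranks)) {
    defined <- vapply(recs, function(r)
      ranks[j] %in% names(r$truth), logical(1))
    use <- recs[defined]
    n <- length(use)
    out$n_excluded[j] <- length(recs) - n
    out$n_total[j] <- n
    if (n == 0L) next
    complete <- vapply(use, function(r)
      status_at_rank(r$path, ranks[j]) == "complete", logical(1))
    correct <- vapply(use, function(r) r$p >= j, logical(1))
    weights <- vapply(use, function(r) genome_weight(j, r$p, r$h), numeric(1))
    out$n_complete[j] <- sum(complete)
    out$n_correct[j] <- sum(correct)
    out$CA[j] <- if (any(complete)) sum(correct) / sum(complete) else NA_real_
    out$AA[j] <- mean(correct)
    out$WA[j] <- mean(weights)
    out$CR[j] <- mean(complete)
  }
  structure(out, class = c("hiertax_eval", "data.frame"),
            records = data.frame(
              genome_id = vapply(recs, function(r) r$path$genome_id,
                                 character(1)),
              p = vapply(recs, `[[`, integer(1), "p"),
              h = vapply(recs, `[[`, integer(1), "h")))
}

#' @export
print.hiertax_eval <- function(x, digits = 4, ...) {
  cat("Per-rank classification performance (genome level):\n")
  df <- as.data.frame(x)
  df$CA <- round(df$CA, digits); df$AA <- round(df$AA, digits)
  df$WA <- round(df$WA, digits); df$CR <- round(df$CR, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to TSV
#'
#' @param report a `hiertax_eval`.
#' @param path output file.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
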