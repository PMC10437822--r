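# Taxonomy, lineages, and classification-path records.
#
# A taxonomy is a rooted tree of named taxa; every internal node is a
# "parent taxon" that owns one local classifier.  A genome's classification
# path records, per non-root rank, one of three mutually exclusive
# statuses: complete, uncertain, or unattempted.

.gtdb_prefixes <- c(d = "Domain", p = "Phylum", c = "Class", o = "Order",
                    f = "Family", g = "Genus", s = "Species")

#' The canonical GTDB rank names
#'
#' @return Character vector `Domain, Phylum, Class, Order, Family, Genus,
#'   Species`.
#' @export
gtdb_ranks <- function() unname(.gtdb_prefixes)

#' Parse a GTDB-style lineage string
#'
#' Parses `"d__Bacteria;p__Bacteroidota;...;s__..."` into a named character
#' vector of taxon names (names are rank labels).  Trailing ranks may be
#' empty (`"s__"`) or absent, yielding a truncated lineage; ranks may be
#' skipped (e.g. a 4-rank taxonomy using `d__/p__/g__/s__`) as long as the
#' prefix order is respected.
#'
#' @param line a single lineage string.
#' @return Named character vector of taxon names, one element per non-empty
#'   rank, in rank order.
#' @export
parse_gtdb_lineage <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  toks <- strsplit(trimws(line), ";", fixed = TRUE)[[1]]
  toks <- trimws(toks)
  out <- character(0)
  last_idx <- 0L
  truncated <- FALSE
  for (tok in toks) {
    if (!grepl("^[a-z]__", tok))
      stop("malformed lineage token: '", tok, "'", call. = FALSE)
    pfx <- substr(tok, 1L, 1L)
    idx <- match(pfx, names(.gtdb_prefixes))
    if (is.na(idx))
      stop("unknown rank prefix in token: '", tok, "'", call. = FALSE)
    if (idx <= last_idx)
      stop("rank prefixes out of order at token: '", tok, "'", call. = FALSE)
    last_idx <- idx
    name <- substr(tok, 4L, nchar(tok))
    if (nzchar(name)) {
      if (truncated)
        stop("named rank after an empty rank at token: '", tok, "'",
             call. = FALSE)
      out[.gtdb_prefixes[[idx]]] <- name
    } else {
      truncated <- TRUE   # empty suffix rank: lineage truncated here
    }
  }
  out
}

#' Serialise a lineage back to a GTDB-style string
#'
#' Inverse of [parse_gtdb_lineage()] for lineages over the canonical GTDB
#' ranks: `parse -> serialize -> parse` round-trips byte-identically.
#'
#' @param lineage named character vector as returned by
#'   [parse_gtdb_lineage()].
#' @return A single lineage string.
#' @export
format_gtdb_lineage <- function(lineage) {
  pfx <- names(.gtdb_prefixes)[match(names(lineage), .gtdb_prefixes)]
  if (anyNA(pfx)) stop("unknown rank name in lineage", call. = FALSE)
  paste0(pfx, "__", unname(lineage), collapse = ";")
}

#' Build a taxonomy tree from lineages
#'
#' Constructs the rooted tree containing every (rank, taxon) of the input
#' lineages.  Taxon names are scoped by their full parent path; in strict
#' mode (default) the same (rank, name) appearing under two different
#' parents is a consistency error.
#'
#' @param lineages list of named character vectors (see
#'   [parse_gtdb_lineage()]).
#' @param ranks ordered character vector of non-root rank names; defaults to
#'   the union of ranks seen in `lineages`, ordered as in [gtdb_ranks()].
#' @param strict reject duplicate (rank, name) under different parents?
#' @return Object of class `hiertax_taxonomy`: a node table (`id`, `name`,
#'   `rank`, `parent`) with the root at id 1, plus the ordered rank list.
#' @export
build_taxonomy <- function(lineages, ranks = NULL, strict = TRUE) {
  if (length(lineages) == 0L) stop("no lineages supplied", call. = FALSE)
  if (is.null(ranks)) {
    seen <- unique(unlist(lapply(lineages, names)))
    ranks <- c(gtdb_ranks()[gtdb_ranks() %in% seen], setdiff(seen, gtdb_ranks()))
  }
  nodes <- data.frame(id = 1L, name = "Root", rank = "root", parent = NA_integer_,
                      stringsAsFactors = FALSE)
  key2id <- new.env(parent = emptyenv())   # "rank\rname\rparent_id" -> id
  rn2id <- new.env(parent = emptyenv())    # "rank\rname" -> id (strict check)
  for (lin in lineages) {
    lin <- lin[names(lin) %in% ranks]
    lin <- lin[order(match(names(lin), ranks))]
    if (!identical(names(lin), ranks[seq_along(lin)]))
      stop("lineage skips ranks present in the taxonomy rank list: ",
           paste(names(lin), collapse = ";"), call. = FALSE)
    parent <- 1L
    for (j in seq_along(lin)) {
      rk <- names(lin)[j]; nm <- lin[[j]]
      key <- paste(rk, nm, parent, sep = "\r")
      id <- key2id[[key]]
      if (is.null(id)) {
        rnkey <- paste(rk, nm, sep = "\r")
        prev <- rn2id[[rnkey]]
        if (strict && !is.null(prev))
          stop("taxon '", nm, "' at rank ", rk,
               " appears under two different parents", call. = FALSE)
        id <- nrow(nodes) + 1L
        nodes[id, ] <- list(id, nm, rk, parent)
        key2id[[key]] <- id
        if (is.null(prev)) rn2id[[rnkey]] <- id
      }
      parent <- id
    }
  }
  structure(list(nodes = nodes, ranks = ranks), class = "hiertax_taxonomy")
}

#' @export
print.hiertax_taxonomy <- function(x, ...) {
  cat(sprintf("Taxonomy: %d taxa over %d ranks (%s)\n",
              nrow(x$nodes) - 1L, length(x$ranks),
              paste(x$ranks, collapse = " > ")))
  tab <- table(factor(x$nodes$rank, levels = x$ranks))
  for (r in x$ranks) cat(sprintf("  %-8s %d\n", r, tab[[r]]))
  invisible(x)
}

taxonomy_children <- function(tax, id) {
  tax$nodes$id[!is.na(tax$nodes$parent) & tax$nodes$parent == id]
}

taxonomy_node_name <- function(tax, id) tax$nodes$name[match(id, tax$nodes$id)]

# id of the child of `parent_id` named `name` (NA if absent)
taxonomy_child_id <- function(tax, parent_id, name) {
  kids <- taxonomy_children(tax, parent_id)
  kids[match(name, tax$nodes$name[match(kids, tax$nodes$id)])]
}

# full lineage (named vector rank -> name) of a node
taxonomy_lineage <- function(tax, id) {
  out <- character(0)
  while (!is.na(id) && id != 1L) {
    i <- match(id, tax$nodes$id)
    out <- c(stats::setNames(tax$nodes$name[i], tax$nodes$rank[i]), out)
    id <- tax$nodes$parent[i]
  }
  out
}

# internal node ids (>= 1 child), in breadth-first order from the root
taxonomy_internal_ids <- function(tax) {
  ids <- integer(0); queue <- 1L
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    kids <- taxonomy_children(tax, id)
    if (length(kids)) ids <- c(ids, id)
    queue <- c(queue, kids)
  }
  ids
}

#' Construct a classification path
#'
#' A classification path records, for one genome and every non-root rank,
#' the predicted taxon, its confidence, the stopping threshold applied (NA
#' for single-child/novelty steps) and a status.  Statuses along a path are
#' always a run of `complete`, then at most one `uncertain`, then only
#' `unattempted`.
#'
#' @param genome_id genome identifier.
#' @param ranks ordered character vector of non-root rank names.
#' @param taxon,confidence,threshold,status parallel vectors over `ranks`
#'   (`taxon` NA and `confidence` NA where unattempted).
#' @return Object of class `hiertax_path` with a `steps` data frame.
#' @export
classification_path <- function(genome_id, ranks, taxon, confidence,
                                threshold, status) {
  steps <- data.frame(rank = ranks, taxon = taxon,
                      confidence = confidence, threshold = threshold,
                      status = status, stringsAsFactors = FALSE)
  p <- structure(list(genome_id = genome_id, steps = steps),
                 class = "hiertax_path")
  validate_path(p)
  p
}

#' Validate the run structure of a classification path
#'
#' Checks the path-shape invariant: statuses are `complete* uncertain?
#' unattempted*`, unattempted steps carry no confidence, and an uncertain
#' multi-child step has confidence strictly below its threshold.
#'
#' @param path a `hiertax_path`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_path <- function(path) {
  st <- path$steps$status
  if (!all(st %in% c("complete", "uncertain", "unattempted")))
    stop("unknown status in path", call. = FALSE)
  runs <- rle(st)$values
  legal <- list(character(0), "complete", "uncertain", "unattempted",
                c("complete", "uncertain"), c("complete", "unattempted"),
                c("uncertain", "unattempted"),
                c("complete", "uncertain", "unattempted"))
  if (!any(vapply(legal, identical, logical(1), runs)))
    stop("path violates complete*/uncertain?/unattempted* structure",
         call. = FALSE)
  if (any(st == "unattempted" & !is.na(path$steps$confidence)))
    stop("unattempted step carries a confidence", call. = FALSE)
  unc <- which(st == "uncertain")
  if (length(unc) == 1L) {
    thr <- path$steps$threshold[unc]; cf <- path$steps$confidence[unc]
    if (!is.na(thr) && !is.na(cf) && cf >= thr)
      stop("uncertain multi-child step with confidence >= threshold",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Status of a path at a given rank
#'
#' @param path a `hiertax_path`.
#' @param rank a non-root rank name present in the path.
#' @return `"complete"`, `"uncertain"` or `"unattempted"`.
#' @export
status_at_rank <- function(path, rank) {
  i <- match(rank, path$steps$rank)
  if (is.na(i)) stop("rank '", rank, "' not in path", call. = FALSE)
  path$steps$status[i]
}

#' Length of a classification path
#'
#' The number of ranks predicted before descent stopped.  By default this
#' counts the complete steps only; `include_uncertain = TRUE` also counts
#' the uncertain step's predicted taxon.
#'
#' @param path a `hiertax_path`.
#' @param include_uncertain count the uncertain step too?
#' @return Integer path length `h`.
#' @export
path_length <- function(path, include_uncertain = FALSE) {
  h <- sum(path$steps$status == "complete")
  if (include_uncertain) h <- h + sum(path$steps$status == "uncertain")
  as.integer(h)
}

#' @export
print.hiertax_path <- function(x, ...) {
  cat(format_path(x), "\n")
  invisible(x)
}

#' Render a classification path in arrow notation
#'
#' Human-readable rendering, e.g.
#' `"Domain Bacteria (confidence 99%) -> Phylum X (confidence 90%) (uncertain)"`.
#'
#' @param path a `hiertax_path`.
#' @return A single string.
#' @export
format_path <- function(path) {
  st <- path$steps
  keep <- st$status != "unattempted"
  if (!any(keep)) return(sprintf("%s: unclassified", path$genome_id))
  parts <- vapply(which(keep), function(i) {
    s <- sprintf("%s %s (confidence %.0f%%)", st$rank[i], st$taxon[i],
                 100 * st$confidence[i])
    if (st$status[i] == "uncertain") s <- paste(s, "(uncertain)")
    s
  }, character(1))
  sprintf("%s: %s", path$genome_id, paste(parts, collapse = " -> "))
}
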