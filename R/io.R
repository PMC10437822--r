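# Readers and writers shared by all modules: FASTA, lineage TSV, results
# TSV, threshold TSV and model archives.  All writers are deterministic
# given their inputs; readers reject rather than guess on schema mismatch.

.results_schema <- "hiertax_results_v1"
.model_format_version <- 1L

#' Read a FASTA file
#'
#' Plain or gzip-compressed, multi-record, CRLF-tolerant.  Sequences are
#' uppercased; IUPAC codes outside `{A,C,G,T,N}` are mapped to `N`
#' downstream by [normalize_seq()].
#'
#' @param path file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("failed to parse FASTA '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Read a directory of FASTA genomes
#'
#' Each `*.fasta`/`*.fa`/`*.fna` file (optionally gzipped) is one genome;
#' the genome id is the file name without extension, its contigs are the
#' records.
#'
#' @param dir directory path.
#' @return Named list: genome id -> character vector of contig sequences.
#' @export
read_fasta_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(fasta|fa|fna)(\\.gz)?$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no FASTA files in ", dir, call. = FALSE)
  out <- lapply(files, read_fasta)
  names(out) <- sub("\\.(fasta|fa|fna)(\\.gz)?$", "", basename(files))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a lineage TSV
#'
#' Two tab-separated columns: genome id and GTDB-style lineage string.  A
#' header line is optional (detected by the second field not matching a
#' lineage).
#'
#' @param path file path.
#' @return Named list: genome id -> parsed lineage (named character vector).
#' @export
read_lineage_tsv <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(raw) < 2L) stop("lineage TSV needs two columns: ", path,
                           call. = FALSE)
  if (!grepl("^[a-z]__", raw[1, 2])) raw <- raw[-1, , drop = FALSE]  # header
  out <- lapply(raw[[2]], parse_gtdb_lineage)
  names(out) <- raw[[1]]
  out
}

#' Write a lineage TSV
#'
#' @param lineages named list of lineages (named character vectors).
#' @param path output path.
#' @export
write_lineage_tsv <- function(lineages, path) {
  lines <- vapply(lineages, format_gtdb_lineage, character(1))
  utils::write.table(data.frame(genome_id = names(lineages), lineage = lines,
                                stringsAsFactors = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write classification paths to a results TSV
#'
#' One row per genome; per rank three columns `<rank>.taxon`,
#' `<rank>.confidence` (4 decimals) and `<rank>.status`.  Unattempted cells
#' are empty.  The first line is a schema-version comment.
#'
#' @param paths list of `hiertax_path` objects with identical rank lists.
#' @param path output file.
#' @export
write_results_tsv <- function(paths, path) {
  stopifnot(length(paths) > 0L)
  ranks <- paths[[1]]$steps$rank
  for (p in paths)
    if (!identical(p$steps$rank, ranks))
      stop("paths have heterogeneous rank lists", call. = FALSE)
  rows <- lapply(paths, function(p) {
    cells <- unlist(lapply(seq_along(ranks), function(i) {
      s <- p$steps[i, ]
      if (s$status == "unattempted") c("", "", "unattempted")
      else c(s$taxon, sprintf("%.4f", s$confidence), s$status)
    }))
    c(p$genome_id, cells)
  })
  header <- c("genome_id",
              unlist(lapply(ranks, function(r)
                paste(r, c("taxon", "confidence", "status"), sep = "."))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", .results_schema), con)
  writeLines(paste(header, collapse = "\t"), con)
  for (r in rows) writeLines(paste(r, collapse = "\t"), con)
  invisible(path)
}

#' Read a results TSV back into classification paths
#'
#' @param path file written by [write_results_tsv()].
#' @return List of `hiertax_path` objects.
#' @export
read_results_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, paste0("#", .results_schema)))
    stop("unrecognised results schema in ", path, " (expected ",
         .results_schema, ")", call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character")
  ranks <- unique(sub("\\.(taxon|confidence|status)$", "",
                      colnames(tab)[-1]))
  lapply(seq_len(nrow(tab)), function(i) {
    taxon <- conf <- rep(NA_character_, length(ranks))
    status <- character(length(ranks))
    for (j in seq_along(ranks)) {
      taxon[j] <- tab[i, paste0(ranks[j], ".taxon")]
      conf[j] <- tab[i, paste0(ranks[j], ".confidence")]
      status[j] <- tab[i, paste0(ranks[j], ".status")]
    }
    empty <- !nzchar(taxon)
    classification_path(tab[i, 1], ranks,
                        taxon = ifelse(empty, NA_character_, taxon),
                        confidence = ifelse(nzchar(conf), as.numeric(conf), NA),
                        threshold = rep(NA_real_, length(ranks)),
                        status = status)
  })
}

#' Write a stopping-threshold table to TSV
#'
#' Columns `parent`, `child`, `a` (accuracy-constrained grid minimum), `b`
#' (mean confidence of correct records), `T` (threshold), `n_records` --
#' every threshold is auditable.
#'
#' @param table data frame as produced by [build_threshold_table()].
#' @param path output file.
#' @export
write_threshold_tsv <- function(table, path) {
  tab <- table
  for (cl in c("a", "b", "T"))
    tab[[cl]] <- sprintf("%.6f", tab[[cl]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stopping-threshold TSV
#'
#' @param path file written by [write_threshold_tsv()].
#' @return Data frame with numeric `a`, `b`, `T` columns.
#' @export
read_threshold_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  for (cl in c("a", "b", "T")) tab[[cl]] <- as.numeric(tab[[cl]])
  tab
}

#' Save a trained hierarchy to disk
#'
#' Single-file archive carrying a format version and the feature spec;
#' [load_hiertax()] refuses to load on version or k mismatch.
#'
#' @param object a fitted `hiertax` model.
#' @param path output file path.
#' @export
save_hiertax <- function(object, path) {
  stopifnot(inherits(object, "hiertax"))
  saveRDS(list(format_version = .model_format_version, model = object), path)
  invisible(path)
}

#' Load a trained hierarchy from disk
#'
#' @param path archive written by [save_hiertax()].
#' @param k if non-NULL, required k-mer length; a stored model with a
#'   different feature spec is refused.
#' @return The `hiertax` model.
#' @export
load_hiertax <- function(path, k = NULL) {
  arc <- readRDS(path)
  if (!is.list(arc) || !identical(arc$format_version, .model_format_version))
    stop("unrecognised model archive format in ", path, call. = FALSE)
  if (!is.null(k) && arc$model$config$k != k)
    stop("model archive was built with k = ", arc$model$config$k,
         ", requested k = ", k, call. = FALSE)
  arc$model
}
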