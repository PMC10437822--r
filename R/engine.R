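# Training and classifying phases.
#
# Training: per parent taxon, assemble the node dataset, run the
# cross-validation route, pick stopping thresholds per child (multi-child
# parents), and fit the fully trained QSVM; single-child parents get the
# novelty QSVM.  Classifying: each query genome descends the taxonomy from
# the root; at a multi-child node it proceeds iff the classification
# confidence is greater than or equal to the stopping threshold of the
# (parent, predicted child) pair, at a single-child node iff the novelty
# classifier predicts the original taxon.  Descent stopping marks that
# rank "uncertain" and all lower ranks "unattempted".

#' Configuration of a hierarchical classifier run
#'
#' @param k k-mer length of the FCGR features (default 7).
#' @param sampling a [sampling_config()].
#' @param stp an [stp_config()].
#' @param folds cross-validation folds for the preprocessing route.
#' @param outlier_fraction fraction relabelled by the novelty classifier.
#' @param balance apply [balance_classes()] to node datasets?
#' @param max_ratio,min_count balancing parameters (see
#'   [balance_classes()]).
#' @param root_single_child how to treat a root whose corpus contains a
#'   single taxon at the first rank: `"collapse"` (default) assigns that
#'   universally shared taxon with confidence 1 and moves on -- the rank
#'   carries no contrast to learn from; `"novelty"` trains a novelty
#'   classifier there like at any other single-child parent.
#' @param seed master seed; all node-level seeds derive from it.
#' @return Object of class `hiertax_config`.
#' @export
hiertax_config <- function(k = 7L, sampling = sampling_config(),
                           stp = stp_config(), folds = 5L,
                           outlier_fraction = 0.10, balance = TRUE,
                           max_ratio = 10, min_count = 5L,
                           root_single_child = c("collapse", "novelty"),
                           seed = 1L) {
  structure(list(k = as.integer(k), sampling = sampling, stp = stp,
                 folds = as.integer(folds),
                 outlier_fraction = outlier_fraction, balance = balance,
                 max_ratio = max_ratio, min_count = as.integer(min_count),
                 root_single_child = match.arg(root_single_child),
                 seed = as.integer(seed)),
            class = "hiertax_config")
}

# training items of one genome under a sampling config: a list of sequences
.genome_items <- function(contigs, cfg) {
  contigs <- vapply(contigs, function(s) as.character(normalize_seq(s)),
                    character(1))
  if (cfg$mode == "contigs") {
    as.list(filter_contigs(contigs, cfg$min_contig_len))
  } else {
    genome <- pseudo_concatenate(contigs)
    replicate_fragments(genome, cfg)
  }
}

#' Train a hierarchical taxonomic classifier
#'
#' The training phase: builds the taxonomy from the lineages, extracts
#' FCGR features from the per-genome training items, and for every parent
#' taxon fits the local classifier -- a quadratic-kernel SVM with Platt
#' calibration plus per-child stopping thresholds for multi-child parents,
#' a novelty QSVM for single-child parents.
#'
#' @param genomes named list: genome id -> character vector of contig
#'   sequences, or a directory of FASTA files.
#' @param lineages named list: genome id -> lineage (named character
#'   vector), or a lineage TSV path.
#' @param config a [hiertax_config()].
#' @param skip_failed collect node-level failures and continue instead of
#'   aborting?
#' @return Object of class `hiertax`: taxonomy, per-parent models,
#'   threshold table, cross-validation records and the config snapshot.
#' @export
hiertax_train <- function(genomes, lineages, config = hiertax_config(),
                          skip_failed = FALSE) {
  if (is.character(genomes) && length(genomes) == 1L)
    genomes <- read_fasta_dir(genomes)
  if (is.character(lineages) && length(lineages) == 1L)
    lineages <- read_lineage_tsv(lineages)
  missing <- setdiff(names(genomes), names(lineages))
  if (length(missing))
    message(length(missing), " genome(s) without lineage excluded from training")
  genomes <- genomes[intersect(names(genomes), names(lineages))]
  lineages <- lineages[names(genomes)]
  if (length(genomes) == 0L) stop("no labelled training genomes", call. = FALSE)

  taxonomy <- build_taxonomy(lineages)
  spec <- kmer_spec(config$k)

  # training items and features, seeded once for reproducible sampling
  set.seed(config$seed)
  items <- list(); item_genome <- character(0)
  for (gid in names(genomes)) {
    gi <- .genome_items(genomes[[gid]], config$sampling)
    items <- c(items, gi)
    item_genome <- c(item_genome, rep(gid, length(gi)))
  }
  if (length(items) == 0L) stop("no training items survived sampling",
                                call. = FALSE)
  features <- fcgr_matrix(items, spec)

  models <- list(); cv_by_parent <- list(); failures <- character(0)
  internal <- taxonomy_internal_ids(taxonomy)
  for (pos in seq_along(internal)) {
    pid <- internal[pos]
    kids <- taxonomy_children(taxonomy, pid)
    node_seed <- config$seed + 1000L + pos
    res <- tryCatch({
      ds <- assemble_node_dataset(taxonomy, pid, features, item_genome,
                                  lineages)
      if (length(kids) >= 2L) {
        if (config$balance) {
          set.seed(node_seed)
          ds <- balance_classes(ds, config$max_ratio, config$min_count)
        }
        cv <- crossval_confidences(ds, config$folds, seed = node_seed)
        model <- train_multi_child(ds, seed = node_seed, cv = cv)
        list(model = model, cv = cv)
      } else if (pid == 1L && config$root_single_child == "collapse") {
        list(model = structure(list(child = taxonomy_node_name(taxonomy,
                                                               kids)),
                               class = "collapsed_node"), cv = NULL)
      } else {
        model <- train_single_child(ds, config$outlier_fraction,
                                    seed = node_seed)
        list(model = model, cv = NULL)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s",
                                      taxonomy_node_name(taxonomy, pid),
                                      conditionMessage(res)))
    } else {
      models[[as.character(pid)]] <- res$model
      if (!is.null(res$cv)) cv_by_parent[[as.character(pid)]] <- res$cv
    }
  }
  if (length(failures) && !skip_failed)
    stop("training failed at node(s):\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)

  thresholds <- build_threshold_table(taxonomy, cv_by_parent, config$stp,
                                      skip_missing = skip_failed)
  structure(list(taxonomy = taxonomy, models = models,
                 thresholds = thresholds, cv_by_parent = cv_by_parent,
                 config = config, failures = failures,
                 n_genomes = length(genomes), n_items = length(items)),
            class = "hiertax")
}

# threshold lookup for (parent_id, child name); NA if absent
.lookup_threshold <- function(thresholds, parent_id, child) {
  i <- which(thresholds$parent_id == parent_id & thresholds$child == child)
  if (length(i) == 0L) return(NA_real_)
  thresholds$T[i[1]]
}

# Core descent shared by prediction and by tests that stub the node
# predictor.  `node_predict(pid, kids)` must return list(child=, confidence=,
# outlier=logical) for the node with id `pid`.
.descend <- function(taxonomy, node_predict, thresholds) {
  ranks <- taxonomy$ranks
  nr <- length(ranks)
  taxon <- rep(NA_character_, nr); conf <- rep(NA_real_, nr)
  thr <- rep(NA_real_, nr); status <- rep("unattempted", nr)
  node <- 1L
  for (j in seq_len(nr)) {
    kids <- taxonomy_children(taxonomy, node)
    if (length(kids) == 0L) break               # truncated branch: leaf above lowest rank
    pred <- node_predict(node, kids)
    if (length(kids) >= 2L) {
      t_pc <- .lookup_threshold(thresholds, node, pred$child)
      taxon[j] <- pred$child; conf[j] <- pred$confidence; thr[j] <- t_pc
      if (!is.na(t_pc) && pred$confidence < t_pc) {
        status[j] <- "uncertain"
        break
      }
      status[j] <- "complete"
    } else {
      taxon[j] <- pred$child; conf[j] <- pred$confidence
      if (isTRUE(pred$outlier)) {
        status[j] <- "uncertain"
        break
      }
      status[j] <- "complete"
    }
    node <- taxonomy_child_id(taxonomy, node, taxon[j])
  }
  list(taxon = taxon, confidence = conf, threshold = thr, status = status)
}

# node predictor backed by the trained models, for one feature row
.model_node_predict <- function(object, v) {
  force(v)
  function(pid, kids) {
    model <- object$models[[as.character(pid)]]
    if (is.null(model))
      stop("no trained model for node '",
           taxonomy_node_name(object$taxonomy, pid), "'", call. = FALSE)
    if (inherits(model, "collapsed_node")) {
      list(child = model$child, confidence = 1, outlier = FALSE)
    } else if (inherits(model, "multi_child_model")) {
      pr <- predict_with_confidence(model, v)
      list(child = pr$predicted[1], confidence = pr$confidence[1],
           outlier = FALSE)
    } else {
      pr <- predict_single_child(model, v)
      list(child = if (pr$outlier[1]) model$original_class else
        pr$predicted[1],
        confidence = pr$confidence[1], outlier = pr$outlier[1])
    }
  }
}

#' Classify one genome with a trained hierarchy
#'
#' Features are extracted from the whole pseudo-concatenated query genome
#' (no fragment sampling at classification time) and the genome descends
#' the taxonomy until a stopping rule fires or the lowest rank is reached.
#'
#' @param object a fitted `hiertax` model.
#' @param contigs character vector of the genome's contig sequences.
#' @param genome_id identifier recorded on the path.
#' @return A `hiertax_path`.
#' @export
classify_genome <- function(object, contigs, genome_id = "query") {
  stopifnot(inherits(object, "hiertax"))
  seq <- pseudo_concatenate(vapply(contigs, function(s)
    as.character(normalize_seq(s)), character(1)))
  fv <- count_kmers(seq, kmer_spec(object$config$k))
  if (fv$degenerate)
    stop("genome '", genome_id, "' has no usable k-mers (effective length ",
         fv$effective_length, ")", call. = FALSE)
  d <- .descend(object$taxonomy,
                .model_node_predict(object, fv$values),
                object$thresholds)
  classification_path(genome_id, object$taxonomy$ranks, d$taxon,
                      d$confidence, d$threshold, d$status)
}

#' Classify a batch of genomes
#'
#' Order-preserving map of [classify_genome()] with per-genome isolation:
#' one failing genome yields an error record instead of aborting the
#' batch.
#'
#' @param object a fitted `hiertax` model.
#' @param genomes named list: genome id -> character vector of contigs, or
#'   a directory of FASTA files.
#' @return Object of class `hiertax_paths`: a list of `hiertax_path`
#'   and/or `hiertax_error` records, in input order.
#' @export
classify_batch <- function(object, genomes) {
  if (is.character(genomes) && length(genomes) == 1L)
    genomes <- read_fasta_dir(genomes)
  out <- lapply(names(genomes), function(gid) {
    tryCatch(classify_genome(object, genomes[[gid]], gid),
             error = function(e)
               structure(list(genome_id = gid,
                              message = conditionMessage(e)),
                         class = "hiertax_error"))
  })
  structure(out, class = "hiertax_paths")
}

#' @export
print.hiertax_paths <- function(x, ...) {
  for (p in x) {
    if (inherits(p, "hiertax_error"))
      cat(sprintf("%s: ERROR: %s\n", p$genome_id, p$message))
    else cat(format_path(p), "\n")
  }
  invisible(x)
}

#' @rdname classify_batch
#' @param newdata genomes to classify (as in `genomes`).
#' @param ... unused.
#' @export
predict.hiertax <- function(object, newdata, ...) {
  classify_batch(object, newdata)
}

#' @export
print.hiertax <- function(x, ...) {
  n_multi <- sum(vapply(x$models, inherits, logical(1), "multi_child_model"))
  n_single <- sum(vapply(x$models, inherits, logical(1), "single_child_model"))
  cat("Hierarchical FCGR/QSVM taxonomic classifier\n")
  cat(sprintf("  k = %d (%d features); %d training genomes, %d items\n",
              x$config$k, 4L^x$config$k, x$n_genomes, x$n_items))
  cat(sprintf("  %d multi-child and %d single-child (novelty) node models\n",
              n_multi, n_single))
  cat(sprintf("  %d stopping thresholds over ranks: %s\n",
              nrow(x$thresholds), paste(x$taxonomy$ranks, collapse = " > ")))
  invisible(x)
}

#' @export
summary.hiertax <- function(object, ...) {
  cat("Training-set cross-validation accuracy per multi-child parent:\n")
  for (pid in names(object$cv_by_parent)) {
    cv <- object$cv_by_parent[[pid]]
    cat(sprintf("  %-20s n = %4d  accuracy = %.3f  mean confidence = %.3f\n",
                taxonomy_node_name(object$taxonomy, as.integer(pid)),
                nrow(cv), mean(cv$predicted == cv$truth),
                mean(cv$confidence)))
  }
  cat("\nStopping thresholds:\n")
  print.data.frame(object$thresholds[, c("parent", "child", "a", "b", "T",
                                         "n_records")],
                   row.names = FALSE, digits = 3)
  invisible(object)
}

#' Plot the stopping thresholds of a trained hierarchy
#'
#' Dot chart of the per-(parent, child) stopping thresholds, grouped by
#' parent taxon.
#'
#' @param x a fitted `hiertax` model.
#' @param ... passed to [graphics::dotchart()].
#' @export
plot.hiertax <- function(x, ...) {
  tb <- x$thresholds
  if (nrow(tb) == 0L) {
    warning("no multi-child thresholds to plot")
    return(invisible(x))
  }
  graphics::dotchart(tb$T, labels = paste(tb$parent, tb$child, sep = " > "),
                     xlab = "stopping threshold T", xlim = range(0, 1, tb$T),
                     ...)
  invisible(x)
}
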