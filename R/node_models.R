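# Per-parent-node classifiers.
#
# Multi-child parents get a quadratic-kernel (degree-2 polynomial) SVM
# trained on the whole node dataset, decomposed one-vs-one.  Two confidence
# routes exist, mirroring the two phases of the pipeline:
#   * training/preprocessing route: stratified five-fold cross-validation;
#     per-item confidence = max over classes of the softmax of the item's
#     per-class decision-score sums.  These feed the stopping-threshold
#     picker.
#   * classification route: per-pair Platt sigmoids fitted on the
#     cross-validated decision scores, coupled into a posterior; the
#     confidence is the maximum posterior.
# Single-child parents get a "novelty" QSVM: a random fraction (default
# 10%) of the training items is relabelled as an artificial outlier taxon,
# and the confidence of a prediction is the logistic of the signed decision
# score toward the predicted side.

.svm_defaults <- function(dim) list(cost = 1, degree = 2, coef0 = 1,
                                    gamma = dim)

# Fit a degree-2 polynomial SVM.  Features are raw FCGR frequencies (no
# standardisation); the kernel scale gamma defaults to the feature
# dimension 4^k so that typical inner products of frequency vectors are
# O(1).
.fit_qsvm <- function(x, y, params = .svm_defaults(ncol(x))) {
  e1071::svm(x, factor(y, levels = sort(unique(y))),
             kernel = "polynomial", degree = params$degree,
             coef0 = params$coef0, gamma = params$gamma, cost = params$cost,
             scale = FALSE)
}

# Pairwise decision values -> per-class score sums.  Column names of the
# libsvm decision matrix are "A/B" with positive values favouring A.
.class_scores <- function(decision, classes) {
  scores <- matrix(0, nrow(decision), length(classes),
                   dimnames = list(NULL, classes))
  for (cn in colnames(decision)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    scores[, pair[1]] <- scores[, pair[1]] + decision[, cn]
    scores[, pair[2]] <- scores[, pair[2]] - decision[, cn]
  }
  scores
}

#' Softmax of a score vector
#'
#' @param s numeric vector of scores.
#' @return Probability vector summing to 1.
#' @export
softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

# Platt scaling: fit sigmoid P(y=1|s) = 1/(1+exp(a*s+b)) by regularised
# maximum likelihood (Newton with backtracking, following Lin, Lin & Weng's
# numerically stable formulation).
fit_platt <- function(scores, y) {
  stopifnot(length(scores) == length(y))
  n1 <- sum(y); n0 <- length(y) - n1
  t <- ifelse(y == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  a <- 0; b <- log((n0 + 1) / (n1 + 1))
  obj <- function(a, b) {
    f <- a * scores + b
    sum(ifelse(f >= 0, t * f + log1p(exp(-f)), (t - 1) * f + log1p(exp(f))))
  }
  val <- obj(a, b)
  for (it in 1:100) {
    f <- a * scores + b
    p <- ifelse(f >= 0, exp(-f) / (1 + exp(-f)), 1 / (1 + exp(f)))
    d1 <- t - p                       # dL/df per item (note sign convention)
    g_a <- sum(scores * d1); g_b <- sum(d1)
    w <- pmax(p * (1 - p), 1e-12)
    h_aa <- sum(scores^2 * w) + 1e-12
    h_ab <- sum(scores * w)
    h_bb <- sum(w) + 1e-12
    det <- h_aa * h_bb - h_ab^2
    da <- -(h_bb * g_a - h_ab * g_b) / det
    db <- -(h_aa * g_b - h_ab * g_a) / det
    step <- 1
    repeat {
      newval <- obj(a + step * da, b + step * db)
      if (newval < val + 1e-10 || step < 1e-10) break
      step <- step / 2
    }
    a <- a + step * da; b <- b + step * db
    if (abs(val - newval) < 1e-10) break
    val <- newval
  }
  c(a = a, b = b)
}

.platt_prob <- function(par, s) 1 / (1 + exp(par[["a"]] * s + par[["b"]]))

# stratified fold assignment, deterministic given the RNG state
.stratified_folds <- function(labels, folds) {
  n <- length(labels)
  fold <- integer(n)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Cross-validated classifications and confidences for a node dataset
#'
#' Stratified `folds`-fold cross-validation of the node's quadratic-kernel
#' SVM: every item receives exactly one out-of-fold prediction, and its
#' confidence is the maximum over classes of the softmax of its per-class
#' decision-score sums.  These records are the input to stopping-threshold
#' selection.
#'
#' @param dataset a `node_dataset` (or any list with `x` and `labels`).
#' @param folds number of folds; reduced (with a message) if some class has
#'   fewer items than `folds`.
#' @param seed integer seed for fold assignment.
#' @param params SVM hyper-parameters.
#' @return Data frame with one row per item: `truth`, `predicted`,
#'   `confidence`, `fold`, plus the pairwise decision-score matrix as
#'   attribute `"decision"`.
#' @export
crossval_confidences <- function(dataset, folds = 5L, seed = 1L,
                                 params = NULL) {
  x <- dataset$x; labels <- dataset$labels
  classes <- sort(unique(labels))
  if (is.null(params)) params <- .svm_defaults(ncol(x))
  min_class <- min(table(labels))
  if (min_class < 2L)
    stop("cross-validation needs >= 2 items per class", call. = FALSE)
  if (min_class < folds) {
    message("reducing folds from ", folds, " to ", min_class,
            " (smallest class size)")
    folds <- max(2L, min_class)
  }
  set.seed(seed)
  fold <- .stratified_folds(labels, folds)
  n <- length(labels)
  npair <- length(classes) * (length(classes) - 1L) / 2L
  decision <- matrix(NA_real_, n, npair)
  predicted <- character(n); confidence <- numeric(n)
  for (f in seq_len(folds)) {
    train <- fold != f; test <- fold == f
    if (!any(test)) next
    m <- .fit_qsvm(x[train, , drop = FALSE], labels[train], params)
    pr <- stats::predict(m, x[test, , drop = FALSE], decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    colnames(decision) <- colnames(dv)
    decision[test, ] <- dv
    sc <- .class_scores(dv, classes)
    post <- t(apply(sc, 1L, softmax))
    jj <- apply(post, 1L, function(p) which(p == max(p))[1])  # lexicographic tie-break
    idx <- which(test)
    predicted[idx] <- classes[jj]
    confidence[idx] <- post[cbind(seq_along(jj), jj)]
  }
  out <- data.frame(truth = labels, predicted = predicted,
                    confidence = confidence, fold = fold,
                    stringsAsFactors = FALSE)
  attr(out, "decision") <- decision
  attr(out, "classes") <- classes
  out
}

#' Train the multi-child classifier of a parent taxon
#'
#' Fits the fully trained quadratic-kernel SVM on the entire node dataset
#' and calibrates per-pair Platt sigmoids on cross-validated decision
#' scores.
#'
#' @param dataset a `node_dataset` with at least 2 classes and at least 2
#'   items per class.
#' @param folds,seed,params passed to [crossval_confidences()]; pass a
#'   precomputed record set via `cv` to avoid refitting.
#' @param cv optional output of [crossval_confidences()] on `dataset`.
#' @return Object of class `multi_child_model`.
#' @export
train_multi_child <- function(dataset, folds = 5L, seed = 1L, params = NULL,
                              cv = NULL) {
  x <- dataset$x; labels <- dataset$labels
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("multi-child training needs >= 2 classes", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2L))
    stop("class(es) with a single item: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  if (any(grepl("/", classes, fixed = TRUE)))
    stop("child taxon names must not contain '/'", call. = FALSE)
  if (is.null(params)) params <- .svm_defaults(ncol(x))
  if (is.null(cv)) cv <- crossval_confidences(dataset, folds, seed, params)

  decision <- attr(cv, "decision")
  platt <- list()
  for (cn in colnames(decision)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    in_pair <- labels %in% pair & !is.na(decision[, cn])
    platt[[cn]] <- fit_platt(decision[in_pair, cn],
                             as.integer(labels[in_pair] == pair[1]))
  }
  svm_fit <- .fit_qsvm(x, labels, params)
  structure(list(classes = classes, svm = svm_fit, platt = platt,
                 params = params, cv = cv, dim = ncol(x)),
            class = "multi_child_model")
}

#' Predict child taxon and confidence with a multi-child model
#'
#' Pairwise decision values are mapped through the Platt sigmoids and
#' coupled into a posterior by normalised averaging of the pairwise
#' probabilities; the prediction is the argmax posterior (lexicographically
#' first child on ties) and the confidence the maximum posterior, which
#' always lies in `[1/C, 1]`.
#'
#' @param model a `multi_child_model`.
#' @param x feature vector or matrix of feature rows.
#' @return Data frame with columns `predicted` and `confidence` (one row
#'   per input row); the posterior matrix is attached as attribute
#'   `"posterior"`.
#' @export
predict_with_confidence <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$dim)
    stop("feature dimension ", ncol(x), " does not match model (",
         model$dim, ")", call. = FALSE)
  pr <- stats::predict(model$svm, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  C <- length(model$classes)
  post <- matrix(0, nrow(x), C, dimnames = list(NULL, model$classes))
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    r <- .platt_prob(model$platt[[cn]], dv[, cn])
    post[, pair[1]] <- post[, pair[1]] + r
    post[, pair[2]] <- post[, pair[2]] + (1 - r)
  }
  post <- post / rowSums(post)
  j <- apply(post, 1L, function(p) which(p == max(p))[1])
  data.frame(predicted = model$classes[j],
             confidence = post[cbind(seq_len(nrow(post)), j)],
             stringsAsFactors = FALSE) |>
    structure(posterior = post)
}

#' Train the single-child (novelty) classifier of a parent taxon
#'
#' Relabels a uniformly random `ceiling(outlier_fraction * n)` subset of
#' the items as an artificial outlier taxon and fits a binary
#' quadratic-kernel SVM of original vs outlier.
#'
#' @param dataset a `node_dataset` with exactly one class and at least 10
#'   items.
#' @param outlier_fraction fraction of items relabelled (default 0.10).
#' @param seed integer seed for the relabelled subset.
#' @param params SVM hyper-parameters.
#' @return Object of class `single_child_model`.
#' @export
train_single_child <- function(dataset, outlier_fraction = 0.10, seed = 1L,
                               params = NULL) {
  x <- dataset$x; labels <- dataset$labels
  stopifnot(outlier_fraction > 0, outlier_fraction < 1)
  if (length(unique(labels)) != 1L)
    stop("single-child training needs exactly one class", call. = FALSE)
  n <- nrow(x)
  if (n < 10L)
    stop("single-child training needs >= 10 items (got ", n, ")",
         call. = FALSE)
  set.seed(seed)
  n_out <- ceiling(outlier_fraction * n)
  out_idx <- sort(sample.int(n, n_out))
  y <- rep("original", n); y[out_idx] <- "outlier"
  if (is.null(params)) params <- .svm_defaults(ncol(x))
  svm_fit <- .fit_qsvm(x, y, params)
  structure(list(original_class = labels[1], svm = svm_fit,
                 outlier_fraction = outlier_fraction, outlier_idx = out_idx,
                 params = params, dim = ncol(x)),
            class = "single_child_model")
}

#' Predict with a single-child (novelty) model
#'
#' Classifies each item as the original child taxon or the artificial
#' outlier taxon; the confidence is the logistic `1/(1+exp(-s))` of the
#' signed decision score toward the predicted side (0.5 on the boundary).
#'
#' @param model a `single_child_model`.
#' @param x feature vector or matrix of feature rows.
#' @return Data frame with columns `predicted` (the original child's name
#'   or `"outlier"`), `outlier` (logical) and `confidence`.
#' @export
predict_single_child <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$dim)
    stop("feature dimension ", ncol(x), " does not match model (",
         model$dim, ")", call. = FALSE)
  pr <- stats::predict(model$svm, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  cn <- colnames(dv)[1]
  pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
  s <- dv[, 1]
  if (pair[1] != "original") s <- -s    # orient toward "original"
  is_outlier <- s < 0
  conf <- 1 / (1 + exp(-abs(s)))        # logistic toward predicted side
  conf[s == 0] <- 0.5
  data.frame(predicted = ifelse(is_outlier, "outlier", model$original_class),
             outlier = is_outlier, confidence = conf,
             stringsAsFactors = FALSE)
}
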