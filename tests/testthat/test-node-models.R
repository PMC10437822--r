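# Small separable fixtures in frequency-like feature space: class centres
# on the simplex, tight Gaussian clouds, renormalised to sum 1.
make_clusters <- function(n_per_class, centres, sd = 0.01, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centres)), function(i) {
    m <- matrix(stats::rnorm(n_per_class * ncol(centres),
                             mean = rep(centres[i, ], each = n_per_class),
                             sd = sd), n_per_class)
    m <- abs(m)
    m / rowSums(m)
  }))
  labels <- rep(rownames(centres), each = n_per_class)
  structure(list(parent_id = 1L, x = x, labels = labels,
                 provenance = data.frame(genome = labels,
                                         row = seq_along(labels))),
            class = "node_dataset")
}

centres2 <- matrix(c(0.7, 0.1, 0.1, 0.1,
                     0.1, 0.1, 0.1, 0.7), 2, byrow = TRUE,
                   dimnames = list(c("X", "Y"), NULL))
centres3 <- matrix(c(0.7, 0.1, 0.1, 0.1,
                     0.1, 0.7, 0.1, 0.1,
                     0.1, 0.1, 0.7, 0.1), 3, byrow = TRUE,
                   dimnames = list(c("X", "Y", "Z"), NULL))

test_that("separable clusters are learned perfectly with high confidence", {
  ds <- make_clusters(20, centres2, seed = 2)
  m <- train_multi_child(ds, seed = 1)
  pr <- predict_with_confidence(m, ds$x)
  expect_identical(pr$predicted, ds$labels)
  # an item deep inside one cluster is confidently assigned
  expect_gt(min(pr$confidence), 0.9)
  # posterior rows sum to 1
  expect_equal(rowSums(attr(pr, "posterior")), rep(1, nrow(ds$x)),
               tolerance = 1e-9)
})

test_that("a midpoint query between two symmetric classes is ~50/50", {
  ds <- make_clusters(25, centres2, seed = 3)
  m <- train_multi_child(ds, seed = 1)
  mid <- colMeans(rbind(colMeans(ds$x[ds$labels == "X", ]),
                        colMeans(ds$x[ds$labels == "Y", ])))
  pr <- predict_with_confidence(m, mid)
  expect_lt(abs(pr$confidence - 0.5), 0.1)
})

test_that("randomly permuted labels give chance-level CV accuracy", {
  accs <- vapply(1:5, function(s) {
    ds <- make_clusters(20, centres2, seed = s)
    set.seed(s)
    ds$labels <- sample(ds$labels)
    cv <- crossval_confidences(ds, folds = 5, seed = s)
    mean(cv$predicted == cv$truth)
  }, numeric(1))
  # binomial noise around 1/2 over 5 seeds x 40 items
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("dimension mismatches are rejected", {
  ds <- make_clusters(10, centres2, seed = 4)
  m <- train_multi_child(ds, seed = 1)
  expect_error(predict_with_confidence(m, runif(5)), "dimension")
  sm <- train_single_child(
    structure(list(parent_id = 1L, x = ds$x[ds$labels == "X", ],
                   labels = rep("X", 10)), class = "node_dataset"),
    seed = 1)
  expect_error(predict_single_child(sm, runif(5)), "dimension")
})

test_that("a class with one item fails training with its name", {
  ds <- make_clusters(5, centres2, seed = 5)
  keep <- c(which(ds$labels == "X"), which(ds$labels == "Y")[1])
  ds$x <- ds$x[keep, ]; ds$labels <- ds$labels[keep]
  expect_error(train_multi_child(ds, seed = 1), "Y")
})

test_that("softmax-max confidence matches its closed form", {
  expect_equal(max(softmax(c(2, 1, 0))),
               exp(2) / (exp(2) + exp(1) + 1), tolerance = 1e-12)
  expect_equal(max(softmax(c(2, 1, 0))), 0.6652, tolerance = 1e-4)
  expect_equal(softmax(c(5, 5, 5, 5)), rep(0.25, 4))   # all equal -> 1/C
})

test_that("cross-validation yields exactly one out-of-fold record per item", {
  ds <- make_clusters(12, centres3, seed = 6)
  cv <- crossval_confidences(ds, folds = 5, seed = 9)
  expect_equal(nrow(cv), 36L)
  expect_true(all(cv$confidence >= 1 / 3 & cv$confidence <= 1))
  expect_true(all(table(cv$fold, ds$labels) > 0))   # stratified
})

test_that("leave-one-out crossval matches a brute-force held-out loop", {
  ds <- make_clusters(10, centres3, sd = 0.05, seed = 7)   # 30 items
  n <- nrow(ds$x)
  cv <- crossval_confidences(ds, folds = n, seed = 1)
  classes <- sort(unique(ds$labels))
  set.seed(1)
  fold <- hiertax:::.stratified_folds(ds$labels, n)
  for (i in sample(n, 8)) {                 # spot-check items
    train <- fold != fold[i]
    m <- hiertax:::.fit_qsvm(ds$x[train, ], ds$labels[train])
    pr <- predict(m, ds$x[i, , drop = FALSE], decision.values = TRUE)
    sc <- hiertax:::.class_scores(attr(pr, "decision.values"), classes)
    post <- softmax(sc[1, ])
    expect_identical(cv$predicted[i], classes[which.max(post)])
    expect_equal(cv$confidence[i], max(post), tolerance = 1e-9)
  }
})

test_that("confidences are invariant under a fixed feature permutation", {
  ds <- make_clusters(15, centres2, seed = 8)
  perm <- c(3, 1, 4, 2)
  ds_p <- ds; ds_p$x <- ds$x[, perm]
  m <- train_multi_child(ds, seed = 2)
  m_p <- train_multi_child(ds_p, seed = 2)
  q <- ds$x[5, ]
  pr <- predict_with_confidence(m, q)
  pr_p <- predict_with_confidence(m_p, q[perm])
  expect_identical(pr$predicted, pr_p$predicted)
  expect_equal(pr$confidence, pr_p$confidence, tolerance = 1e-9)
})

test_that("the Platt sigmoid is monotone in the decision score", {
  set.seed(10)
  s <- c(stats::rnorm(40, 1.5), stats::rnorm(40, -1.5))
  y <- rep(c(1L, 0L), each = 40)
  par <- hiertax:::fit_platt(s, y)
  grid <- seq(-3, 3, by = 0.1)
  p <- hiertax:::.platt_prob(par, grid)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p > 0 & p < 1))
  # scores near the positive cloud calibrate high, negative cloud low
  expect_gt(hiertax:::.platt_prob(par, 1.5), 0.8)
  expect_lt(hiertax:::.platt_prob(par, -1.5), 0.2)
})

test_that("novelty training relabels the right number of items, seeded", {
  x <- make_clusters(50, centres2, seed = 11)$x
  ds <- structure(list(parent_id = 1L, x = x, labels = rep("only", 100)),
                  class = "node_dataset")
  m <- train_single_child(ds, outlier_fraction = 0.10, seed = 4)
  expect_length(m$outlier_idx, 10L)
  m2 <- train_single_child(ds, outlier_fraction = 0.5, seed = 4)
  expect_length(m2$outlier_idx, 50L)
  m3 <- train_single_child(ds, outlier_fraction = 0.10, seed = 4)
  expect_identical(m$outlier_idx, m3$outlier_idx)

  small <- structure(list(parent_id = 1L, x = x[1:5, ],
                          labels = rep("only", 5)), class = "node_dataset")
  expect_error(train_single_child(small, seed = 1), ">= 10 items")
})

test_that("novelty confidence is the logistic of the decision score", {
  x <- make_clusters(30, centres2, seed = 12)$x[1:30, ]
  ds <- structure(list(parent_id = 1L, x = x, labels = rep("only", 30)),
                  class = "node_dataset")
  m <- train_single_child(ds, seed = 2)
  pr <- predict_single_child(m, x)
  expect_true(all(pr$confidence >= 0.5 & pr$confidence <= 1))
  # decision score 0 -> confidence 0.5 by construction of the map
  expect_equal(1 / (1 + exp(0)), 0.5)
  # most in-distribution items come back as the original taxon
  expect_gt(mean(pr$predicted == "only"), 0.6)
})
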