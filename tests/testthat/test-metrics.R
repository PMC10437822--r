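ranks6 <- c("Phylum", "Class", "Order", "Family", "Genus", "Species")

# path with `n_complete` complete correct steps, then optionally wrong
# completes / an uncertain stop, against truth t1..t6
make_path <- function(id, n_correct, n_complete, uncertain_after = FALSE) {
  taxon <- rep(NA_character_, 6); status <- rep("unattempted", 6)
  conf <- rep(NA_real_, 6)
  if (n_complete > 0) {
    taxon[1:n_complete] <- ifelse(seq_len(n_complete) <= n_correct,
                                  paste0("t", 1:n_complete),
                                  paste0("wrong", 1:n_complete))
    status[1:n_complete] <- "complete"
    conf[1:n_complete] <- 0.9
  }
  if (uncertain_after && n_complete < 6) {
    status[n_complete + 1] <- "uncertain"
    taxon[n_complete + 1] <- paste0("u", n_complete + 1)
    conf[n_complete + 1] <- 0.5
  }
  classification_path(id, ranks6, taxon, conf, rep(NA_real_, 6), status)
}

truth6 <- stats::setNames(paste0("t", 1:6), ranks6)

test_that("correct_down_to follows the complete-and-correct definition", {
  p <- make_path("x", n_correct = 1, n_complete = 1, uncertain_after = TRUE)
  expect_true(correct_down_to(p, truth6, 0))      # root: always correct
  expect_true(correct_down_to(p, truth6, 1))
  expect_false(correct_down_to(p, truth6, 2))     # uncertain at rank 2
  expect_false(correct_down_to(p, truth6, 3))
  # complete but wrong taxon fails
  pw <- make_path("y", n_correct = 1, n_complete = 2)
  expect_true(correct_down_to(pw, truth6, 1))
  expect_false(correct_down_to(pw, truth6, 2))
})

test_that("genome weights match the printed closed forms", {
  expect_equal(genome_weight(j = 3, p = 3, h = 3), 1)      # fully correct
  expect_equal(genome_weight(j = 6, p = 0, h = 1), 0)      # nothing correct
  expect_equal(genome_weight(j = 6, p = 4, h = 6), 0.5)    # (1/6)(4 - 2/2*... ) = 0.5
  expect_equal(genome_weight(j = 6, p = 1, h = 6), 0)      # clamped at 0
  expect_error(genome_weight(j = 0, p = 1, h = 1), "j")
})

test_that("genome weight is monotone in p and antitone in h", {
  for (j in 1:6) for (h in 0:6) {
    w <- vapply(0:h, genome_weight, numeric(1), j = j, h = h)
    expect_true(all(diff(w) >= 0))
  }
  for (j in 1:6) for (p in 0:4) {
    w <- vapply(p:6, function(h) genome_weight(j, p, h), numeric(1))
    expect_true(all(diff(w) <= 0))
  }
})

test_that("the evaluation report reproduces hand-computed ratios", {
  # all-correct: every metric 1 at every rank
  paths <- lapply(1:4, function(i) make_path(paste0("g", i), 6, 6))
  truth <- stats::setNames(rep(list(truth6), 4), paste0("g", 1:4))
  ev <- evaluate_paths(paths, truth)
  expect_true(all(ev$CA == 1 & ev$AA == 1 & ev$WA == 1 & ev$CR == 1))

  # records with (p, h) = (6,6), (4,6), (0,1), (6,6): WA(rank 6) = 0.625
  paths2 <- list(make_path("g1", 6, 6), make_path("g2", 4, 6),
                 make_path("g3", 0, 1), make_path("g4", 6, 6))
  ev2 <- evaluate_paths(paths2, truth)
  expect_equal(ev2$WA[6], (1 + 0.5 + 0 + 1) / 4)
  rec <- attr(ev2, "records")
  expect_equal(rec$p, c(6L, 4L, 0L, 6L))
  expect_equal(rec$h, c(6L, 6L, 1L, 6L))

  # 2 complete-at-j, 1 correct-down-to-j, 4 genomes: CA 0.5, AA 0.25, CR 0.5
  paths3 <- list(make_path("g1", 6, 6), make_path("g2", 3, 6),
                 make_path("g3", 2, 2), make_path("g4", 0, 3))
  ev3 <- evaluate_paths(paths3, truth)
  expect_equal(ev3$CA[6], 0.5)                   # 1 correct of 2 complete
  expect_equal(ev3$AA[6], 0.25)
  expect_equal(ev3$CR[6], 0.5)
})

test_that("truncated reference lineages are excluded below the truncation", {
  paths <- list(make_path("g1", 6, 6), make_path("g2", 6, 6))
  truth <- list(g1 = truth6, g2 = truth6[1:4])   # g2 unnamed below Family
  ev <- evaluate_paths(paths, truth)
  expect_equal(ev$n_total, c(2L, 2L, 2L, 2L, 1L, 1L))
  expect_equal(ev$n_excluded[5:6], c(1L, 1L))
  expect_equal(ev$AA[6], 1)                      # over the 1 eligible genome
})

test_that("CA is NA when nothing is completely classified at a rank", {
  paths <- list(make_path("g1", 2, 2, uncertain_after = TRUE))
  ev <- evaluate_paths(paths, list(g1 = truth6))
  expect_true(is.na(ev$CA[4]))
  expect_equal(ev$CR[4], 0)
})

test_that("evaluate_paths matches a per-definition recomputation oracle", {
  set.seed(61)
  ranks <- c("Phylum", "Class", "Order", "Family")
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    pts <- lapply(seq_len(n), function(i)
      random_path_and_truth(sprintf("g%d", i), ranks))
    paths <- lapply(pts, `[[`, "path")
    truths <- lapply(pts, `[[`, "truth")
    names(truths) <- vapply(paths, `[[`, character(1), "genome_id")
    ev <- evaluate_paths(paths, truths)
    j <- sample(4, 1)
    want <- oracle_metrics(paths, unname(truths), j)
    expect_equal(ev$CA[j], want$CA)
    expect_equal(ev$AA[j], want$AA)
    expect_equal(ev$WA[j], want$WA)
    expect_equal(ev$CR[j], want$CR)
    # metric orderings hold whenever defined
    if (!is.na(ev$CA[j])) expect_gte(ev$CA[j], ev$AA[j])
    expect_gte(ev$WA[j], ev$AA[j])
  }
})
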