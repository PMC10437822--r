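test_that("contig filtering uses 'shorter than' semantics", {
  contigs <- c(strrep("A", 4999), strrep("C", 5000), strrep("G", 12000))
  kept <- filter_contigs(contigs, 5000)
  expect_equal(nchar(kept), c(5000L, 12000L))
  expect_identical(filter_contigs(contigs, 1), contigs)
  expect_identical(filter_contigs(character(0), 5000), character(0))
})

test_that("representative fragments are disjoint, in range, and sized", {
  set.seed(23)
  g <- random_dna(50000)
  cfg <- sampling_config(n_fragments = 4, fragment_len = 10000)
  s <- sample_representative_fragment(g, cfg)
  expect_equal(nchar(s), 4 * 10000 + 3)
  iv <- attr(s, "intervals")
  expect_equal(nrow(iv), 4L)
  # pairwise disjoint, inside [0, L)
  o <- order(iv[, "start"])
  expect_true(all(iv[o, "end"][-4] <= iv[o, "start"][-1]))
  expect_true(all(iv[, "start"] >= 0) && all(iv[, "end"] <= 50000))
})

test_that("interval sampling is valid across many random regimes", {
  set.seed(29)
  for (i in 1:2000) {
    f <- sample(5:50, 1)
    n <- sample(1:4, 1)
    L <- n * f + sample(0:100, 1)
    starts <- hiertax:::.sample_disjoint_starts(L, n, f)
    expect_true(all(diff(starts) >= f))
    expect_true(starts[1] >= 0 && starts[n] + f <= L)
  }
})

test_that("an exactly-tiling genome is sampled deterministically", {
  g <- random_dna(40000)
  cfg <- sampling_config(n_fragments = 4, fragment_len = 10000)
  set.seed(1); s1 <- sample_representative_fragment(g, cfg)
  set.seed(2); s2 <- sample_representative_fragment(g, cfg)
  expect_identical(as.character(s1), as.character(s2))
  expect_equal(attr(s1, "intervals")[, "start"], c(0L, 10000L, 20000L, 30000L))
})

test_that("short genomes fall back to fewer fragments or the whole genome", {
  cfg <- sampling_config(n_fragments = 4, fragment_len = 10000,
                         min_contig_len = 5000)
  set.seed(31)
  g <- random_dna(15000)                     # floor(L/f) = 1 fragment
  s <- sample_representative_fragment(g, cfg)
  expect_equal(nchar(s), 10000L)
  g2 <- random_dna(8000)                     # whole genome as one fragment
  s2 <- sample_representative_fragment(g2, cfg)
  expect_equal(nchar(s2), 8000L)
  g3 <- random_dna(3000)                     # below min_contig_len: skip
  expect_error(sample_representative_fragment(g3, cfg),
               class = "hiertax_skip")
})

test_that("replication is independent per replicate and seeded", {
  g <- random_dna(30000)
  cfg <- sampling_config(n_fragments = 2, fragment_len = 5000,
                         n_replicates = 20)
  set.seed(5); r1 <- replicate_fragments(g, cfg)
  expect_length(r1, 20L)
  set.seed(5); r2 <- replicate_fragments(g, cfg)
  expect_identical(r1, r2)                   # determinism under a fixed seed
  cfg1 <- sampling_config(n_fragments = 2, fragment_len = 5000,
                          n_replicates = 1)
  set.seed(6); expect_length(replicate_fragments(g, cfg1), 1L)
})

test_that("node datasets are assembled with child labels and exclusions", {
  lins <- list(
    gA1 = parse_gtdb_lineage("d__D;p__X;c__CX1"),
    gA2 = parse_gtdb_lineage("d__D;p__X;c__CX2"),
    gA3 = parse_gtdb_lineage("d__D;p__X;c__CX1"),
    gB1 = parse_gtdb_lineage("d__D;p__Y;c__CY1"),
    gB2 = parse_gtdb_lineage("d__D;p__Y;c__CY1"),
    gT  = c(Domain = "D", Phylum = "X"))       # truncated above Class
  tax <- build_taxonomy(lins)
  feats <- matrix(runif(12 * 4), 12, 4)
  item_genome <- rep(names(lins), each = 2)

  # at the domain node: all 12 items, labelled by phylum
  did <- tax$nodes$id[tax$nodes$name == "D"]
  ds <- assemble_node_dataset(tax, did, feats, item_genome, lins)
  expect_equal(nrow(ds$x), 12L)
  expect_setequal(unique(ds$labels), c("X", "Y"))

  # at phylum X: truncated genome excluded, others labelled by class
  xid <- tax$nodes$id[tax$nodes$name == "X"]
  dsx <- assemble_node_dataset(tax, xid, feats, item_genome, lins)
  expect_equal(nrow(dsx$x), 6L)
  expect_equal(attr(dsx, "n_excluded"), 1L)
  expect_setequal(unique(dsx$labels), c("CX1", "CX2"))

  # leaf node has no children
  cid <- tax$nodes$id[tax$nodes$name == "CX1"]
  expect_error(assemble_node_dataset(tax, cid, feats, item_genome, lins),
               "no children")
})

test_that("class balancing caps majorities and lifts minorities", {
  mk <- function(counts) {
    labels <- rep(names(counts), counts)
    structure(list(parent_id = 1L,
                   x = matrix(seq_along(labels), ncol = 1),
                   labels = labels,
                   provenance = data.frame(genome = labels,
                                           row = seq_along(labels))),
              class = "node_dataset")
  }
  set.seed(37)
  b <- balance_classes(mk(c(A = 100, B = 5)), max_ratio = 10, min_count = 5)
  expect_equal(as.vector(table(b$labels)), c(50L, 5L))

  b2 <- balance_classes(mk(c(A = 8, B = 8)), max_ratio = 10, min_count = 5)
  expect_equal(as.vector(table(b2$labels)), c(8L, 8L))   # identity

  b3 <- balance_classes(mk(c(A = 3, B = 3)), max_ratio = 10, min_count = 5)
  expect_equal(as.vector(table(b3$labels)), c(5L, 5L))   # upsampled

  # never empties a class that had items
  b4 <- balance_classes(mk(c(A = 1000, B = 1)), max_ratio = 2, min_count = 1)
  expect_true(all(c("A", "B") %in% b4$labels))
})
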