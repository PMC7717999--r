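test_that("degenerate distance structures give all-singleton or single-GST partitions", {
  tr <- ape::read.tree(text = "(((a,b),c),(d,e));")
  ids <- tr$tip.label
  far <- matrix(100L, 5, 5, dimnames = list(ids, ids)); diag(far) <- 0L
  near <- matrix(1L, 5, 5, dimnames = list(ids, ids)); diag(near) <- 0L
  prio <- sort(ids)

  all_single <- cluster_gsts(tr, far, threshold = 100, priority = prio)
  expect_equal(all_single$n_gsts, 5)
  one <- cluster_gsts(tr, near, threshold = 100, priority = prio)
  expect_equal(one$n_gsts, 1)
  expect_setequal(one$membership$genome_id, ids)
})

test_that("greedy merging on a caterpillar tree matches an independent replay", {
  tr <- ape::read.tree(text = "(((((a,b),c),d),e),f);")
  ids <- tr$tip.label
  d <- matrix(0L, 6, 6, dimnames = list(ids, ids))
  d["a", "b"] <- d["b", "a"] <- 10L
  d["a", "c"] <- d["c", "a"] <- 30L
  d["b", "c"] <- d["c", "b"] <- 25L
  d[c("a", "b", "c"), c("d", "e", "f")] <- 80L
  d[c("d", "e", "f"), c("a", "b", "c")] <- 80L
  d["d", "e"] <- d["e", "d"] <- 15L
  d["d", "f"] <- d["f", "d"] <- 90L
  d["e", "f"] <- d["f", "e"] <- 90L
  prio <- c("a", "d", "f", "b", "c", "e")
  asn <- cluster_gsts(tr, d, threshold = 50, priority = prio)
  blocks <- split(asn$membership$genome_id, asn$membership$gst_id)
  blocks <- lapply(unname(blocks), sort)
  expect_equal(blocks, oracle_cluster_gsts(tr, d, 50, prio))
})

test_that("clustering invariants hold over random instances and the replay oracle agrees", {
  set.seed(202)
  for (rep in 1:40) {
    inst <- random_gst_instance(sample(4:12, 1))
    thr <- sample(20:120, 1)
    asn <- cluster_gsts(inst$tree, inst$d, threshold = thr,
                        priority = inst$priority)
    memb <- asn$membership
    # partition of the leaf set
    expect_setequal(memb$genome_id, inst$tree$tip.label)
    expect_equal(anyDuplicated(memb$genome_id), 0L)
    # threshold: every GST's internal max pairwise distance below threshold
    for (g in unique(memb$gst_id)) {
      mm <- memb$genome_id[memb$gst_id == g]
      if (length(mm) > 1) expect_lt(max(inst$d[mm, mm]), thr)
    }
    # each GST is a connected clade: its members are exactly the tips below
    # some tree node
    desc <- phangorn::Descendants(inst$tree, type = "tips")
    leafsets <- lapply(desc, function(ix) sort(inst$tree$tip.label[ix]))
    for (g in unique(memb$gst_id)) {
      mm <- sort(memb$genome_id[memb$gst_id == g])
      expect_true(any(vapply(leafsets, identical, logical(1), mm)))
    }
    # equality with the independent replay of the stated rule
    blocks <- lapply(unname(split(memb$genome_id, memb$gst_id)), sort)
    expect_equal(blocks, oracle_cluster_gsts(inst$tree, inst$d, thr, inst$priority))
    # determinism
    asn2 <- cluster_gsts(inst$tree, inst$d, threshold = thr,
                         priority = inst$priority)
    expect_identical(asn$membership, asn2$membership)
    # monotonicity: a higher threshold never yields more GSTs
    asn_hi <- cluster_gsts(inst$tree, inst$d, threshold = thr + 40,
                           priority = inst$priority)
    expect_lte(asn_hi$n_gsts, asn$n_gsts)
  }
})

test_that("threshold comparison is strict: a pair at exactly the threshold blocks the merge", {
  tr <- ape::read.tree(text = "(a,b);")
  d <- matrix(c(0L, 20000L, 20000L, 0L), 2, dimnames = list(c("a", "b"), c("a", "b")))
  asn <- cluster_gsts(tr, d, threshold = 20000, priority = c("a", "b"))
  expect_equal(asn$n_gsts, 2)
  d2 <- d; d2["a", "b"] <- d2["b", "a"] <- 19999L
  asn2 <- cluster_gsts(tr, d2, threshold = 20000, priority = c("a", "b"))
  expect_equal(asn2$n_gsts, 1)
})

test_that("representatives are the highest-priority member of each GST", {
  pipe <- small_pipeline()
  reps <- select_representatives(pipe$assignment, pipe$priority)
  memb <- pipe$assignment$membership
  for (g in names(reps)) {
    mm <- memb$genome_id[memb$gst_id == as.integer(g)]
    expect_equal(reps[[g]], mm[which.min(match(mm, pipe$priority))])
  }
  # brute force on random partitions
  set.seed(5)
  ids <- sprintf("g%02d", 1:12)
  for (i in 1:10) {
    prio <- sample(ids)
    part <- tibble::tibble(genome_id = ids, gst_id = sample(1:4, 12, TRUE))
    reps <- select_representatives(part, prio)
    for (g in names(reps)) {
      mm <- part$genome_id[part$gst_id == as.integer(g)]
      expect_equal(reps[[g]], mm[which.min(match(mm, prio))])
    }
  }
})

test_that("taxonomy collapses GST clades, suppresses unary nodes and keeps one root", {
  # one GST covering the whole tree -> species root with a single leaf child
  tr <- ape::read.tree(text = "((a,b),c);")
  ids <- tr$tip.label
  near <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  one <- cluster_gsts(tr, near, threshold = 10, priority = sort(ids))
  tax1 <- build_taxonomy(tr, one)
  expect_equal(nrow(tax1$nodes), 2)
  expect_equal(tax1$nodes$rank, c("species", "strain-type"))

  # balanced 4-leaf tree, 2 GSTs of 2 -> root with two GST leaves
  tr4 <- ape::read.tree(text = "((a,b),(c,d));")
  d4 <- matrix(50L, 4, 4, dimnames = list(tr4$tip.label, tr4$tip.label))
  diag(d4) <- 0L
  d4["a", "b"] <- d4["b", "a"] <- 1L
  d4["c", "d"] <- d4["d", "c"] <- 1L
  asn4 <- cluster_gsts(tr4, d4, threshold = 10, priority = sort(tr4$tip.label))
  expect_equal(asn4$n_gsts, 2)
  tax4 <- build_taxonomy(tr4, asn4)
  expect_equal(nrow(tax4$nodes), 3)
  expect_equal(sum(tax4$nodes$rank == "species"), 1)
  expect_equal(tax4$nodes$parent_id[tax4$nodes$rank == "strain-type"], c(1L, 1L))

  # bigger case: every internal node of the taxonomy has >= 2 children
  pipe <- small_pipeline()
  tax <- pipe$taxonomy
  internals <- tax$nodes$node_id[!(tax$nodes$node_id %in% tax$gst_nodes)]
  for (u in internals)
    expect_gte(sum(tax$nodes$parent_id == u), 2)
  # a non-clade "GST" is rejected
  bad <- pipe$assignment
  bad$membership$gst_id[match(c("GST01_S01", "GST02_S01"),
                              bad$membership$genome_id)] <- c(99L, 99L)
  expect_error(build_taxonomy(pipe$sim$tree, bad), "not a clade")
})
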