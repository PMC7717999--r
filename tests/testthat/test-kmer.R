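# tiny 3-GST taxonomy ((G1,G2),G3): node ids are breadth-first from the root
toy_taxonomy <- function() {
  tr <- ape::read.tree(text = "((a,b),c);")
  d <- matrix(50L, 3, 3, dimnames = list(tr$tip.label, tr$tip.label))
  diag(d) <- 0L
  asn <- cluster_gsts(tr, d, threshold = 10, priority = c("a", "b", "c"))
  list(tree = tr, taxonomy = build_taxonomy(tr, asn))
}

test_that("k-mer database maps every shared k-mer to the brute-force LCA", {
  toy <- toy_taxonomy()
  tax <- toy$taxonomy
  set.seed(31)
  base <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  shared_ab <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  uniq <- replicate(3, paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""))
  rep_genes <- list("1" = c(base, shared_ab, uniq[1]),
                    "2" = c(base, shared_ab, uniq[2]),
                    "3" = c(base, uniq[3]))
  db <- build_kmer_db(rep_genes, tax, k = 15)
  entries <- kmer_db_entries(db)

  # brute-force census: canonical k-mer -> set of GSTs -> LCA by hand
  census <- list()
  for (g in names(rep_genes)) {
    for (km in unlist(lapply(rep_genes[[g]], all_canonical_kmers, 15)))
      census[[km]] <- union(census[[km]], g)
  }
  anc <- lapply(tax$gst_nodes, function(lf) rev(taxonomy_ancestors(tax, lf)))
  expected <- vapply(census, function(gs) {
    paths <- anc[gs]
    common <- Reduce(intersect, paths)
    common[length(common)]
  }, integer(1))
  got <- setNames(entries$node_id, entries$kmer)
  expect_equal(length(got), length(expected))
  expect_equal(got[names(expected)], expected)

  # spot checks of the contract
  leaf3 <- tax$gst_nodes[["3"]]
  km3 <- setdiff(all_canonical_kmers(uniq[3], 15),
                 unlist(lapply(c(base, shared_ab, uniq[1:2]),
                               all_canonical_kmers, 15)))
  expect_true(all(got[km3] == leaf3))
  km_all <- Reduce(intersect, lapply(rep_genes, function(x)
    unlist(lapply(x, all_canonical_kmers, 15))))
  expect_true(all(got[km_all] == 1L)) # root
})

test_that("sequences shorter than k warn and contribute nothing; even k is rejected", {
  toy <- toy_taxonomy()
  expect_error(build_kmer_db(list("1" = "ACGTACGTACGTACGT"), toy$taxonomy, k = 16),
               "odd")
  expect_warning(
    db <- build_kmer_db(list("1" = c("ACGTACG", strrep("ACGT", 20)),
                             "2" = strrep("TTGCA", 16),
                             "3" = strrep("GATC", 20)),
                        toy$taxonomy, k = 15),
    "shorter than k")
  expect_false(any(grepl("^ACGTACG$", kmer_db_entries(db)$kmer)))
})

test_that("read classification scores root-to-leaf paths like the exhaustive oracle", {
  toy <- toy_taxonomy()
  tax <- toy$taxonomy
  set.seed(77)
  mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  rep_genes <- list("1" = mk(300), "2" = mk(300), "3" = mk(300))
  db <- build_kmer_db(rep_genes, tax, k = 15)

  # error-free read from a region unique to one GST -> that leaf
  read1 <- substring(rep_genes[["3"]], 100, 200)
  asn <- classify_reads(c(r1 = read1), db)
  expect_equal(asn$node_id, unname(tax$gst_nodes[["3"]]))

  # read absent from the database -> unclassified; read below k -> unclassified
  asn2 <- classify_reads(c(r2 = mk(60), r3 = "ACGTACGTAC"), db)
  expect_true(all(is.na(asn2$node_id)))

  # stitched read with hits in two leaves: exhaustive path enumeration picks
  # the winner; verify against a manual census of hit counts
  stitched <- paste0(substring(rep_genes[["1"]], 1, 80),
                     substring(rep_genes[["3"]], 1, 40))
  entries <- kmer_db_entries(db)
  lut <- setNames(entries$node_id, entries$kmer)
  hits <- table(stats::na.omit(lut[all_kmers_in_order(stitched, 15)]))
  paths <- lapply(tax$gst_nodes, function(lf) taxonomy_ancestors(tax, lf))
  scores <- vapply(paths, function(p)
    sum(hits[as.character(p)], na.rm = TRUE), numeric(1))
  winners <- tax$gst_nodes[scores == max(scores)]
  expected <- if (length(winners) == 1) unname(winners) else {
    common <- Reduce(intersect, lapply(unname(winners), function(lf)
      rev(taxonomy_ancestors(tax, lf))))
    common[length(common)]
  }
  got <- classify_reads(c(s = stitched), db)$node_id
  expect_equal(got, unname(expected))
})

test_that("classification ties and internal-only hits resolve to the LCA", {
  toy <- toy_taxonomy()
  tax <- toy$taxonomy
  # identical representative sequence for GSTs 1 and 2 -> all their k-mers
  # sit at their LCA; a read from it must land on that internal node
  set.seed(9)
  shared <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  other <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  db <- build_kmer_db(list("1" = shared, "2" = shared, "3" = other),
                      tax, k = 15)
  parent12 <- tax$nodes$parent_id[tax$nodes$node_id == tax$gst_nodes[["1"]]]
  got <- classify_reads(c(r = substring(shared, 50, 150)), db)$node_id
  expect_equal(got, parent12)
})

test_that("abundance estimation redistributes internal counts leaf-proportionally and conserves reads", {
  toy <- toy_taxonomy()
  tax <- toy$taxonomy
  leaf1 <- tax$gst_nodes[["1"]]; leaf2 <- tax$gst_nodes[["2"]]
  parent12 <- tax$nodes$parent_id[tax$nodes$node_id == leaf1]

  # all reads on one leaf
  a1 <- tibble::tibble(read_id = sprintf("r%d", 1:5),
                       node_id = rep(unname(tax$gst_nodes[["2"]]), 5), rank = "strain-type")
  p1 <- estimate_abundance(a1, tax, sample_id = "s")
  expect_equal(p1$gst_id, 2L)
  expect_equal(p1$relative, 1)

  # leaf counts {90, 10} with 100 on their parent -> {180, 20}
  nodes <- c(rep(leaf1, 90), rep(leaf2, 10), rep(parent12, 100))
  a2 <- tibble::tibble(read_id = sprintf("r%d", seq_along(nodes)),
                       node_id = nodes, rank = NA_character_)
  p2 <- estimate_abundance(a2, tax)
  expect_equal(p2$count[p2$gst_id == 1], 180)
  expect_equal(p2$count[p2$gst_id == 2], 20)
  expect_equal(p2$relative[p2$gst_id == 1], 0.9)
  # conservation: redistributed total equals classified total
  expect_equal(sum(p2$count), length(nodes))
  expect_equal(attr(p2, "n_classified"), length(nodes))

  # internal counts above all-zero leaves spread uniformly
  a3 <- tibble::tibble(read_id = sprintf("r%d", 1:10),
                       node_id = rep(parent12, 10), rank = NA_character_)
  p3 <- estimate_abundance(a3, tax)
  expect_equal(sort(p3$gst_id), c(1L, 2L))
  expect_equal(p3$count, c(5, 5))

  # all reads unclassified -> explicitly flagged empty profile
  a4 <- tibble::tibble(read_id = c("r1", "r2"), node_id = NA_integer_,
                       rank = NA_character_)
  p4 <- estimate_abundance(a4, tax)
  expect_true(attr(p4, "empty"))
  expect_equal(nrow(p4), 0)
  expect_error(estimate_abundance(a4[0, ], tax), "empty")
})

test_that("estimated abundance tracks the truth on a two-GST community", {
  pipe <- small_pipeline()
  sim <- pipe$sim
  ab <- setNames(c(0.7, 0.3), c("GST01_S01", "GST02_S01"))
  rs <- simulate_reads(sim$genomes, n_reads = 20000, abundances = ab,
                       error_rate = 0, seed = 21)
  prof <- profile_sample(rs$reads, pipe$db, sample_id = "two_gst")
  est <- setNames(prof$relative, prof$gst_id)
  truth <- c("1" = 0.7, "2" = 0.3)
  expect_lt(max(abs(est[names(truth)] - truth)), 0.02)
})
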