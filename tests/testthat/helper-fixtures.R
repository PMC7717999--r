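# Shared fixtures (built once per run) and independent oracles used across
# the suite. Oracles deliberately avoid the package's own code paths.

fixture_env <- new.env()

# 3 GSTs x 4 strains, small genomes: the workhorse community
small_sim <- function() {
  if (is.null(fixture_env$sim)) {
    cfg <- sim_config(seed = 42, genome_length = 60000, n_genes = 50,
                      gene_length_range = c(600, 1000), n_gsts = 3,
                      strains_per_gst = 4, within_gst_snv = 50,
                      between_gst_snv = 3000, accessory_fraction = 0.1)
    fixture_env$sim <- simulate_strain_genomes(cfg)
  }
  fixture_env$sim
}

# reference, SNV sets, distances, GST assignment, taxonomy, k-mer db for it
small_pipeline <- function() {
  if (is.null(fixture_env$pipe)) {
    sim <- small_sim()
    ts <- sim$genomes[sim$genomes$is_type_strain, ]
    ref <- build_core_reference(ts$genes[[1]][sim$truth$core_gene_ids])
    snvs <- lapply(seq_len(nrow(sim$genomes)),
                   function(i) call_snvs(sim$genomes[i, ], ref))
    names(snvs) <- sim$genomes$genome_id
    d <- snv_distance_matrix(snvs)
    prio <- prioritize_genomes(sim$genomes)
    asn <- cluster_gsts(sim$tree, d, threshold = 500, priority = prio)
    tax <- build_taxonomy(sim$tree, asn)
    rep_genes <- lapply(asn$representative, function(g) {
      gs <- sim$genomes$genes[[match(g, sim$genomes$genome_id)]]
      unname(gs[intersect(names(gs), sim$truth$core_gene_ids)])
    })
    db <- build_kmer_db(rep_genes, tax, k = 31)
    fixture_env$pipe <- list(sim = sim, ref = ref, snvs = snvs, d = d,
                             priority = prio, assignment = asn,
                             taxonomy = tax, rep_genes = rep_genes, db = db)
  }
  fixture_env$pipe
}

# ---- oracles --------------------------------------------------------------

# brute-force replay of the greedy sister-clade merging rule, written over a
# recursive leafset representation independent of the implementation
oracle_cluster_gsts <- function(tree, d, threshold, priority) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  leafset <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], leafset), use.names = FALSE)
  }
  parent_of <- function(node) {
    e <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(e)) e else NA_integer_
  }
  clustered <- character(0)
  blocks <- list()
  repeat {
    rem <- priority[!(priority %in% clustered)]
    if (length(rem) == 0) break
    node <- match(rem[1], tree$tip.label)
    repeat {
      p <- parent_of(node)
      if (is.na(p)) break
      lv <- leafset(p)
      if (any(lv %in% clustered)) break
      if (max(d[lv, lv]) >= threshold) break
      node <- p
    }
    lv <- leafset(node)
    blocks[[length(blocks) + 1L]] <- sort(lv)
    clustered <- c(clustered, lv)
  }
  blocks
}

# two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins (same relative-tolerance convention as R)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  xs <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(xs, m, n_, k)
  p0 <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# PERMANOVA pseudo-F via the Gower-centered linear-model route
oracle_permanova_f <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  G <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% G %*% J
  X <- stats::model.matrix(~ factor(labels))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  a <- length(unique(labels))
  ss_a <- sum(diag(H %*% G))
  ss_w <- sum(diag((diag(n) - H) %*% G))
  (ss_a / (a - 1)) / (ss_w / (n - a))
}

# global-alignment identity via Biostrings (equivalent scoring: match +1,
# mismatch -1, linear gap -2)
oracle_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

# Hamming distance computed in plain R
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# all-pairs Hamming distance between full core-gene concatenations, ordered
# lexicographically by family id (mirrors the reference layout)
oracle_core_hamming_matrix <- function(sim) {
  core <- sort(sim$truth$core_gene_ids)
  seqs <- vapply(seq_len(nrow(sim$genomes)), function(i)
    paste(sim$genomes$genes[[i]][core], collapse = ""), character(1))
  n <- length(seqs)
  d <- matrix(0L, n, n,
              dimnames = list(sim$genomes$genome_id, sim$genomes$genome_id))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    d[i, j] <- d[j, i] <- oracle_hamming(seqs[i], seqs[j])
  d
}

# random rooted tree plus random symmetric integer distances, for property
# tests of the clustering rule
random_gst_instance <- function(n_leaves, dmax = 100) {
  tr <- ape::rtree(n_leaves, rooted = TRUE)
  tr$tip.label <- sprintf("g%02d", seq_len(n_leaves))
  d <- matrix(0L, n_leaves, n_leaves,
              dimnames = list(tr$tip.label, tr$tip.label))
  v <- sample.int(dmax, n_leaves * (n_leaves - 1) / 2, replace = TRUE)
  d[upper.tri(d)] <- v
  d <- d + t(d)
  list(tree = tr, d = d, priority = sample(tr$tip.label))
}

# all permutations of a label vector (small n only)
combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in combinat_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# canonical k-mer helpers for brute-force database censuses
revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

canon <- function(s) min(s, revcomp(s))

all_kmers_in_order <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  kms <- substring(seq, 1:(n - k + 1), k:n)
  kms <- kms[!grepl("[^ACGT]", kms)]
  vapply(kms, canon, character(1), USE.NAMES = FALSE)
}

all_canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  kms <- substring(seq, 1:(n - k + 1), k:n)
  kms <- kms[!grepl("[^ACGT]", kms)]
  unique(vapply(kms, canon, character(1), USE.NAMES = FALSE))
}

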