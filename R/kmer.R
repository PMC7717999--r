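#' Build a canonical k-mer LCA database from GST representative core genes
#'
#' Every canonical k-mer (a k-mer and its reverse complement count as one
#' key) occurring in the core genes of any representative genome maps to the
#' lowest common ancestor, in the GST taxonomy, of all GSTs containing it.
#' Sequences shorter than k contribute nothing (with a warning). k must be
#' odd so canonicalization is unambiguous.
#'
#' @param rep_genes named list: GST id (as character) -> character vector of
#'   core gene sequences of that GST's representative genome.
#' @param taxonomy a `gst_taxonomy` from [build_taxonomy()].
#' @param k k-mer length (odd, at most 31).
#' @return object of class `kmer_db` (holds an external pointer; rebuild
#'   rather than serialize).
#' @export
build_kmer_db <- function(rep_genes, taxonomy, k = 31L) {
  stopifnot(inherits(taxonomy, "gst_taxonomy"))
  if (k %% 2 == 0) stop("k must be odd")
  if (k > 31) stop("k must be at most 31")
  gst_ids <- names(rep_genes)
  if (!all(gst_ids %in% names(taxonomy$gst_nodes)))
    stop("rep_genes names GSTs absent from the taxonomy")
  seqs <- unlist(rep_genes, use.names = FALSE)
  nodes <- rep(unname(taxonomy$gst_nodes[gst_ids]),
               vapply(rep_genes, length, integer(1)))
  short <- nchar(seqs) < k
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than k contribute no k-mers")
    seqs <- seqs[!short]; nodes <- nodes[!short]
  }
  parent <- taxonomy_parent_vec(taxonomy)
  ptr <- cpp_kmerdb_build(seqs, as.integer(nodes), as.integer(parent), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), taxonomy = taxonomy),
            class = "kmer_db")
}

#' @export
print.kmer_db <- function(x, ...) {
  cat(sprintf("<kmer_db> k=%d, %s canonical k-mers over %d taxonomy nodes\n",
              x$k, format(cpp_kmerdb_size(x$ptr), big.mark = ","),
              nrow(x$taxonomy$nodes)))
  invisible(x)
}

#' Dump the k-mer -> node map (small databases only)
#'
#' @param db a `kmer_db`.
#' @return tibble with `kmer` and `node_id`.
#' @export
kmer_db_entries <- function(db) {
  as_tibble(cpp_kmerdb_entries(db$ptr, db$k)) |> arrange(.data$kmer)
}

#' Classify reads against a k-mer LCA database
#'
#' For each read, the taxonomy nodes hit by its canonical k-mers are
#' collected; each root-to-leaf path is scored by the sum of hit counts on
#' its nodes, and the read is assigned the deepest node of the
#' maximum-scoring path (ties between equal-scoring paths resolve to the LCA
#' of their deepest nodes). Reads with no database hit — including reads
#' shorter than k — are unclassified. Ambiguous bases break k-mer extraction.
#'
#' @param reads tibble with `read_id` and `seq` (e.g. `read_sim$reads`), or a
#'   named character vector.
#' @param db a `kmer_db`.
#' @return tibble of class `read_assignment`: `read_id`, `node_id` (`NA` =
#'   unclassified), `rank`.
#' @export
classify_reads <- function(reads, db) {
  stopifnot(inherits(db, "kmer_db"))
  if (is.character(reads))
    reads <- tibble(read_id = names(reads) %||% sprintf("read_%07d", seq_along(reads)),
                    seq = unname(reads))
  parent <- taxonomy_parent_vec(db$taxonomy)
  node <- cpp_classify(db$ptr, reads$seq, as.integer(parent), db$k)
  nd <- db$taxonomy$nodes
  out <- tibble(read_id = reads$read_id, node_id = node,
                rank = nd$rank[match(node, nd$node_id)])
  class(out) <- c("read_assignment", class(out))
  out
}

#' Estimate GST abundance from read assignments
#'
#' Direct leaf assignments are kept; reads assigned to internal taxonomy
#' nodes are redistributed to the GST leaves below them proportionally to
#' those leaves' direct-assignment counts (uniformly when every descendant
#' leaf has zero direct counts). Relative abundances are normalized over the
#' GST leaves. This leaf-proportional redistribution is a deliberate
#' simplification of Bracken's Bayesian scheme; it preserves its fixed point
#' when leaf assignments dominate.
#'
#' @param assignments a `read_assignment` from [classify_reads()].
#' @param taxonomy the `gst_taxonomy` of the database.
#' @param sample_id optional sample label carried on the profile.
#' @return tibble of class `abundance_profile`: `gst_id`, `count`
#'   (re-estimated read count), `relative`; attributes `sample_id`,
#'   `n_classified`, `empty`.
#' @export
estimate_abundance <- function(assignments, taxonomy, sample_id = NA_character_) {
  if (nrow(assignments) == 0) stop("assignments are empty")
  classified <- assignments$node_id[!is.na(assignments$node_id)]
  gst_leaf <- taxonomy$gst_nodes           # gst id (chr) -> node id
  gsts <- as.integer(names(gst_leaf))
  if (length(classified) == 0) {
    out <- tibble(gst_id = integer(0), count = numeric(0), relative = numeric(0))
    return(structure(out, class = c("abundance_profile", class(out)),
                     sample_id = sample_id, n_classified = 0L, empty = TRUE))
  }
  direct <- table(factor(classified, levels = sort(unique(taxonomy$nodes$node_id))))
  direct <- setNames(as.numeric(direct), names(direct))
  leaf_counts <- setNames(direct[as.character(gst_leaf)], names(gst_leaf))

  # leaves below each node
  par <- taxonomy_parent_vec(taxonomy)
  below <- function(node) {
    gsts[vapply(gst_leaf, function(lf) node %in% taxonomy_ancestors(taxonomy, lf),
                logical(1))]
  }
  internal <- setdiff(taxonomy$nodes$node_id, unname(gst_leaf))
  for (u in internal) {
    c_u <- direct[[as.character(u)]]
    if (c_u == 0) next
    lv <- below(u)
    ld <- direct[as.character(gst_leaf[as.character(lv)])]
    w <- if (sum(ld) > 0) ld / sum(ld) else rep(1 / length(lv), length(lv))
    leaf_counts[as.character(lv)] <- leaf_counts[as.character(lv)] + c_u * w
  }
  out <- tibble(gst_id = gsts, count = unname(leaf_counts),
                relative = unname(leaf_counts) / sum(leaf_counts)) |>
    filter(.data$count > 0)
  structure(out, class = c("abundance_profile", class(out)),
            sample_id = sample_id, n_classified = length(classified),
            empty = FALSE)
}

#' One-call GST profiling of a read set
#'
#' Classifies the reads and re-estimates GST abundance.
#'
#' @inheritParams classify_reads
#' @inheritParams estimate_abundance
#' @return an `abundance_profile`.
#' @export
profile_sample <- function(reads, db, sample_id = NA_character_) {
  estimate_abundance(classify_reads(reads, db), db$taxonomy, sample_id)
}

#' Write a Kraken-report-style summary of a classified sample
#'
#' Columns: percentage of reads in the clade, clade read count, direct read
#' count, rank code, node id, name (indented by depth).
#'
#' @param assignments a `read_assignment`.
#' @param taxonomy the matching `gst_taxonomy`.
#' @param path output path.
#' @export
write_kraken_report <- function(assignments, taxonomy, path) {
  nd <- taxonomy$nodes
  n_total <- nrow(assignments)
  direct <- table(factor(assignments$node_id, levels = nd$node_id))
  clade <- vapply(nd$node_id, function(u) {
    inside <- vapply(nd$node_id, function(v)
      u %in% taxonomy_ancestors(taxonomy, v), logical(1))
    sum(direct[inside])
  }, numeric(1))
  depth <- vapply(nd$node_id, function(u)
    length(taxonomy_ancestors(taxonomy, u)) - 1L, integer(1))
  rank_code <- c(species = "S", `no rank` = "-", `strain-type` = "T")[nd$rank]
  lines <- sprintf("%6.2f\t%d\t%d\t%s\t%d\t%s%s",
                   100 * clade / max(n_total, 1), clade,
                   as.integer(direct), rank_code, nd$node_id,
                   strrep("  ", depth), nd$name)
  unclassified <- sum(is.na(assignments$node_id))
  lines <- c(sprintf("%6.2f\t%d\t%d\tU\t0\tunclassified",
                     100 * unclassified / max(n_total, 1), unclassified,
                     unclassified), lines)
  writeLines(lines, path)
  invisible(path)
}
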