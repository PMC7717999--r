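#' Cluster tree leaves into genome-based strain types (GSTs)
#'
#' Greedy sister-clade merging under a maximum pairwise SNV distance:
#' starting from the highest-priority unclustered leaf (the type strain on
#' the first round), the current clade is repeatedly replaced by its parent
#' clade — absorbing the sister subtree — as long as every leaf of the
#' enlarged clade is still unclustered and the maximum pairwise SNV distance
#' over the enlarged clade stays strictly below `threshold`. The clade is
#' then frozen as a GST and the procedure restarts from the next unclustered
#' leaf in priority order, until the leaves are partitioned. GST ids follow
#' creation order.
#'
#' @param tree rooted `phylo` tree with genome ids as tip labels; an unrooted
#'   tree is midpoint-rooted.
#' @param d symmetric pairwise SNV distance matrix covering all tips.
#' @param threshold maximum pairwise SNV distance within a GST (strict:
#'   a merge is allowed only when the maximum pair is below this value).
#' @param priority ordered genome ids from [prioritize_genomes()]; must cover
#'   all tips, with the type strain first.
#' @return object of class `gst_assignment`: `membership` (tibble
#'   `genome_id`, `gst_id`), `representative` (named character, GST id ->
#'   genome id), `threshold`, `n_gsts`.
#' @export
cluster_gsts <- function(tree, d, threshold = 20000, priority) {
  tips <- tree$tip.label
  if (!all(tips %in% rownames(d)) || !all(tips %in% colnames(d)))
    stop("distance matrix does not cover all tree leaves")
  if (!all(tips %in% priority)) stop("priority list does not cover all leaves")
  priority <- priority[priority %in% tips]
  if (length(tips) > 2 && !ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)

  if (length(tips) == 1) {
    memb <- tibble(genome_id = tips, gst_id = 1L)
  } else {
    desc <- phangorn::Descendants(tree, type = "tips")
    pvec <- integer(length(tips) + tree$Nnode)
    pvec[tree$edge[, 2]] <- tree$edge[, 1]
    clustered <- character(0)
    blocks <- list()
    while (length(clustered) < length(tips)) {
      seed_id <- priority[!(priority %in% clustered)][1]
      cur <- match(seed_id, tips)
      repeat {
        p <- pvec[cur]
        if (p == 0L) break
        leaves <- tips[desc[[p]]]
        if (any(leaves %in% clustered)) break
        if (length(leaves) > 1 && max(d[leaves, leaves]) >= threshold) break
        cur <- p
      }
      members <- tips[desc[[cur]]]
      blocks[[length(blocks) + 1L]] <- members
      clustered <- c(clustered, members)
    }
    memb <- dplyr::bind_rows(lapply(seq_along(blocks), function(i)
      tibble(genome_id = blocks[[i]], gst_id = i)))
  }
  out <- structure(list(membership = memb,
                        representative = NULL,
                        threshold = threshold,
                        n_gsts = max(memb$gst_id)),
                   class = "gst_assignment")
  out$representative <- select_representatives(out, priority)
  out
}

#' @export
print.gst_assignment <- function(x, ...) {
  cat(sprintf("<gst_assignment> %d genomes in %d GSTs (threshold %s SNVs)\n",
              nrow(x$membership), x$n_gsts, format(x$threshold, big.mark = ",")))
  invisible(x)
}

#' Select the representative genome of each GST
#'
#' The member earliest in the priority order represents its GST.
#'
#' @param assignment a `gst_assignment`.
#' @param priority ordered genome ids, highest priority first.
#' @return named character vector: GST id (as character) -> genome id.
#' @export
select_representatives <- function(assignment, priority) {
  memb <- if (inherits(assignment, "gst_assignment")) assignment$membership else assignment
  rank <- match(memb$genome_id, priority)
  if (anyNA(rank)) stop("priority list does not cover all members")
  memb |>
    mutate(rank = rank) |>
    group_by(.data$gst_id) |>
    summarise(rep = .data$genome_id[which.min(.data$rank)], .groups = "drop") |>
    (\(x) setNames(x$rep, as.character(x$gst_id)))()
}

#' GST membership as a tidy table
#'
#' @param x a `gst_assignment`.
#' @param ... unused.
#' @return tibble with `genome_id`, `gst_id`, `is_representative`.
#' @method tidy gst_assignment
#' @export
tidy.gst_assignment <- function(x, ...) {
  x$membership |>
    mutate(is_representative = .data$genome_id %in% x$representative)
}

#' Build the collapsed taxonomy used for k-mer LCA classification
#'
#' Collapses every GST clade of the phylogeny to a single leaf, suppresses
#' the internal nodes left with a single child, and roots everything under a
#' species node, mirroring the tree topology above the GSTs. Node ids are
#' stable integers (root = 1, breadth-first).
#'
#' @param tree the rooted `phylo` tree the GSTs were clustered on.
#' @param assignment a `gst_assignment`; every GST must be a clade of `tree`.
#' @return object of class `gst_taxonomy`: `nodes` (tibble `node_id`,
#'   `parent_id` (0 for the root), `rank` in species/no rank/strain-type,
#'   `name`, `gst_id`), `gst_nodes` (named integer, GST id -> node id).
#' @export
build_taxonomy <- function(tree, assignment) {
  memb <- assignment$membership
  tips <- tree$tip.label
  n_tip <- length(tips)
  single_leaf <- n_tip == 1
  gsts <- sort(unique(memb$gst_id))

  if (single_leaf) {
    nodes <- tibble(node_id = 1:2, parent_id = c(0L, 1L),
                    rank = c("species", "strain-type"),
                    name = c("species", "GST1"), gst_id = c(NA_integer_, 1L))
    return(structure(list(nodes = nodes, gst_nodes = c("1" = 2L)),
                     class = "gst_taxonomy"))
  }

  desc <- phangorn::Descendants(tree, type = "tips")
  pvec <- integer(n_tip + tree$Nnode)
  pvec[tree$edge[, 2]] <- tree$edge[, 1]
  gst_node <- vapply(gsts, function(g) {
    members <- memb$genome_id[memb$gst_id == g]
    node <- if (length(members) == 1) match(members, tips) else
      ape::getMRCA(tree, members)
    if (!setequal(tips[desc[[node]]], members))
      stop("GST ", g, " is not a clade of the tree")
    node
  }, integer(1))

  # parent chains from each GST node to the tree root, then splice out every
  # internal node that ends up with a single child
  par <- integer(0)   # named: tree-node -> tree-node (0 = above everything)
  for (v in gst_node) {
    u <- v
    while (pvec[u] != 0L && is.na(par[as.character(u)])) {
      par[as.character(u)] <- pvec[u]
      u <- pvec[u]
    }
    if (pvec[u] == 0L) par[as.character(u)] <- 0L
  }
  internal <- setdiff(as.integer(names(par)), gst_node)
  repeat {
    kids <- table(factor(unname(par[par != 0L]), levels = internal))
    unary <- internal[kids <= 1]
    if (length(unary) == 0) break
    for (u in unary) {
      child <- as.integer(names(par)[par == u])
      if (length(child)) par[as.character(child)] <- par[as.character(u)]
      par <- par[names(par) != as.character(u)]
    }
    internal <- setdiff(internal, unary)
  }

  top <- as.integer(names(par)[par == 0L])
  if (top %in% gst_node) {
    # one GST spans the whole tree: keep a species root above the single leaf
    par[as.character(top)] <- -1L
    internal <- c(-1L, internal)
    par <- c(par, setNames(0L, "-1"))
    top <- -1L
  }

  # breadth-first integer ids from the root
  ids <- setNames(integer(0), character(0))
  queue <- top
  nid <- 0L
  order_nodes <- integer(0)
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    nid <- nid + 1L
    ids[as.character(u)] <- nid
    order_nodes <- c(order_nodes, u)
    kids <- as.integer(names(par)[par == u])
    queue <- c(queue, sort(kids))
  }
  nodes <- dplyr::bind_rows(lapply(order_nodes, function(u) {
    is_gst <- u %in% gst_node
    g <- if (is_gst) gsts[match(u, gst_node)] else NA_integer_
    tibble(node_id = ids[[as.character(u)]],
           parent_id = if (par[[as.character(u)]] %in% c(0L))
             0L else ids[[as.character(par[[as.character(u)]])]],
           rank = if (u == top) "species" else if (is_gst) "strain-type" else "no rank",
           name = if (u == top) "species" else if (is_gst) sprintf("GST%d", g)
                  else sprintf("node%d", ids[[as.character(u)]]),
           gst_id = g)
  }))
  gst_ids <- nodes$node_id[!is.na(nodes$gst_id)]
  names(gst_ids) <- as.character(nodes$gst_id[!is.na(nodes$gst_id)])
  structure(list(nodes = nodes, gst_nodes = gst_ids[order(as.integer(names(gst_ids)))]),
            class = "gst_taxonomy")
}

#' @export
print.gst_taxonomy <- function(x, ...) {
  cat(sprintf("<gst_taxonomy> %d nodes, %d GST leaves\n",
              nrow(x$nodes), length(x$gst_nodes)))
  invisible(x)
}

# parent vector indexed by node_id (0 = root's parent)
taxonomy_parent_vec <- function(taxonomy) {
  nd <- taxonomy$nodes[order(taxonomy$nodes$node_id), ]
  nd$parent_id
}

# ancestors of a node, self included, root last
taxonomy_ancestors <- function(taxonomy, node) {
  par <- taxonomy_parent_vec(taxonomy)
  out <- integer(0)
  while (node != 0L) { out <- c(out, node); node <- par[node] }
  out
}

#' Collapse the phylogeny to one tip per GST
#'
#' Keeps the representative tip of each GST and relabels it `GST<g>`,
#' producing the GST-level tree (with the original branch lengths) used for
#' weighted UniFrac.
#'
#' @param tree the `phylo` tree of all genomes.
#' @param assignment a `gst_assignment` with representatives.
#' @return `phylo` tree with tips `GST<g>`.
#' @export
gst_tree <- function(tree, assignment) {
  reps <- assignment$representative
  tr <- ape::keep.tip(tree, unname(reps))
  tr$tip.label <- paste0("GST", names(reps)[match(tr$tip.label, reps)])
  tr
}
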