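#' Filter samples by classification depth and gene hits
#'
#' Keeps samples with at least `min_reads` reads classified to the species
#' (20,000 by default: samples with fewer classified reads are removed) and
#' at least `min_hits` predicted-gene hits against the pan-genome (500 by
#' default).
#'
#' @param samples tibble with `sample_id`, `n_classified`, `n_hits` columns
#'   (see [sample_table()]).
#' @param min_reads,min_hits retention thresholds.
#' @return the retained rows.
#' @export
filter_samples <- function(samples, min_reads = 20000, min_hits = 500) {
  filter(samples, .data$n_classified >= min_reads, .data$n_hits >= min_hits)
}

#' Assemble per-sample profiles into a cohort table
#'
#' @param abundance list of `abundance_profile` objects.
#' @param genes list of `gene_profile` objects (same order).
#' @param host_species optional character vector of host labels.
#' @return tibble with `sample_id`, `host_species`, `n_classified`, `n_hits`
#'   and list-columns `abundance`, `genes`.
#' @export
sample_table <- function(abundance, genes, host_species = NA_character_) {
  stopifnot(length(abundance) == length(genes))
  tibble(
    sample_id = vapply(abundance, function(p) attr(p, "sample_id"), character(1)),
    host_species = rep(host_species, length.out = length(abundance)),
    n_classified = vapply(abundance, function(p) as.numeric(attr(p, "n_classified")),
                          numeric(1)),
    n_hits = vapply(genes, function(g) as.numeric(g$n_hits), numeric(1)),
    abundance = abundance, genes = genes)
}

#' Group samples by their dominant GST
#'
#' Each sample is assigned to the host group of its most abundant GST
#' (argmax ties broken by the smallest GST id and flagged); groups are then
#' dropped unless they contain strictly more than `min_samples` samples.
#'
#' @param abundance long tibble with `sample_id`, `gst_id`, `relative` — use
#'   [abundance_long()] to build one from profiles.
#' @param min_samples strict group-size floor (a group must have more than
#'   this many samples to be kept; default 5).
#' @return list of class `host_groups`: `samples` (tibble `sample_id`,
#'   `dominant_gst`, `tie`, `group_id`, `kept`), `groups` (tibble `group_id`,
#'   `dominant_gst`, `n_samples`, `kept`).
#' @export
assign_host_groups <- function(abundance, min_samples = 5L) {
  dom <- abundance |>
    group_by(.data$sample_id) |>
    summarise(
      dominant_gst = min(.data$gst_id[.data$relative == max(.data$relative)]),
      tie = sum(.data$relative == max(.data$relative)) > 1,
      .groups = "drop") |>
    mutate(group_id = sprintf("HG_GST%d", .data$dominant_gst))
  groups <- dom |>
    group_by(.data$group_id, .data$dominant_gst) |>
    summarise(n_samples = n(), .groups = "drop") |>
    mutate(kept = .data$n_samples > min_samples)
  dom <- left_join(dom, select(groups, "group_id", "kept"), by = "group_id")
  structure(list(samples = dom, groups = groups), class = "host_groups")
}

#' Long abundance table from profiles
#'
#' @param profiles list of `abundance_profile` objects.
#' @return tibble with `sample_id`, `gst_id`, `relative`.
#' @export
abundance_long <- function(profiles) {
  dplyr::bind_rows(lapply(profiles, function(p)
    mutate(as_tibble(p), sample_id = attr(p, "sample_id"), .before = 1)))
}

#' Host-specific gene detection by Fisher's exact test
#'
#' For every (gene cluster, host group) pair a 2x2 presence/absence x
#' in-group/out-group contingency table is tested with the two-sided Fisher's
#' exact test ([stats::fisher.test()], exact hypergeometric). A gene is
#' called specific to the group when p < `alpha` AND its in-group prevalence
#' exceeds its out-group prevalence (a gene depleted in the group is not
#' "specific" to it). No multiple-testing correction is applied by default;
#' `correct = "BH"` switches the cutoff to Benjamini-Hochberg-adjusted
#' p-values. `min_prevalence` optionally drops genes present in fewer
#' samples than the floor before testing.
#'
#' @param presence logical sample-by-cluster matrix (rownames = sample ids),
#'   or a long tibble with `sample_id`, `cluster_id` listing present pairs.
#' @param groups named character vector sample id -> group id, or a
#'   `host_groups` object (kept samples only).
#' @param alpha significance cutoff (default 0.01).
#' @param correct `"none"` (default) or `"BH"`.
#' @param min_prevalence minimum number of samples a gene must be present in
#'   to be tested (default 0 = test everything).
#' @return tibble of class `host_specific_calls`: `cluster_id`, `group_id`,
#'   `a` (in-group present), `b` (in-group absent), `c` (out-group present),
#'   `d` (out-group absent), `p_value`, `specific`.
#' @export
fisher_host_specific <- function(presence, groups, alpha = 0.01,
                                 correct = c("none", "BH"),
                                 min_prevalence = 0L) {
  correct <- match.arg(correct)
  if (inherits(groups, "host_groups")) {
    kept <- groups$samples[groups$samples$kept, ]
    groups <- setNames(kept$group_id, kept$sample_id)
  }
  if (length(unique(groups)) < 2) stop("at least two host groups are required")
  if (!is.matrix(presence)) {
    samples <- sort(unique(presence$sample_id))
    clusters <- sort(unique(presence$cluster_id))
    m <- matrix(FALSE, length(samples), length(clusters),
                dimnames = list(samples, clusters))
    m[cbind(match(presence$sample_id, samples),
            match(presence$cluster_id, clusters))] <- TRUE
    presence <- m
  }
  presence <- presence[rownames(presence) %in% names(groups), , drop = FALSE]
  grp <- groups[rownames(presence)]
  prev <- colSums(presence)
  presence <- presence[, prev >= min_prevalence, drop = FALSE]
  out <- list()
  for (g in sort(unique(grp))) {
    ing <- grp == g
    n_in <- sum(ing); n_out <- sum(!ing)
    a <- colSums(presence[ing, , drop = FALSE])
    c_ <- colSums(presence[!ing, , drop = FALSE])
    b <- n_in - a; d <- n_out - c_
    p <- vapply(seq_along(a), function(i) {
      if (a[i] + c_[i] == 0 || b[i] + d[i] == 0) return(1)
      fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), 2))$p.value
    }, numeric(1))
    p_eff <- if (correct == "BH") stats::p.adjust(p, "BH") else p
    out[[g]] <- tibble(cluster_id = colnames(presence), group_id = g,
                       a = as.integer(a), b = as.integer(b),
                       c = as.integer(c_), d = as.integer(d),
                       p_value = p,
                       specific = p_eff < alpha & (a / n_in > c_ / n_out))
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("host_specific_calls", class(res))
  res
}

#' Weighted UniFrac distance between two GST abundance profiles
#'
#' Raw weighted UniFrac: the sum over branches of branch length times the
#' absolute difference in the fraction of each sample's abundance descending
#' through the branch. `normalized = TRUE` divides by the abundance-weighted
#' total branch length `sum(l_b * (A_b + B_b))`.
#'
#' @param a,b named numeric abundance vectors over the tree's tip labels
#'   (normalized to sum to 1; missing tips count as 0, but every name must be
#'   a tip).
#' @param tree `phylo` tree with branch lengths whose tips cover the GSTs
#'   (e.g. from [gst_tree()]).
#' @param normalized divide by the abundance-weighted tree length.
#' @return non-negative distance.
#' @export
weighted_unifrac <- function(a, b, tree, normalized = FALSE) {
  tips <- tree$tip.label
  if (!all(names(a) %in% tips) || !all(names(b) %in% tips))
    stop("profile names a GST missing from the tree")
  av <- setNames(numeric(length(tips)), tips); av[names(a)] <- a / sum(a)
  bv <- setNames(numeric(length(tips)), tips); bv[names(b)] <- b / sum(b)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  A <- vapply(desc, function(ix) sum(av[ix]), numeric(1))
  B <- vapply(desc, function(ix) sum(bv[ix]), numeric(1))
  len <- tree$edge.length
  d <- sum(len * abs(A - B))
  if (normalized) {
    denom <- sum(len * (A + B))
    d <- if (denom > 0) d / denom else 0
  }
  d
}

#' Jaccard distance between two gene profiles
#'
#' `1 - |A intersect B| / |A union B|`; two empty sets are at distance 0.
#'
#' @param a,b `gene_profile` objects or character vectors of cluster ids.
#' @return distance in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  if (inherits(a, "gene_profile")) a <- a$present
  if (inherits(b, "gene_profile")) b <- b$present
  u <- length(union(a, b))
  if (u == 0) return(0)
  1 - length(intersect(a, b)) / u
}

#' Pairwise sample distance matrix
#'
#' Weighted UniFrac over abundance profiles or Jaccard over gene profiles,
#' for all sample pairs.
#'
#' @param samples a [sample_table()] tibble.
#' @param method `"unifrac"` or `"jaccard"`.
#' @param tree GST tree (required for UniFrac).
#' @param normalized passed to [weighted_unifrac()].
#' @return symmetric matrix with sample ids as dimnames.
#' @export
sample_distance_matrix <- function(samples, method = c("unifrac", "jaccard"),
                                   tree = NULL, normalized = FALSE) {
  method <- match.arg(method)
  n <- nrow(samples)
  d <- matrix(0, n, n, dimnames = list(samples$sample_id, samples$sample_id))
  vecs <- if (method == "unifrac") {
    if (is.null(tree)) stop("UniFrac requires a GST tree")
    lapply(samples$abundance, function(p)
      setNames(p$relative, paste0("GST", p$gst_id)))
  } else {
    lapply(samples$genes, function(g) g$present)
  }
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d[i, j] <- d[j, i] <- if (method == "unifrac")
      weighted_unifrac(vecs[[i]], vecs[[j]], tree, normalized)
    else jaccard_distance(vecs[[i]], vecs[[j]])
  }
  d
}

permanova_f <- function(d2, grp_idx, n_groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in seq_len(n_groups)) {
    ix <- which(grp_idx == g)
    if (length(ix) > 1) {
      sub <- d2[ix, ix]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(ix)
    }
  }
  ss_among <- ss_total - ss_within
  list(f = (ss_among / (n_groups - 1)) / (ss_within / (n - n_groups)),
       ss_among = ss_among, ss_within = ss_within, ss_total = ss_total)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a distance matrix: Anderson's pseudo-F from
#' among/within sums of squared distances, with a free label-permutation
#' null (no strata) and `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`.
#'
#' @param d symmetric distance matrix or `dist`.
#' @param labels group label per sample (in `d`'s row order), at least two
#'   groups with two samples each.
#' @param n_perm number of permutations (default 9999).
#' @param seed optional integer seed for the permutation draw.
#' @return object of class `gst_permanova` with `statistic` (pseudo-F),
#'   `p_value`, `df`, `ss` and the permutation settings; see
#'   [tidy.gst_permanova()].
#' @export
gst_permanova <- function(d, labels, n_perm = 9999, seed = NULL) {
  d <- as.matrix(d)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(d))
  tab <- table(labels)
  if (length(tab) < 2) stop("PERMANOVA requires at least two groups")
  if (any(tab < 2)) stop("every group needs at least two samples")
  n <- nrow(d)
  a <- length(tab)
  grp_idx <- as.integer(factor(labels))
  d2 <- d^2
  obs <- permanova_f(d2, grp_idx, a)
  with_seed(seed, {
    perm_f <- vapply(seq_len(n_perm), function(i)
      permanova_f(d2, sample(grp_idx), a)$f, numeric(1))
    structure(list(statistic = obs$f,
                   p_value = (1 + sum(perm_f >= obs$f)) / (1 + n_perm),
                   df = c(among = a - 1L, within = n - a),
                   ss = c(among = obs$ss_among, within = obs$ss_within,
                          total = obs$ss_total),
                   n = n, n_groups = a, n_perm = n_perm),
              class = "gst_permanova")
  })
}

#' @export
print.gst_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f (df %d, %d), p = %.4g (%d permutations)\n",
              x$statistic, x$df[1], x$df[2], x$p_value, x$n_perm))
  invisible(x)
}

#' Tidy a PERMANOVA fit
#'
#' @param x a `gst_permanova`.
#' @param ... unused.
#' @return `tidy()`: one row per term (group, residual, total) with `df`,
#'   `ss`, `statistic`, `p.value`; `glance()`: a one-row summary.
#' @method tidy gst_permanova
#' @export
tidy.gst_permanova <- function(x, ...) {
  tibble(term = c("group", "residual", "total"),
         df = c(x$df[1], x$df[2], x$n - 1L),
         ss = unname(x$ss),
         statistic = c(x$statistic, NA, NA),
         p.value = c(x$p_value, NA, NA))
}

#' @rdname tidy.gst_permanova
#' @method glance gst_permanova
#' @export
glance.gst_permanova <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         n = x$n, n_groups = x$n_groups, n_perm = x$n_perm)
}

#' Pairwise PERMANOVA between all group pairs
#'
#' @inheritParams gst_permanova
#' @return tibble with `group1`, `group2`, `statistic`, `p.value`.
#' @export
pairwise_permanova <- function(d, labels, n_perm = 9999, seed = NULL) {
  d <- as.matrix(d)
  labels <- as.character(labels)
  gs <- sort(unique(labels))
  combos <- utils::combn(gs, 2, simplify = FALSE)
  dplyr::bind_rows(lapply(combos, function(pr) {
    ix <- labels %in% pr
    fit <- gst_permanova(d[ix, ix], labels[ix], n_perm = n_perm, seed = seed)
    tibble(group1 = pr[1], group2 = pr[2],
           statistic = fit$statistic, p.value = fit$p_value)
  }))
}

#' Principal coordinates of a distance matrix
#'
#' Classical MDS ([stats::cmdscale()]) for ordination plots.
#'
#' @param d symmetric distance matrix.
#' @param k number of axes.
#' @return tibble with `sample_id` and `PCo1..PCok`, with the fraction of
#'   variance per axis in attribute `eig_fraction`.
#' @export
pcoa_coords <- function(d, k = 2) {
  fit <- cmdscale(as.matrix(d), k = k, eig = TRUE)
  out <- as_tibble(fit$points, .name_repair = ~ paste0("PCo", seq_len(k)))
  out <- mutate(out, sample_id = rownames(as.matrix(d)), .before = 1)
  pos <- fit$eig[fit$eig > 0]
  attr(out, "eig_fraction") <- fit$eig[seq_len(k)] / sum(pos)
  out
}
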