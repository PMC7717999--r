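#' Ancestor-aware read-level classification precision
#'
#' The fraction of classified reads assigned to their true GST leaf or to
#' any ancestor of it in the taxonomy. Unclassified reads are excluded from
#' the denominator ("assignments made"); the classified fraction is
#' reported alongside.
#'
#' @param assignments a `read_assignment` from [classify_reads()].
#' @param truth named vector read id -> true GST id, or a tibble with
#'   `read_id` and `gst_id` (or `genome_id` plus `gst` mapping via
#'   `strain_sim$truth$gst`).
#' @param taxonomy the `gst_taxonomy` of the database.
#' @return tibble with one row: `precision`, `classified_fraction`,
#'   `n_reads`, `n_classified`, `n_correct`.
#' @export
read_level_precision <- function(assignments, truth, taxonomy) {
  if (is.data.frame(truth)) truth <- setNames(truth$gst_id, truth$read_id)
  if (!all(assignments$read_id %in% names(truth)))
    stop("truth lacks entries for some classified reads")
  classified <- filter(assignments, !is.na(.data$node_id))
  n_cls <- nrow(classified)
  if (n_cls == 0)
    return(tibble(precision = NA_real_, classified_fraction = 0,
                  n_reads = nrow(assignments), n_classified = 0L, n_correct = 0L))
  anc <- lapply(taxonomy$gst_nodes, function(lf) taxonomy_ancestors(taxonomy, lf))
  true_gst <- as.character(truth[classified$read_id])
  ok <- vapply(seq_len(n_cls), function(i)
    classified$node_id[i] %in% anc[[true_gst[i]]], logical(1))
  tibble(precision = mean(ok),
         classified_fraction = n_cls / nrow(assignments),
         n_reads = nrow(assignments), n_classified = n_cls,
         n_correct = sum(ok))
}

#' Correlation between true and estimated GST abundance
#'
#' Standard Pearson correlation over the union GST universe (GSTs absent
#' from one vector count as 0). A zero-variance vector yields `NA` with a
#' warning.
#'
#' @param estimated an `abundance_profile` or named numeric vector
#'   (GST id -> relative abundance).
#' @param true_abundance named numeric vector of true relative abundances.
#' @return Pearson r.
#' @export
abundance_correlation <- function(estimated, true_abundance) {
  if (inherits(estimated, "abundance_profile"))
    estimated <- setNames(estimated$relative, estimated$gst_id)
  gsts <- union(names(estimated), names(true_abundance))
  e <- setNames(numeric(length(gsts)), gsts); e[names(estimated)] <- estimated
  t_ <- setNames(numeric(length(gsts)), gsts); t_[names(true_abundance)] <- true_abundance
  if (stats::sd(e) == 0 || stats::sd(t_) == 0) {
    warning("zero-variance abundance vector; correlation undefined")
    return(NA_real_)
  }
  cor(e, t_)
}

#' TPR and F1 of a gene presence/absence profile against truth
#'
#' `TPR = TP / (TP + FN)` and `F1 = 2PR / (P + R)` with
#' `P = TP / (TP + FP)` and `R = TPR`, where TP/FP/FN compare the called
#' presence set with the true gene-family content.
#'
#' @param profile a `gene_profile` or character vector of called cluster ids.
#' @param true_content character vector of true cluster ids (nonempty).
#' @return tibble with one row: `tp`, `fp`, `fn`, `precision`, `tpr`, `f1`.
#' @export
gene_profile_tpr_f1 <- function(profile, true_content) {
  if (inherits(profile, "gene_profile")) profile <- profile$present
  if (length(true_content) == 0) stop("empty truth")
  tp <- length(intersect(profile, true_content))
  fp <- length(setdiff(profile, true_content))
  fn <- length(setdiff(true_content, profile))
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  tpr <- tp / (tp + fn)
  f1 <- if (prec + tpr > 0) 2 * prec * tpr / (prec + tpr) else 0
  tibble(tp = tp, fp = fp, fn = fn, precision = prec, tpr = tpr, f1 = f1)
}

#' Gene-profiling accuracy benchmark on a synthetic community
#'
#' End-to-end desk-scale analog of validating gene-composition profiling on
#' simulated metagenomes: per genome and coverage level, pseudo-contigs are
#' formed from Lander-Waterman coverage gaps (contigs >= 500 bp), CDSs are
#' clipped to the contigs (fragments >= 100 bp) and profiled against the
#' pan-genome built from the community's true CDS sets, and TPR/F1 are
#' scored against the genome's true cluster content.
#'
#' @param sim a `strain_sim`.
#' @param pan optionally a pre-built `pan_genome` of the community's true
#'   CDSs (built here when `NULL`).
#' @param coverages numeric vector of fold coverages.
#' @param read_length read length of the coverage model.
#' @param seed integer seed for the coverage draws.
#' @return tibble with `coverage`, `genome_id`, `tp`, `fp`, `fn`,
#'   `precision`, `tpr`, `f1`.
#' @export
gene_profile_benchmark <- function(sim, pan = NULL, coverages = c(5, 10),
                                   read_length = 150L, seed = 1L) {
  stopifnot(inherits(sim, "strain_sim"))
  if (is.null(pan)) pan <- community_pangenome(sim)
  out <- list()
  k <- 0L
  for (cov in coverages) {
    for (i in seq_len(nrow(sim$genomes))) {
      k <- k + 1L
      gid <- sim$genomes$genome_id[i]
      asm <- simulate_contigs(sim$genomes[i, ], coverage = cov,
                              read_length = read_length,
                              seed = seed + 1000L * k)
      prof <- profile_genes(asm$cds, pan, sample_id = gid)
      out[[k]] <- mutate(
        gene_profile_tpr_f1(prof, true_cluster_content(pan, gid)),
        coverage = cov, genome_id = gid, .before = 1)
    }
  }
  dplyr::bind_rows(out)
}

#' Pan-genome of a synthetic community's true CDS sets
#'
#' @param sim a `strain_sim`.
#' @param ... passed to [cluster_genes()].
#' @return a `pan_genome`.
#' @export
community_pangenome <- function(sim, ...) {
  cds <- dplyr::bind_rows(lapply(seq_len(nrow(sim$genomes)), function(i)
    tibble(gene_id = names(sim$genomes$genes[[i]]),
           genome_id = sim$genomes$genome_id[i],
           seq = unname(sim$genomes$genes[[i]]))))
  cluster_genes(cds, ...)
}
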