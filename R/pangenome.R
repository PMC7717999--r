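#' Cluster coding sequences into gene families (90/90 greedy clustering)
#'
#' Greedy incremental clustering of nucleotide CDSs: sequences are processed
#' in order of decreasing length (ties by gene id); each sequence joins the
#' first existing cluster whose representative it matches at `min_id`
#' identity over a global alignment with bidirectional coverage of at least
#' `min_cov` of both sequences, otherwise it founds a new cluster. Identity
#' is matches over alignment columns of a banded global alignment (match +1,
#' mismatch -1, gap -2); bidirectional coverage reduces, for a global
#' alignment, to the shorter sequence being at least `min_cov` of the longer.
#' An exact canonical 15-mer prefilter restricts the candidate
#' representatives.
#'
#' @param cds tibble with `gene_id`, `genome_id`, `seq` columns.
#' @param min_id minimum fractional identity (default 0.90).
#' @param min_cov minimum bidirectional coverage (default 0.90).
#' @return object of class `pan_genome`: `clusters` (tibble `cluster_id`,
#'   `gene_id`, `genome_id`, `is_representative`), `reps` (named character,
#'   cluster id -> representative sequence), `n_genomes`, `summary` (filled
#'   by [label_core_singleton()]), `min_id`, `min_cov`.
#' @export
cluster_genes <- function(cds, min_id = 0.90, min_cov = 0.90) {
  if (nrow(cds) == 0) stop("empty CDS input")
  ord <- order(-nchar(cds$seq), cds$gene_id)
  cds <- cds[ord, ]
  assign <- cpp_cluster_greedy(cds$seq, min_id, min_cov)
  cluster_id <- sprintf("C%05d", assign)
  is_rep <- !duplicated(assign)
  clusters <- tibble(cluster_id = cluster_id,
                     gene_id = cds$gene_id,
                     genome_id = cds$genome_id,
                     is_representative = is_rep)
  reps <- setNames(cds$seq[is_rep], cluster_id[is_rep])
  reps <- reps[order(names(reps))]
  pan <- structure(list(clusters = clusters, reps = reps,
                        n_genomes = dplyr::n_distinct(cds$genome_id),
                        summary = NULL, min_id = min_id, min_cov = min_cov),
                   class = "pan_genome")
  label_core_singleton(pan)
}

#' Label core and singleton gene clusters
#'
#' A cluster is core when its members come from strictly more than
#' `core_fraction` of the genomes ("over 95%" of genomes), and a singleton
#' when it has exactly one member. With more than one genome the two labels
#' are mutually exclusive.
#'
#' @param pan a `pan_genome`.
#' @param n_genomes total number of genomes (defaults to the number seen in
#'   the cluster table).
#' @param core_fraction strict core prevalence threshold (default 0.95).
#' @return the `pan_genome` with its `summary` tibble (`cluster_id`,
#'   `n_members`, `n_genomes`, `core`, `singleton`) refreshed.
#' @export
label_core_singleton <- function(pan, n_genomes = NULL, core_fraction = 0.95) {
  stopifnot(inherits(pan, "pan_genome"))
  n_genomes <- n_genomes %||% pan$n_genomes
  pan$summary <- pan$clusters |>
    group_by(.data$cluster_id) |>
    summarise(n_members = n(),
              n_genomes = dplyr::n_distinct(.data$genome_id),
              .groups = "drop") |>
    mutate(core = .data$n_genomes > core_fraction * !!n_genomes,
           singleton = .data$n_members == 1L)
  pan
}

#' @export
print.pan_genome <- function(x, ...) {
  cat(sprintf("<pan_genome> %d clusters from %d CDSs across %d genomes (%d core, %d singletons)\n",
              length(x$reps), nrow(x$clusters), x$n_genomes,
              sum(x$summary$core), sum(x$summary$singleton)))
  invisible(x)
}

#' Drop clusters contaminated by decoy genomes
#'
#' Stand-in for species-specificity filtering of the pan-genome: any cluster
#' containing a member from one of the decoy (non-target-species) genomes is
#' removed entirely.
#'
#' @param pan a `pan_genome`.
#' @param decoy_genomes character vector of decoy genome ids.
#' @return the filtered `pan_genome`.
#' @export
drop_decoy_clusters <- function(pan, decoy_genomes) {
  bad <- unique(pan$clusters$cluster_id[pan$clusters$genome_id %in% decoy_genomes])
  pan$clusters <- filter(pan$clusters, !(.data$cluster_id %in% bad),
                         !(.data$genome_id %in% decoy_genomes))
  pan$reps <- pan$reps[setdiff(names(pan$reps), bad)]
  pan$n_genomes <- dplyr::n_distinct(pan$clusters$genome_id)
  label_core_singleton(pan)
}

#' Profile the gene content of a sample against the pan-genome
#'
#' Searches each predicted CDS against the cluster representatives; the best
#' hit meeting both the identity and the bidirectional-coverage threshold
#' marks that cluster present in the sample.
#'
#' @param cds tibble with `seq` (and optionally `cds_id`) — e.g. the `cds`
#'   table of [simulate_contigs()] — or a character vector of sequences.
#' @param pan a `pan_genome`.
#' @param min_id,min_cov thresholds (default the pan-genome's own).
#' @param sample_id optional sample label.
#' @return object of class `gene_profile`: `present` (character vector of
#'   cluster ids), `n_hits` (matched CDS count), `hits` (tibble `cds_id`,
#'   `cluster_id`, `identity`), `sample_id`.
#' @export
profile_genes <- function(cds, pan, min_id = NULL, min_cov = NULL,
                          sample_id = NA_character_) {
  stopifnot(inherits(pan, "pan_genome"))
  min_id <- min_id %||% pan$min_id
  min_cov <- min_cov %||% pan$min_cov
  if (is.character(cds))
    cds <- tibble(cds_id = names(cds) %||% sprintf("cds%05d", seq_along(cds)),
                  seq = unname(cds))
  if (!"cds_id" %in% names(cds))
    cds <- mutate(cds, cds_id = sprintf("cds%05d", dplyr::row_number()))
  if (nrow(cds) == 0) {
    return(structure(list(present = character(0), n_hits = 0L,
                          hits = tibble(cds_id = character(0),
                                        cluster_id = character(0),
                                        identity = numeric(0)),
                          sample_id = sample_id), class = "gene_profile"))
  }
  res <- cpp_best_hit(cds$seq, unname(pan$reps), min_id, min_cov)
  hit <- res$index > 0
  hits <- tibble(cds_id = cds$cds_id[hit],
                 cluster_id = names(pan$reps)[res$index[hit]],
                 identity = res$identity[hit])
  structure(list(present = sort(unique(hits$cluster_id)),
                 n_hits = sum(hit),
                 hits = hits,
                 sample_id = sample_id), class = "gene_profile")
}

#' @export
print.gene_profile <- function(x, ...) {
  cat(sprintf("<gene_profile> sample %s: %d clusters present (%d CDS hits)\n",
              x$sample_id, length(x$present), x$n_hits))
  invisible(x)
}

#' True cluster content of a clustered genome
#'
#' Maps a genome's true gene families to pan-genome cluster ids via the
#' cluster membership of that genome's own CDSs — the ground-truth presence
#' set that gene profiles are evaluated against.
#'
#' @param pan a `pan_genome` built from the genomes' true CDS sets.
#' @param genome_id genome id.
#' @return character vector of cluster ids.
#' @export
true_cluster_content <- function(pan, genome_id) {
  sort(unique(pan$clusters$cluster_id[pan$clusters$genome_id == genome_id]))
}
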