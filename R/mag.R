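#' Quality tier of a metagenome-assembled genome
#'
#' High quality requires completeness strictly above 90% and contamination
#' below 5%; medium quality requires completeness of at least 50% and
#' contamination below 10%; everything else is rejected. Completeness and
#' contamination are inputs (estimated upstream, e.g. by marker-gene tools),
#' not computed here.
#'
#' @param completeness numeric vector, percent in `[0, 100]`.
#' @param contamination numeric vector, percent `>= 0`.
#' @return character vector over `"high"`, `"medium"`, `"rejected"`.
#' @export
tier_mag_quality <- function(completeness, contamination) {
  stopifnot(all(completeness >= 0 & completeness <= 100),
            all(contamination >= 0))
  dplyr::case_when(
    completeness > 90 & contamination < 5 ~ "high",
    completeness >= 50 & contamination < 10 ~ "medium",
    .default = "rejected")
}

chop_fragments <- function(seq, fragment) {
  L <- nchar(seq)
  n <- L %/% fragment
  if (n == 0) return(character(0))
  starts <- (seq_len(n) - 1L) * fragment + 1L
  substring(seq, starts, starts + fragment - 1L)
}

#' Species assignment by fragment-based average nucleotide identity (ANI)
#'
#' Both genomes are cut into consecutive fixed-length fragments (1,020 bp by
#' default); each fragment is matched to its best-aligning fragment of the
#' other genome, and ANI is the mean identity over reciprocal best pairs.
#' The MAG is assigned to the species when ANI exceeds `threshold` percent.
#' When no fragment pair is alignable the ANI is undefined and the MAG is
#' not a member.
#'
#' @param mag_seq MAG sequence (concatenated contigs are fine).
#' @param ref_seq type-strain genome sequence.
#' @param threshold percent ANI above which the MAG belongs to the species.
#' @param fragment fragment length in bp.
#' @return list: `ani` (percent, `NA` if undefined), `member` (logical),
#'   `n_pairs` (reciprocal best fragment pairs used).
#' @export
assign_species_by_ani <- function(mag_seq, ref_seq, threshold = 95,
                                  fragment = 1020L) {
  if (nchar(mag_seq) == 0 || nchar(ref_seq) == 0) stop("empty sequence")
  fa <- chop_fragments(mag_seq, fragment)
  fb <- chop_fragments(ref_seq, fragment)
  if (length(fa) == 0 || length(fb) == 0)
    return(list(ani = NA_real_, member = FALSE, n_pairs = 0L))
  ab <- cpp_best_hit(fa, fb, min_id = 0, min_cov = 0.9)
  ba <- cpp_best_hit(fb, fa, min_id = 0, min_cov = 0.9)
  recip <- which(ab$index > 0 & ba$index[pmax(ab$index, 1)] == seq_along(fa))
  if (length(recip) == 0)
    return(list(ani = NA_real_, member = FALSE, n_pairs = 0L))
  ids <- (ab$identity[recip] + ba$identity[ab$index[recip]]) / 2
  ani <- 100 * mean(ids)
  list(ani = ani, member = ani > threshold, n_pairs = length(recip))
}

#' Place a MAG among the GSTs by covered-position SNV distance
#'
#' Computes the mean pairwise SNV distance — restricted to core-reference
#' positions the MAG actually covers — between the MAG and the members of
#' each GST, and attaches the MAG to the minimizing GST. When even the
#' minimum exceeds the GST threshold scaled by the covered fraction, the MAG
#' is reported as lying outside all GSTs (a novel lineage). MAGs covering
#' less than 10% of the core reference are refused.
#'
#' @param mag_snvs `snv_set` of the MAG against the shared core reference
#'   (missing core genes recorded by [call_snvs()]).
#' @param assignment a `gst_assignment`.
#' @param reference_snvs named list of `snv_set`s for the reference genomes.
#' @param threshold the GST SNV threshold (scaled by the covered fraction).
#' @return object of class `mag_placement`: `mag_id`, `gst_id` (`NA` when
#'   outside), `outside`, `covered_fraction`, `distances` (tibble `gst_id`,
#'   `mean_snv`).
#' @export
place_mag <- function(mag_snvs, assignment, reference_snvs, threshold = 20000) {
  stopifnot(inherits(mag_snvs, "snv_set"))
  ref_len <- attr(mag_snvs, "reference_length")
  covered <- 1 - length(missing_positions(mag_snvs)) / ref_len
  if (covered < 0.1)
    stop("MAG covers less than 10% of the core reference; placement refused")
  memb <- assignment$membership
  dists <- memb |>
    mutate(d = vapply(.data$genome_id, function(g)
      snv_distance(mag_snvs, reference_snvs[[g]]), numeric(1))) |>
    group_by(.data$gst_id) |>
    summarise(mean_snv = mean(.data$d), .groups = "drop")
  best <- which.min(dists$mean_snv)
  outside <- dists$mean_snv[best] > threshold * covered
  structure(list(mag_id = attr(mag_snvs, "genome_id"),
                 gst_id = if (outside) NA_integer_ else dists$gst_id[best],
                 outside = outside,
                 covered_fraction = covered,
                 distances = dists), class = "mag_placement")
}

#' @export
print.mag_placement <- function(x, ...) {
  cat(sprintf("<mag_placement> %s: %s (%.0f%% of core covered)\n",
              x$mag_id,
              if (x$outside) "outside all GSTs" else paste0("GST", x$gst_id),
              100 * x$covered_fraction))
  invisible(x)
}

#' Identify MAG genes absent from the pan-genome
#'
#' Genes failing the identity/coverage match against every pan-genome
#' representative are unmatched; unmatched genes are clustered at the same
#' thresholds into novel gene families. A novel family whose representative
#' nevertheless matches a cluster already present in the sample's gene
#' profile is excluded (guards against border-line duplicates).
#'
#' @param mag_cds named character vector of MAG CDS sequences (>= 100 bp).
#' @param pan a `pan_genome`.
#' @param sample_profile optional `gene_profile` of the MAG's source sample.
#' @param min_id,min_cov thresholds (default the pan-genome's own).
#' @return object of class `novel_gene_set`: `unmatched` (character gene
#'   ids), `clusters` (tibble `novel_cluster_id`, `gene_id`,
#'   `is_representative`).
#' @export
identify_novel_genes <- function(mag_cds, pan, sample_profile = NULL,
                                 min_id = NULL, min_cov = NULL) {
  stopifnot(inherits(pan, "pan_genome"))
  min_id <- min_id %||% pan$min_id
  min_cov <- min_cov %||% pan$min_cov
  if (is.null(names(mag_cds))) names(mag_cds) <- sprintf("mag_cds%05d", seq_along(mag_cds))
  hit <- cpp_best_hit(unname(mag_cds), unname(pan$reps), min_id, min_cov)
  unmatched <- names(mag_cds)[hit$index == 0]
  if (length(unmatched) == 0) {
    return(structure(list(unmatched = character(0),
                          clusters = tibble(novel_cluster_id = character(0),
                                            gene_id = character(0),
                                            is_representative = logical(0))),
                     class = "novel_gene_set"))
  }
  seqs <- mag_cds[unmatched]
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  assign <- cpp_cluster_greedy(unname(seqs), min_id, min_cov)
  clusters <- tibble(novel_cluster_id = sprintf("N%04d", assign),
                     gene_id = names(seqs),
                     is_representative = !duplicated(assign))
  if (!is.null(sample_profile) && length(sample_profile$present) > 0) {
    reps <- clusters$gene_id[clusters$is_representative]
    chk <- cpp_best_hit(unname(mag_cds[reps]),
                        unname(pan$reps[sample_profile$present]),
                        min_id, min_cov)
    drop_ids <- unique(clusters$novel_cluster_id[clusters$is_representative][chk$index > 0])
    clusters <- filter(clusters, !(.data$novel_cluster_id %in% drop_ids))
  }
  structure(list(unmatched = unmatched, clusters = clusters),
            class = "novel_gene_set")
}
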