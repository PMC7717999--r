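#' Prioritize isolate genomes by assembly quality
#'
#' Orders a genome collection by assembly level (complete, then
#' chromosome-level, then everything else), breaking ties by descending N50
#' and finally by genome id, so the order is a deterministic total order.
#' The head of this order seeds GST clustering and picks representatives.
#'
#' @param genomes tibble with `genome_id`, `assembly_level` (one of
#'   `"complete"`, `"chromosome"`, `"other"`) and `n50` columns.
#' @return character vector of genome ids, highest priority first.
#' @export
prioritize_genomes <- function(genomes) {
  stopifnot(nrow(genomes) > 0)
  lev <- match(genomes$assembly_level, c("complete", "chromosome", "other"))
  if (anyNA(lev)) stop("assembly_level must be complete/chromosome/other")
  genomes$genome_id[order(lev, -genomes$n50, genomes$genome_id)]
}

#' Build the concatenated core-genome reference
#'
#' Concatenates the type strain's core genes (lexicographic order by gene
#' family id, for determinism) into a single species-specific reference
#' sequence and records each gene's 1-based start offset.
#'
#' @param core_genes named character vector: gene family id -> gene sequence
#'   of the type strain.
#' @return list of class `core_reference`: `core_gene_ids`, `sequence`,
#'   `gene_offsets` (named integer, 1-based inclusive starts), `gene_lengths`.
#' @export
build_core_reference <- function(core_genes) {
  if (length(core_genes) == 0) stop("empty core gene set")
  if (is.null(names(core_genes))) stop("core genes must be named by family id")
  core_genes <- core_genes[order(names(core_genes))]
  len <- nchar(core_genes)
  offsets <- cumsum(c(1L, len[-length(len)]))
  structure(list(
    core_gene_ids = names(core_genes),
    sequence = paste(core_genes, collapse = ""),
    gene_offsets = setNames(as.integer(offsets), names(core_genes)),
    gene_lengths = setNames(as.integer(len), names(core_genes))),
    class = "core_reference")
}

#' Call SNVs of a genome against the core reference
#'
#' Compares the genome's copy of each core gene with the reference copy by
#' exact per-gene anchoring (generator-tagged gene ids; substitution-only
#' evolution guarantees equal lengths) and reports substitution positions in
#' reference coordinates. Core genes absent from the genome contribute no
#' variants and are recorded as missing, not treated as SNVs.
#'
#' @param genome a one-row slice of `strain_sim$genomes`, or a list with
#'   `genome_id` and `genes` (named character vector).
#' @param reference a [build_core_reference()] object.
#' @return tibble of class `snv_set` with `position` (1-based on the
#'   reference), `ref`, `alt`; attributes `genome_id`, `missing_genes`,
#'   `reference_length`.
#' @export
call_snvs <- function(genome, reference) {
  stopifnot(inherits(reference, "core_reference"))
  if (is.data.frame(genome)) {
    stopifnot(nrow(genome) == 1)
    genome <- list(genome_id = genome$genome_id[1], genes = genome$genes[[1]])
  }
  out <- list()
  missing <- character(0)
  for (g in reference$core_gene_ids) {
    if (!(g %in% names(genome$genes))) { missing <- c(missing, g); next }
    gseq <- genome$genes[[g]]
    rseq_start <- reference$gene_offsets[[g]]
    rseq <- substring(reference$sequence, rseq_start,
                      rseq_start + reference$gene_lengths[[g]] - 1L)
    if (nchar(gseq) != nchar(rseq))
      stop("core gene ", g, " length differs from the reference copy; ",
           "per-gene anchoring requires indel-free core genes")
    a <- strsplit(rseq, "", fixed = TRUE)[[1]]
    b <- strsplit(gseq, "", fixed = TRUE)[[1]]
    diff <- which(a != b)
    if (length(diff))
      out[[g]] <- tibble(position = rseq_start + diff - 1L,
                         ref = a[diff], alt = b[diff])
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble(position = integer(0), ref = character(0), alt = character(0))
  res <- dplyr::arrange(res, .data$position)
  structure(res, class = c("snv_set", class(res)),
            genome_id = genome$genome_id,
            missing_genes = missing,
            reference_length = nchar(reference$sequence),
            gene_offsets = reference$gene_offsets,
            gene_lengths = reference$gene_lengths)
}

# positions of the reference covered by genes missing in an snv_set
missing_positions <- function(snv) {
  mg <- attr(snv, "missing_genes")
  if (length(mg) == 0) return(integer(0))
  off <- attr(snv, "gene_offsets")[mg]
  len <- attr(snv, "gene_lengths")[mg]
  unlist(Map(function(o, l) seq.int(o, o + l - 1L), off, len), use.names = FALSE)
}

#' Pairwise SNV distance between two genomes
#'
#' Counts reference positions where the two genomes carry different alleles:
#' the symmetric difference of their variant position sets, with a position
#' where both genomes vary but to different alternate bases counted once.
#' Positions inside core genes missing from either genome are excluded
#' (absence is not a single-nucleotide variation).
#'
#' @param a,b `snv_set` objects from [call_snvs()] against the same reference.
#' @return integer SNV distance.
#' @export
snv_distance <- function(a, b) {
  stopifnot(inherits(a, "snv_set"), inherits(b, "snv_set"))
  if (!identical(attr(a, "reference_length"), attr(b, "reference_length")))
    stop("SNV sets were called against different references")
  excl <- unique(c(missing_positions(a), missing_positions(b)))
  pa <- setNames(a$alt, a$position)
  pb <- setNames(b$alt, b$position)
  if (length(excl)) {
    pa <- pa[!(as.integer(names(pa)) %in% excl)]
    pb <- pb[!(as.integer(names(pb)) %in% excl)]
  }
  common <- intersect(names(pa), names(pb))
  only_a <- setdiff(names(pa), common)
  only_b <- setdiff(names(pb), common)
  length(only_a) + length(only_b) + sum(pa[common] != pb[common])
}

#' All-against-all SNV distance matrix
#'
#' @param snvs named list of `snv_set` objects (same reference).
#' @return symmetric integer matrix with genome ids as dimnames.
#' @export
snv_distance_matrix <- function(snvs) {
  ids <- names(snvs) %||% vapply(snvs, attr, character(1), "genome_id")
  n <- length(snvs)
  d <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d[i, j] <- d[j, i] <- snv_distance(snvs[[i]], snvs[[j]])
  }
  d
}

#' Neighbor-joining tree from an SNV distance matrix
#'
#' Convenience for synthetic pipelines (maximum-likelihood inference is out
#' of scope): builds a neighbor-joining tree with [ape::nj()] and roots it at
#' the midpoint, as greedy clade merging requires a rooted tree.
#'
#' @param d symmetric distance matrix with genome ids as dimnames.
#' @return a rooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  tr <- ape::nj(stats::as.dist(d))
  phangorn::midpoint(tr)
}
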