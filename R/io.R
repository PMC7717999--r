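#' Read and write sequence files
#'
#' Thin wrappers over Biostrings for the plain-text formats the pipeline
#' exchanges: FASTA for genomes/contigs/CDSs, FASTQ for reads (constant Q30
#' qualities on write), Newick for trees, and TSV for tables.
#'
#' @param path file path.
#' @return `read_fasta()` returns a named character vector; `read_fastq()` a
#'   tibble with `read_id` and `seq`.
#' @name io
NULL

#' @rdname io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname io
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname io
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(x), seq = as.character(x))
}

#' @rdname io
#' @param reads tibble with `read_id` and `seq` (e.g. from [simulate_reads()]).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  qual <- Biostrings::BStringSet(strrep("?", nchar(reads$seq))) # constant Q30
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname io
#' @param x a data frame.
#' @export
write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_tsv_file <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Export a distance matrix
#'
#' Writes a symmetric distance matrix either as a square PHYLIP file or as a
#' TSV with row/column ids.
#'
#' @param d symmetric numeric matrix with dimnames.
#' @param path output path.
#' @param format `"phylip"` or `"tsv"`.
#' @export
write_distance_matrix <- function(d, path, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  if (format == "phylip") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d)))
      writeLines(paste(c(sprintf("%-10s", rownames(d)[i]),
                         format(d[i, ], trim = TRUE)), collapse = " "), con)
  } else {
    out <- data.frame(id = rownames(d), d, check.names = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Export a taxonomy in a Kraken-style nodes/names dialect
#'
#' Writes `nodes.dmp` (node id, parent id, rank) and `names.dmp` (node id,
#' name) for a GST taxonomy. Ranks are `species` for the root, `strain-type`
#' for GST leaves and `no rank` for internal nodes.
#'
#' @param taxonomy a `gst_taxonomy` from [build_taxonomy()].
#' @param dir output directory (created if missing).
#' @export
write_taxonomy <- function(taxonomy, dir) {
  stopifnot(inherits(taxonomy, "gst_taxonomy"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nd <- taxonomy$nodes
  nodes <- sprintf("%d\t|\t%d\t|\t%s\t|", nd$node_id,
                   ifelse(nd$parent_id == 0L, nd$node_id, nd$parent_id),
                   nd$rank)
  names <- sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", nd$node_id, nd$name)
  writeLines(nodes, file.path(dir, "nodes.dmp"))
  writeLines(names, file.path(dir, "names.dmp"))
  invisible(dir)
}
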