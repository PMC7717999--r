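#' Simulation configuration for synthetic strain communities
#'
#' Bundles and validates the knobs of the synthetic-data generator. The
#' defaults reproduce the package's desk-scale validation design: 12 distinct
#' strain genomes (one per GST) of ~0.5 Mb with ~400 genes each, clonal
#' within-type structure (at most `within_gst_snv` pairwise SNVs inside a
#' type) and well-separated types (at least `between_gst_snv` SNVs across
#' types).
#'
#' @param seed integer seed driving every random choice of the generator.
#' @param genome_length target ancestral genome length in bp (genes plus
#'   intergenic spacers).
#' @param n_genes number of ancestral gene families.
#' @param gene_length_range length-2 integer vector, min/max gene length (bp).
#' @param n_gsts number of genome-based strain types (GSTs) to simulate.
#' @param strains_per_gst number of strain genomes descending from each GST
#'   ancestor.
#' @param within_gst_snv maximum pairwise SNV distance inside one GST; each
#'   strain receives `floor(within_gst_snv/2)` private substitutions.
#' @param between_gst_snv minimum pairwise SNV distance between strains of
#'   different GSTs.
#' @param accessory_fraction fraction of ancestral genes in the accessory
#'   pool; drives per-strain gene loss and per-GST/per-strain gene gain.
#' @param read_length simulated read length in bp.
#' @param error_rate per-base substitution error probability of simulated
#'   reads (must be < 0.05).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 500000L,
                       n_genes = 400L,
                       gene_length_range = c(600L, 1200L),
                       n_gsts = 12L,
                       strains_per_gst = 1L,
                       within_gst_snv = 100L,
                       between_gst_snv = 5000L,
                       accessory_fraction = 0.05,
                       read_length = 150L,
                       error_rate = 0.005) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              n_gsts = as.integer(n_gsts),
              strains_per_gst = as.integer(strains_per_gst),
              within_gst_snv = as.integer(within_gst_snv),
              between_gst_snv = as.integer(between_gst_snv),
              accessory_fraction = accessory_fraction,
              read_length = as.integer(read_length),
              error_rate = error_rate)
  stopifnot(length(cfg$gene_length_range) == 2,
            cfg$gene_length_range[1] <= cfg$gene_length_range[2],
            cfg$n_genes >= 1, cfg$n_gsts >= 1, cfg$strains_per_gst >= 1,
            cfg$read_length >= 1)
  if (cfg$within_gst_snv >= cfg$between_gst_snv)
    stop("within_gst_snv must be smaller than between_gst_snv")
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.05)
    stop("error_rate must be in [0, 0.05)")
  if (cfg$genome_length < cfg$n_genes * cfg$gene_length_range[1])
    stop("genome_length too small for n_genes genes of minimum length")
  structure(cfg, class = "sim_config")
}

mutate_gene <- function(seq, pos, alt) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  s[pos] <- alt
  paste(s, collapse = "")
}

#' Simulate a collection of clonal strain genomes with known truth
#'
#' Generates one ancestral genome of `n_genes` genes, evolves `n_gsts` GST
#' ancestors separated by at least `between_gst_snv` substitutions for every
#' cross-type pair (substitutions are planted at globally disjoint positions,
#' so pairwise SNV distances are exact sums of private substitution counts),
#' then derives `strains_per_gst` strains per type, each with
#' `floor(within_gst_snv/2)` private substitutions. Accessory-gene turnover
#' adds per-GST private gene families (the host-specific gene truth), one
#' private singleton gene per strain, and per-strain loss of accessory-pool
#' genes. Substitutions land only in stable (never-lost) genes, so SNV
#' distance equals Hamming distance on the shared core genes. No indels are
#' introduced.
#'
#' @param config a [sim_config()].
#' @return A list of class `strain_sim` with elements:
#'   * `genomes`: tibble with `genome_id`, `gst_id`, `assembly_level`, `n50`,
#'     `host_source`, `is_type_strain`, `sequence`, and list-columns `genes`
#'     (named gene sequences) and `gene_coords` (per-gene intervals on the
#'     genome);
#'   * `tree`: the true `phylo` tree mirroring the simulated branching, branch
#'     lengths in substitution counts;
#'   * `truth`: list with `gst` (genome -> GST id), `gene_content` (genome ->
#'     character vector of true gene-family ids), `mutation_log` (tibble of
#'     planted substitutions relative to the ancestor), `core_gene_ids`
#'     (stable families present in every genome), and `ancestral_genes`
#'     (named character vector of ancestral gene sequences).
#' @export
simulate_strain_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_genes <- config$n_genes
    gene_ids <- sprintf("fam%04d", seq_len(n_genes))
    gene_len <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                       n_genes, replace = TRUE)
    if (sum(gene_len) > config$genome_length)
      stop("drawn gene lengths exceed genome_length; increase genome_length")
    anc_genes <- setNames(vapply(gene_len, random_dna, character(1)), gene_ids)

    # intergenic spacers distribute the slack across n_genes + 1 slots
    slack <- config$genome_length - sum(gene_len)
    cuts <- sort(sample.int(slack + 1L, n_genes, replace = TRUE) - 1L)
    spacer_len <- diff(c(0L, cuts, slack))
    spacers <- vapply(spacer_len, function(n) if (n > 0) random_dna(n) else "",
                      character(1))

    # accessory pool: genes subject to loss; the rest are stable and receive
    # all planted substitutions
    n_acc <- round(config$accessory_fraction * n_genes)
    acc_pool <- if (n_acc > 0) sort(sample(gene_ids, n_acc)) else character(0)
    stable_ids <- setdiff(gene_ids, acc_pool)
    stable_len <- gene_len[match(stable_ids, gene_ids)]
    stable_total <- sum(stable_len)

    n_strain <- config$n_gsts * config$strains_per_gst
    m_between <- if (config$n_gsts > 1) as.integer(ceiling(config$between_gst_snv / 2)) else 0L
    m_within <- as.integer(floor(config$within_gst_snv / 2))
    n_needed <- config$n_gsts * m_between + n_strain * m_within
    if (n_needed > stable_total)
      stop("infeasible SNV budget: ", n_needed, " substitutions needed but only ",
           stable_total, " stable core positions available")

    # globally disjoint substitution positions => exact pairwise distances
    global_pos <- sample.int(stable_total, n_needed)
    cum <- cumsum(stable_len)
    pos_gene <- findInterval(global_pos - 1L, c(0L, cum), rightmost.closed = FALSE)
    pos_in_gene <- global_pos - c(0L, cum)[pos_gene]
    take <- 0L
    next_muts <- function(k) {
      if (k == 0) return(tibble(gene_id = character(0), pos = integer(0),
                                ref = character(0), alt = character(0)))
      sel <- take + seq_len(k)
      take <<- take + k
      gid <- stable_ids[pos_gene[sel]]
      p <- pos_in_gene[sel]
      ref <- substring(anc_genes[gid], p, p)
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    character(1), USE.NAMES = FALSE)
      tibble(gene_id = gid, pos = as.integer(p), ref = unname(ref), alt = alt)
    }
    gst_muts <- lapply(seq_len(config$n_gsts), function(g) next_muts(m_between))

    hosts <- rep(c("pig", "mouse", "dog", "human", "chicken", "herbivore"),
                 length.out = config$n_gsts)
    n_loss <- floor(n_acc / 2)
    n_gain_gst <- max(1L, floor(n_acc / 2))

    gst_gains <- lapply(seq_len(config$n_gsts), function(g) {
      ids <- sprintf("fam_g%02d_%03d", g, seq_len(n_gain_gst))
      setNames(vapply(sample(seq(config$gene_length_range[1],
                                 config$gene_length_range[2]), n_gain_gst,
                            replace = TRUE), random_dna, character(1)), ids)
    })

    genomes <- list()
    mut_log <- list()
    gene_content <- list()
    tip_branches <- list()
    idx <- 0L
    for (g in seq_len(config$n_gsts)) {
      for (s in seq_len(config$strains_per_gst)) {
        idx <- idx + 1L
        gid <- sprintf("GST%02d_S%02d", g, s)
        own <- next_muts(m_within)
        muts <- dplyr::bind_rows(
          dplyr::mutate(gst_muts[[g]], level = "gst"),
          dplyr::mutate(own, level = "strain"))
        lost <- if (n_loss > 0) sort(sample(acc_pool, n_loss)) else character(0)
        own_gain_id <- sprintf("fam_%s_p01", gid)
        own_gain <- setNames(random_dna(sample(seq(config$gene_length_range[1],
                                                   config$gene_length_range[2]), 1)),
                             own_gain_id)
        genes <- anc_genes
        if (nrow(muts) > 0) {
          for (gn in unique(muts$gene_id)) {
            mm <- muts[muts$gene_id == gn, ]
            genes[[gn]] <- mutate_gene(genes[[gn]], mm$pos, mm$alt)
          }
        }
        genes <- genes[setdiff(names(genes), lost)]
        genes <- c(genes, gst_gains[[g]], own_gain)
        # layout: ancestral gene order with original spacers (lost genes leave
        # their spacers in place), gains appended with short spacers
        parts <- character(0)
        coords <- list()
        at <- 0L
        for (j in seq_len(n_genes)) {
          parts <- c(parts, spacers[j]); at <- at + spacer_len[j]
          gn <- gene_ids[j]
          if (gn %in% names(genes)) {
            parts <- c(parts, genes[[gn]])
            coords[[length(coords) + 1L]] <-
              tibble(gene_id = gn, start = at + 1L, end = at + nchar(genes[[gn]]))
            at <- at + nchar(genes[[gn]])
          }
        }
        parts <- c(parts, spacers[n_genes + 1L]); at <- at + spacer_len[n_genes + 1L]
        for (gn in c(names(gst_gains[[g]]), own_gain_id)) {
          sp <- random_dna(25L)
          parts <- c(parts, sp, genes[[gn]])
          at <- at + 25L
          coords[[length(coords) + 1L]] <-
            tibble(gene_id = gn, start = at + 1L, end = at + nchar(genes[[gn]]))
          at <- at + nchar(genes[[gn]])
        }
        genomes[[idx]] <- tibble(
          genome_id = gid, gst_id = g,
          host_source = hosts[g],
          is_type_strain = idx == 1L,
          sequence = paste(parts, collapse = ""),
          genes = list(genes),
          gene_coords = list(dplyr::bind_rows(coords)))
        mut_log[[idx]] <- dplyr::mutate(muts, genome_id = gid, .before = 1)
        gene_content[[gid]] <- sort(names(genes))
        tip_branches[[idx]] <- list(gst = g, label = gid, bl = m_within)
      }
    }
    genomes <- dplyr::bind_rows(genomes)

    # assembly metadata: the type strain is the best assembly, the rest get
    # distinct (level, N50) pairs so the priority order is unambiguous
    nG <- nrow(genomes)
    lev <- rep(c("chromosome", "other", "complete"), length.out = max(nG - 1L, 0L))
    genomes$assembly_level <- c("complete", lev)[seq_len(nG)]
    genomes$n50 <- c(config$genome_length + 1000L,
                     config$genome_length - 131L * seq_len(max(nG - 1L, 0L)))[seq_len(nG)]

    # true tree: root -> GST ancestors -> strains (singleton GSTs collapse)
    gst_newick <- vapply(seq_len(config$n_gsts), function(g) {
      labs <- genomes$genome_id[genomes$gst_id == g]
      if (length(labs) == 1) sprintf("%s:%d", labs, m_between + m_within)
      else sprintf("(%s):%d",
                   paste(sprintf("%s:%d", labs, m_within), collapse = ","),
                   m_between)
    }, character(1))
    tree <- if (nG == 1) {
      ape::read.tree(text = sprintf("(%s);", gst_newick[1]))
    } else {
      ape::read.tree(text = sprintf("(%s);", paste(gst_newick, collapse = ",")))
    }

    structure(list(
      genomes = genomes,
      tree = tree,
      config = config,
      truth = list(
        gst = setNames(genomes$gst_id, genomes$genome_id),
        gene_content = gene_content,
        mutation_log = dplyr::bind_rows(mut_log),
        core_gene_ids = stable_ids,
        accessory_pool = acc_pool,
        ancestral_genes = anc_genes)), class = "strain_sim")
  })
}

#' @export
print.strain_sim <- function(x, ...) {
  cat(sprintf("<strain_sim> %d genomes in %d GSTs; %d ancestral gene families (%d stable)\n",
              nrow(x$genomes), x$config$n_gsts, x$config$n_genes,
              length(x$truth$core_gene_ids)))
  invisible(x)
}

#' Simulate shotgun reads from a strain community
#'
#' Draws each read's genome of origin from the given (or freshly drawn)
#' abundance vector, a uniform start position, and independent per-base
#' substitution errors. Read ids encode nothing about the origin; the truth
#' is returned separately. Quality strings are constant Q30.
#'
#' @param genomes tibble with `genome_id` and `sequence` columns (e.g.
#'   `simulate_strain_genomes(...)$genomes`), or a `strain_sim`.
#' @param n_reads number of reads to draw.
#' @param abundances named numeric vector of relative abundances over (a
#'   subset of) the genome ids; if `NULL`, drawn from `distribution` over all
#'   genomes and normalized.
#' @param distribution abundance distribution when `abundances` is `NULL`:
#'   `"lognormal"` (meanlog 0, sdlog 1) or `"exponential"` (rate 1).
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error probability.
#' @param seed optional integer seed.
#' @return list of class `read_sim`: `reads` (tibble `read_id`, `seq`),
#'   `truth` (tibble `read_id`, `genome_id`), `abundance` (named numeric,
#'   sums to 1).
#' @export
simulate_reads <- function(genomes, n_reads, abundances = NULL,
                           distribution = c("lognormal", "exponential"),
                           read_length = 150L, error_rate = 0,
                           seed = NULL) {
  if (inherits(genomes, "strain_sim")) genomes <- genomes$genomes
  if (n_reads <= 0) stop("n_reads must be positive")
  distribution <- match.arg(distribution)
  with_seed(seed, {
    if (is.null(abundances)) {
      raw <- switch(distribution,
                    lognormal = rlnorm(nrow(genomes)),
                    exponential = rexp(nrow(genomes)))
      abundances <- setNames(raw / sum(raw), genomes$genome_id)
    } else {
      if (!all(names(abundances) %in% genomes$genome_id))
        stop("abundances name genomes absent from the collection")
      abundances <- abundances / sum(abundances)
    }
    origin <- sample(names(abundances), n_reads, replace = TRUE,
                     prob = abundances)
    seqs <- setNames(genomes$sequence, genomes$genome_id)[origin]
    lens <- nchar(seqs)
    if (any(lens < read_length)) stop("read_length exceeds a genome length")
    starts <- floor(runif(n_reads) * (lens - read_length + 1)) + 1L
    reads <- substring(seqs, starts, starts + read_length - 1L)
    if (error_rate > 0) {
      n_err <- rbinom(n_reads, read_length, error_rate)
      which_err <- which(n_err > 0)
      for (i in which_err) {
        s <- strsplit(reads[i], "", fixed = TRUE)[[1]]
        pos <- sample.int(read_length, n_err[i])
        s[pos] <- vapply(s[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        reads[i] <- paste(s, collapse = "")
      }
    }
    ids <- sprintf("read_%07d", seq_len(n_reads))
    structure(list(
      reads = tibble(read_id = ids, seq = unname(reads)),
      truth = tibble(read_id = ids, genome_id = unname(origin)),
      abundance = abundances), class = "read_sim")
  })
}

#' Simulate assembly as coverage-gap pseudo-contigs
#'
#' Models the effect of assembling reads at a given fold coverage without
#' running an assembler: uniform read start positions induce a Lander-Waterman
#' coverage profile, uncovered positions split the genome into contigs,
#' contigs shorter than `min_contig` are dropped, and predicted coding
#' sequences are the true gene intervals clipped to the retained contigs,
#' keeping fragments of at least `min_cds` bp.
#'
#' @param sequence genome sequence (single string), or a one-row slice of
#'   `strain_sim$genomes`.
#' @param gene_coords tibble with `gene_id`, `start`, `end` (ignored when a
#'   genome slice is given).
#' @param coverage fold coverage (> 0); `Inf` yields a single full-length
#'   contig with all genes intact.
#' @param read_length read length used for the coverage model.
#' @param seed optional integer seed.
#' @param min_contig minimum contig length retained (bp).
#' @param min_cds minimum CDS fragment length retained (bp).
#' @return list: `contigs` (tibble `contig_id`, `start`, `end`, `seq`),
#'   `cds` (tibble `cds_id`, `gene_id`, `contig_id`, `seq`),
#'   `covered_fraction`.
#' @export
simulate_contigs <- function(sequence, gene_coords = NULL, coverage,
                             read_length = 150L, seed = NULL,
                             min_contig = 500L, min_cds = 100L) {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1)
    gene_coords <- sequence$gene_coords[[1]]
    sequence <- sequence$sequence[1]
  }
  if (coverage <= 0) stop("coverage must be positive")
  L <- nchar(sequence)
  with_seed(seed, {
    if (is.infinite(coverage)) {
      covered <- rep(TRUE, L)
    } else {
      n_reads <- ceiling(coverage * L / read_length)
      starts <- floor(runif(n_reads) * (L - read_length + 1)) + 1L
      delta <- integer(L + 1L)
      tab_s <- tabulate(starts, nbins = L)
      tab_e <- tabulate(starts + read_length, nbins = L + 1L)
      delta[seq_len(L)] <- tab_s
      delta <- delta - tab_e
      covered <- cumsum(delta)[seq_len(L)] > 0
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts_r <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_contig
    contigs <- tibble(
      contig_id = sprintf("ctg%04d", seq_len(sum(keep))),
      start = starts_r[keep], end = ends[keep])
    contigs$seq <- substring(sequence, contigs$start, contigs$end)

    cds <- list()
    if (!is.null(gene_coords) && nrow(gene_coords) > 0 && nrow(contigs) > 0) {
      for (ci in seq_len(nrow(contigs))) {
        cs <- contigs$start[ci]; ce <- contigs$end[ci]
        ov <- gene_coords[gene_coords$end >= cs & gene_coords$start <= ce, ]
        if (nrow(ov) == 0) next
        fs <- pmax(ov$start, cs); fe <- pmin(ov$end, ce)
        ok <- (fe - fs + 1L) >= min_cds
        if (!any(ok)) next
        cds[[length(cds) + 1L]] <- tibble(
          gene_id = ov$gene_id[ok],
          contig_id = contigs$contig_id[ci],
          seq = substring(sequence, fs[ok], fe[ok]))
      }
    }
    cds <- if (length(cds)) dplyr::bind_rows(cds) else
      tibble(gene_id = character(0), contig_id = character(0), seq = character(0))
    if (nrow(cds) > 0)
      cds <- dplyr::mutate(cds, cds_id = sprintf("cds%05d", dplyr::row_number()),
                           .before = 1)
    list(contigs = contigs, cds = cds, covered_fraction = mean(covered))
  })
}
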