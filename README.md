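# gstprofiler

Strain-level, isolate-free host-association analysis of a gut bacterial
symbiont from shotgun metagenomes.

Gut symbionts such as *Limosilactobacillus reuteri* split into host-adapted
lineages: different strain populations dominate in pigs, mice, and dogs, and
those populations carry host-specific accessory genes. Demonstrating this
classically requires isolating and sequencing strains from each host —
the bottleneck this package removes. From a one-time reference collection of
isolate genomes it builds two databases, then profiles any metagenome
directly:

* **Genome-based strain types (GSTs).** Isolate genomes are typed by SNV
  distance on a species core-genome reference (the concatenated core genes
  of the type strain). On the phylogeny, sister clades are merged greedily —
  seeded at the type strain, then at the highest-priority unclustered
  genome — while the maximum all-pairs SNV distance of the growing clade
  stays below a cap (20,000 SNVs by default):

  `GST = largest clade with max_{i,j ∈ clade} d_SNV(i, j) < τ`

  Reads are classified against canonical 31-mers of the GST representatives'
  core genes, each k-mer mapped to the lowest common ancestor of the GSTs
  containing it, reads scored by the maximal root-to-leaf hit path, and
  internal-node counts re-estimated down to GST leaves to give a per-sample
  strain-type abundance profile.
* **Pan-genome gene profiles.** All reference CDSs are clustered at 90%
  identity / 90% bidirectional coverage; a sample's predicted CDSs (contigs
  ≥ 500 bp, fragments ≥ 100 bp) are searched against the cluster
  representatives to yield a gene presence/absence profile.
* **Host-association statistics.** Samples are filtered (≥ 20,000 classified
  reads, ≥ 500 gene hits), grouped by dominant GST (groups must exceed five
  samples), compared by weighted UniFrac / Jaccard distances under PERMANOVA
  (9,999 permutations), and screened for host-specific genes with Fisher's
  exact test (`p < 0.01` plus in-group enrichment). MAGs are quality-tiered,
  assigned to the species by fragment ANI (> 95%), placed among the GSTs by
  covered-position SNV distance (or flagged as novel lineages outside all
  GSTs), and mined for gene families absent from the pan-genome.

Because real isolate collections and cohorts are not shippable, the package
includes a first-class synthetic-data module that generates strain
communities with exact ground truth (per-read origin, true abundances, true
gene content, planted host-specific genes) plus the evaluation metrics used
to validate the pipeline: ancestor-aware read-level precision, true/estimated
abundance correlation, and gene-profile TPR/F1.

## Worked example

```r
library(gstprofiler)

# 1. simulate a community: 3 strain types, 4 strains each, with truth
cfg <- sim_config(seed = 42, genome_length = 60000, n_genes = 50,
                  gene_length_range = c(600, 1000), n_gsts = 3,
                  strains_per_gst = 4, within_gst_snv = 50,
                  between_gst_snv = 3000, accessory_fraction = 0.1)
sim <- simulate_strain_genomes(cfg)
#> <strain_sim> 12 genomes in 3 GSTs; 50 ancestral gene families (45 stable)

# 2. core reference -> SNV distances -> GST clustering -> taxonomy
ts   <- sim$genomes[sim$genomes$is_type_strain, ]
ref  <- build_core_reference(ts$genes[[1]][sim$truth$core_gene_ids])
snvs <- setNames(lapply(seq_len(nrow(sim$genomes)),
                        function(i) call_snvs(sim$genomes[i, ], ref)),
                 sim$genomes$genome_id)
d    <- snv_distance_matrix(snvs)
prio <- prioritize_genomes(sim$genomes)
asn  <- cluster_gsts(sim$tree, d, threshold = 500, priority = prio)
#> <gst_assignment> 12 genomes in 3 GSTs (threshold 500 SNVs)
tax  <- build_taxonomy(sim$tree, asn)

# 3. k-mer database from representative core genes; profile one sample
rep_genes <- lapply(asn$representative, function(g) {
  gs <- sim$genomes$genes[[match(g, sim$genomes$genome_id)]]
  unname(gs[intersect(names(gs), sim$truth$core_gene_ids)])
})
db <- build_kmer_db(rep_genes, tax, k = 31)
#> <kmer_db> k=31, 99,518 canonical k-mers over 4 taxonomy nodes
reads <- simulate_reads(sim, n_reads = 20000,
                        abundances = c(GST01_S01 = 0.6, GST02_S01 = 0.3,
                                       GST03_S01 = 0.1),
                        error_rate = 0, seed = 7)
profile_sample(reads$reads, db, sample_id = "sample1")
#> # A tibble: 3 × 3
#>   gst_id count relative
#>    <int> <dbl>    <dbl>
#> 1      1 7962.   0.599
#> 2      2 3999.   0.301
#> 3      3 1327.   0.0998
```

The estimated strain-type fractions (0.599 / 0.301 / 0.0998) recover the
planted abundances (0.6 / 0.3 / 0.1); the Pearson correlation against the
truth is 0.99999, and the read-level precision — the fraction of classified
reads assigned to their true GST or one of its ancestors — is 0.9997 with
66% of reads classified (the remainder come from intergenic and accessory
sequence absent from the core-gene database):

```r
abundance_correlation(profile_sample(reads$reads, db), c("1" = .6, "2" = .3, "3" = .1))
#> [1] 0.9999949
read_level_precision(classify_reads(reads$reads, db),
                     setNames(sim$truth$gst[reads$truth$genome_id],
                              reads$truth$read_id), tax)
#> # A tibble: 1 × 5
#>   precision classified_fraction n_reads n_classified n_correct
#> 1     1.000               0.664   20000        13288     13284
```

Gene-composition accuracy against the known gene content, using
coverage-gap pseudo-contigs at 5× and 10×:

```r
bench <- gene_profile_benchmark(sim, coverages = c(5, 10), seed = 1)
dplyr::summarise(dplyr::group_by(bench, coverage), tpr = mean(tpr), f1 = mean(f1))
#> # A tibble: 2 × 3
#>   coverage   tpr    f1
#> 1        5 0.830 0.897
#> 2       10 0.977 0.977
```

At 5× coverage roughly one gene in six is interrupted by a coverage gap
(TPR 0.83); at 10× nearly every gene survives intact and both TPR and F1
exceed 0.97, with precision staying near 1 throughout — the qualitative
behavior expected of presence/absence gene profiling as assemblies saturate.

A thin command-line front end over the same functions ships at
`inst/cli/gstprofiler.R` (`simulate`, `profile`, `evaluate` subcommands).

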