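---
title: "Strain-level metagenomic profiling with genome-based strain types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-level metagenomic profiling with genome-based strain types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Host-adapted gut symbionts such as *Limosilactobacillus reuteri* carry
strain-level population structure that tracks the host species they colonize:
distinct phylogenetic lineages dominate in pigs, mice, or dogs, and lineages
carry host-specific accessory genes (mobile elements, biofilm machinery,
transporters). Classical evidence for this comes from isolate genomes, but
isolating and sequencing strains is the bottleneck. `gstprofiler` implements
an isolate-free route: the strain population and gene content of a species in
a shotgun metagenome are profiled directly against reference databases built
once from whatever isolates exist.

The pipeline has four statistical/algorithmic components:

1. **Genome-based strain types (GSTs).** Reference genomes are aligned to a
   species-specific core-genome reference (the concatenated core genes of the
   type strain), giving per-genome SNV sets and an all-against-all SNV
   distance matrix. On a rooted phylogeny of the genomes, GSTs are grown
   greedily: starting from the type strain (and subsequently from the
   highest-priority unclustered genome), the current clade is repeatedly
   replaced by its parent clade as long as (i) no leaf of the enlarged clade
   is already clustered and (ii) the maximum pairwise SNV distance over the
   enlarged clade stays strictly below a cap (20,000 SNVs by default, the
   scale at which *L. reuteri* lineages separate). The result is a partition
   of the genomes into monophyletic strain types.

2. **k-mer LCA classification.** The core genes of each GST's representative
   genome are decomposed into canonical 31-mers; each k-mer maps to the
   lowest common ancestor, in the GST-collapsed tree topology, of all GSTs
   containing it. A read is classified by summing its k-mer hits along each
   root-to-leaf path and taking the deepest node of the maximum-scoring path
   (ties resolve to the LCA of the tied leaves). Reads hitting internal
   nodes are re-estimated down to GST leaves proportionally to the leaves'
   direct-assignment counts — a deliberate simplification of Bracken's
   Bayesian redistribution that preserves its fixed point when leaf
   assignments dominate, and is exactly testable.

3. **Pan-genome gene profiling.** All reference CDSs are clustered greedily
   at 90% nucleotide identity and 90% bidirectional coverage (longest
   sequence first; a sequence joins the first existing representative it
   matches, else founds a cluster). Clusters present in strictly more than
   95% of genomes are core; one-member clusters are singletons. A sample's
   gene profile is the set of clusters hit by its predicted CDSs
   (contigs ≥ 500 bp, CDS fragments ≥ 100 bp) at the same 90/90 thresholds.

4. **Host-association statistics.** Samples with < 20,000 classified reads
   or < 500 gene hits are removed; the rest are grouped by dominant GST and
   groups with ≤ 5 samples are dropped. Population structure is compared
   with weighted UniFrac (GST profiles) and Jaccard (gene profiles)
   distances under one-way PERMANOVA (9,999 label permutations,
   `p = (1 + #{F* ≥ F}) / (1 + n_perm)`). Per gene and host group a 2×2
   presence/absence table is tested with the two-sided Fisher's exact test;
   a gene is host-specific when `p < 0.01` **and** its in-group prevalence
   exceeds its out-group prevalence.

MAGs (metagenome-assembled genomes) enter as sequences plus
completeness/contamination estimates, are tiered (high: completeness > 90%
and contamination < 5%; medium: ≥ 50% and < 10%), assigned to the species by
fragment-based reciprocal-best ANI (1,020 bp fragments, > 95% identity), and
placed by mean SNV distance to each GST's members restricted to the core
positions the MAG covers; a MAG whose minimum distance exceeds the GST cap
scaled by its covered fraction is reported as lying outside all GSTs — the
signature of a host lineage absent from the reference collection. MAG genes
failing the 90/90 search against the pan-genome are clustered into novel
gene families.

## What the synthetic-data generator emulates

Real inputs (isolate collections, SRA cohorts) are out of reach for a desk
test, so every claim the package makes is exercised on synthetic communities
with complete ground truth. `simulate_strain_genomes()` builds one ancestral
genome of `n_genes` genes separated by intergenic spacers, evolves `n_gsts`
GST ancestors and `strains_per_gst` strains per type by planting
substitutions at globally disjoint positions — so every pairwise SNV
distance is an exact sum of private substitution counts, and the SNV-calling
oracle is exact — and applies accessory turnover: a per-GST set of private
gene families (the host-specific truth), one private singleton gene per
strain, and per-strain loss of accessory-pool genes. Substitutions only land
in stable genes, so core-genome SNV distance equals Hamming distance; an
infeasible substitution budget is an error, never a silent clamp.

`simulate_reads()` draws read origins from a supplied or sampled
(log-normal/exponential) abundance vector, uniform start positions, and
independent per-base substitution errors; read ids carry no information
about their origin. `simulate_contigs()` models assembly without an
assembler: at fold coverage *c*, uncovered positions under the
Lander–Waterman model split the genome into contigs, contigs under 500 bp
are dropped, and CDSs are the true gene intervals clipped to contigs
(fragments ≥ 100 bp kept).

Deliberately **not** emulated: realistic Illumina error profiles (errors are
uniform substitutions; quality strings are constant Q30 and quality trimming
is out of scope), indels (so SNV distance is exact), paired-end inserts
(classification is insert-agnostic), host DNA, plasmids, chimeric assembly
artifacts, and strain mixtures within one MAG. Tests passing on these
communities therefore validate the algorithms and their contracts, not
robustness to platform-specific noise.

## Default conditions and why

| knob | default | rationale |
|---|---|---|
| `n_gsts` × `strains_per_gst` | 12 × 1 | the 12-genome gene-profiling validation design |
| `genome_length` | 500 kb | desk-scale stand-in for a ~2 Mb genome; keeps all-pairs work tractable |
| `n_genes` | 400 | preserves the ~72% coding density of the scaled genome |
| `gene_length_range` | 600–1200 bp | bacterial CDS length centers near 900 bp |
| `within_gst_snv` / `between_gst_snv` | 100 / 5000 | clonal types, clearly separated, scaled to the 500 kb core |
| `read_length` | 150 bp | short-read simulators bundle 125/150/301 bp error models; 150 matches NovaSeq output |
| `error_rate` | 0.005 | mid-range short-read substitution error; capped at 0.05 by validation |
| `accessory_fraction` | 0.05 | ~20 accessory genes per genome, enough to plant private families |
| k (classifier) | 31 | standard k-mer classifier default; odd so canonicalization is unambiguous |
| identity / coverage | 0.90 / 0.90 | the pan-genome clustering and search thresholds |
| core prevalence | > 0.95 | strict reading of "over 95% of genomes" |
| Fisher alpha | 0.01 | the host-specificity cutoff; no multiple-testing correction by default |
| PERMANOVA permutations | 9,999 | conventional permutation depth |

## Numerical and design choices

* **Alignment.** Identity is matches over columns of a banded global
  alignment (match +1, mismatch −1, linear gap −2); "bidirectional 90%
  coverage" under a global alignment reduces to the shorter sequence being
  ≥ 90% of the longer. Candidate pairs must share an exact canonical 15-mer;
  at ≥ 90% identity over ≥ 100 bp a shared 15-mer is essentially guaranteed,
  so the prefilter changes speed, not results. The test suite re-validates
  members against representatives with an independent aligner
  (`Biostrings::pairwiseAlignment`).
* **Greedy clustering order.** Length-descending, ties broken by gene id;
  a sequence joins the *first* (creation-order) matching representative.
  Profiling takes the *best* hit; the two agree whenever family divergences
  sit away from the 90% boundary, which is how the planted communities are
  built — near-boundary families can legitimately differ.
* **Core-gene order** in the concatenated reference is lexicographic by
  family id (no order is canonical; this one is deterministic).
* **SNV distance** counts positions where the two genomes' alleles differ:
  one-sided variants count once, positions where both vary to different
  alternates count once, and positions where both carry the same alternate
  do not count. Positions in core genes missing from either genome are
  excluded — absence is not a single-nucleotide variation.
* **SNV calling** anchors genes by id (the generator tags them); a
  whole-genome aligner is intentionally not re-implemented, and real-data
  users supply precomputed variant tables (TSV: genome, position, ref, alt).
* **Rooting.** Greedy clade merging needs a root; unrooted input trees are
  midpoint-rooted. Merges that would absorb already-clustered leaves are
  refused so GSTs always partition the leaf set. The threshold is strict
  ("below 20,000" means ≤ 19,999). GST labels follow creation order
  (type-strain GST first) and are stable but arbitrary.
* **Ties.** Equal-scoring classification paths resolve to the LCA of their
  deepest nodes; dominant-GST ties in host grouping take the smallest GST id
  and are flagged.
* **Fisher sidedness.** Two-sided p-values (exact hypergeometric via
  `stats::fisher.test`, equal to direct enumeration) plus the directionality
  requirement; "specific" semantically requires enrichment, and two-sided
  testing is the common default. A Benjamini–Hochberg option and a
  minimum-prevalence prefilter exist but are off by default, matching the
  plain `p < 0.01` rule.
* **Weighted UniFrac** is the raw (non-normalized) variant by default, with
  `normalized = TRUE` available; branch lengths come from the supplied GST
  tree.
* **PERMANOVA** permutes labels freely (one-way, no strata); the permutation
  p-value includes the identity in numerator and denominator. Permutations
  that recreate the original partition tie with the observed F, so the
  attainable minimum p is `(1 + r)/(1 + n_perm)` with `r` the number of such
  repeats rather than the nominal floor.
* **Degenerate inputs.** All-unclassified samples yield an explicitly
  flagged empty profile, not zeros; zero-variance abundance vectors make the
  correlation undefined (`NA` with a warning); genes absent everywhere get
  `p = 1`; empty gene sets are at Jaccard distance 0 by convention; MAGs
  covering < 10% of the core reference refuse placement.
* **Precision denominator.** Read-level precision counts assignments to the
  true GST or any ancestor over *classified* reads only; the classified
  fraction is reported separately since recall is not part of the metric.

## Problem sizes used by the checks

The shipped tests run on communities of 3–12 genomes with 20–120 genes of
600–1200 bp (40–150 kb genomes), 15,000–20,000 reads per sample, exhaustive
Fisher enumeration up to 30-sample margins, 200 random clustering instances,
200 PERMANOVA null datasets at 199 permutations, and full permutation
enumeration on 6-sample instances. The acceptance script
(`scripts/acceptance.R`) runs the 12-genome design at full default scale
(0.5 Mb, ~400 genes) at 5× and 10× coverage. These sizes are the package's
chosen desk-scale study conditions; the underlying algorithms are the same
at any scale.

## Known limitations

* The k-mer database lives in memory behind an external pointer; it is
  rebuilt per session rather than serialized.
* Leaf-proportional abundance re-estimation is a documented divergence from
  Bracken's k-mer-derived redistribution probabilities; on communities where
  most reads classify at leaves the two coincide, but heavily shared
  references (many reads at internal nodes, few leaf anchors) will stress
  the approximation.
* Real-data SNV calling, assembly, gene prediction, binning, and
  completeness estimation are upstream tools' jobs; the package consumes
  their outputs (variant TSVs, contig/CDS FASTA, completeness numbers) and
  re-implements only simplified, testable stand-ins for simulation.
* GST labels are not comparable across runs with different priorities, and
  named host lineages of the original isolate collections cannot be
  reproduced without those genomes.
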