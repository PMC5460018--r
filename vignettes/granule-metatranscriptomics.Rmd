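---
title: "Quantifying gene expression across MAGs in anammox granules"
author: "granuletx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene expression across MAGs in anammox granules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granuletx)
```

## The problem

Anammox granular sludge hosts a community of anaerobic ammonium-oxidizing
(anammox) bacteria and heterotrophs whose interactions — nitrate-to-nitrite
recycling, degradation of extracellular polymeric substances, amino-acid
cross-feeding — are read out by mapping DNA and mRNA reads onto
metagenome-assembled genomes (MAGs). `granuletx` implements the
quantification layer of such a study: given binned genomes, ORF
coordinates, and read alignments for a DNA and an mRNA library, it produces
per-ORF, per-pathway and per-genome expression summaries, plus the
functional profiles (denitrification steps, peptidase/transporter
inventories, amino-acid auxotrophies) that community-interaction arguments
rest on. Upstream steps — assembly, binning, ORF calling, database
annotation, subcellular-location prediction — are consumed as input files,
not re-implemented.

## The model and its assumptions

**Counting.** Reads are assigned to ORFs under *intersection-strict*
semantics: for every aligned reference position, form the set of
strand-compatible ORFs covering it; the read is assigned only when the
intersection of these sets across all its positions contains exactly one
ORF. A read with any position outside the ORF is `no_feature`; one whose
every position is covered by two or more ORFs is `ambiguous`. Ambiguous and
no-feature reads still count toward their genome's total (they mapped to
the bin's contigs), giving the genome-level tallies their own meaning:
abundance and expression proxies are `reads mapped to genome / genome
length`, normalized across the included bins.

**Normalization.** Per-ORF expression is RPKM,
\(10^9 \cdot c_i / (N \cdot \ell_i)\) for count \(c_i\), ORF length
\(\ell_i\) (nt) and library size \(N\). Within each genome, RPKM is
relativized by the genome's **median** ORF RPKM, so a value of 1 marks
median expression in that genome; this makes expression comparable across
genomes of very different abundance. The median is taken over **all**
predicted ORFs of the genome, including zero-count ones — that is the
literal reading of "median across the genome", and it means a genome with
at least half its ORFs silent has an undefined (NA) relative scale rather
than an imputed one. No pseudocounts are used anywhere; zeros propagate and
are flagged.

**Pathway aggregation.** A reaction's expression is the **maximum** over
its isozyme/multi-copy alternatives; a multi-subunit complex (hydrazine
synthase *hzsABC* is the canonical case) contributes the **minimum** over
its subunits — a complex is no more expressed than its scarcest part.
Pathway expression is the arithmetic mean over reactions, then relativized
by the genome's median ORF RPKM. Pathway *presence* requires every
key-flagged reaction to have at least one assigned enzyme group and overall
completeness (assigned/total reactions) at or above a threshold.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_identity` | 0.95 | minimum alignment identity retained; the species-level (ANI-like) mapping criterion assumed upstream |
| `stranded` | `"yes"` (RNA), `"no"` (DNA) | strand compatibility in counting; RNA-Seq libraries here are strand-specific, DNA strand is meaningless |
| `library_size_mode` | `"mapped"` | RPKM denominator: all identity-passing mapped reads; `"assigned"` restricts to feature-assigned reads |
| `gap_policy` | `"covered"` | deletion-spanned reference positions count as aligned (single genomic footprint); `"per_block"` requires each aligned block inside the feature |
| `completeness_threshold` | 0.75 | fraction of reactions that must be enzyme-assigned for pathway presence |
| `unassigned` | `"exclude"` | reactions with no genes are excluded from the pathway mean; `"zero"` zero-fills them |
| `noise_fraction` | 0.05 | simulator: fraction of RNA reads placed on intergenic sequence |

Design choices where the convention was genuinely open:

* **Identity definition.** SAM does not standardize alignment identity; the
  reader defines it as `1 − NM / aligned_read_length`, with soft-clipped
  bases excluded from the aligned length. Records without an NM tag are
  dropped with a warning by default (configurable to accept).
* **Gap policy.** Whether deletion-spanned positions count as covered is
  mapper- and counter-dependent; since prokaryotic ORFs are unspliced, the
  default treats the read's footprint as one interval, and the per-block
  alternative sits behind a flag. Both are oracle-tested.
* **Complex resolution.** An enzyme-complex group counts as assigned in a
  genome only when *all* its subunit ORFs resolve there. A complex whose
  subunit gene is present but unexpressed is a different, meaningful state:
  the group is assigned with RPKM 0 and a `zero_subunit` flag (the
  denitrification profile surfaces this as an encoded step with a silent
  subunit, e.g. an unexpressed *narI* membrane anchor).
* **Completeness threshold.** Pathway-inference tools apply curated rule
  bases; a flat completeness threshold (default 0.75) over the supplied
  reaction lists approximates manually curated calls while staying
  transparent and configurable.
* **Pathway relativization order.** Pathway relative expression is
  `(mean reaction RPKM) / (median ORF RPKM)` — relativization after
  averaging. Averaging pre-relativized reactions gives the same result up
  to the common median factor, but the chosen order keeps pathway RPKM
  interpretable on the ORF RPKM scale.
* **Multi-mappers.** The pipeline expects one record per read (upstream
  mappers that place ambiguous reads randomly). If several records share a
  read id, one location is chosen uniformly under the pipeline seed, making
  the random placement reproducible.
* **Library size.** "Sequencing depth" is read as all identity-passing
  mapped reads; restricting to assigned reads is available by flag since
  the definition changes only a constant factor within a library.

## The synthetic-data generator

The generator emulates the statistical structure the estimators assume:

* genomes of differing lengths (default five, 0.5–4 Mb — the size range
  typical of granule MAGs) carrying non-overlapping ORFs whose lengths are
  `3 × max(20, ceiling(Gamma(shape 2, scale 150)))` codons (min 60 nt, the
  gene-caller minimum);
* community composition drawn from a symmetric Dirichlet (concentration 1);
* within-genome transcript levels drawn log-normal(0, 1);
* Poisson read counts with expectation `abundance × length` (DNA) or
  `abundance × length × expression` (RNA), with `noise_fraction` of RNA
  reads placed on intergenic sequence in proportion to `abundance × length`
  (for DNA, uniform coverage already spans intergenic sequence, so no
  separate noise term applies);
* fixed-length (125 bp), error-free, perfect-identity single-block reads
  placed entirely inside their source region, so intersection-strict
  counting must recover the emitted count table *exactly* — an end-to-end
  identity oracle. Identity filtering is exercised separately with
  synthetically degraded records.

A single integer seed governs everything through a documented splitting
scheme (`split_seed`): per-genome and per-library substreams, so one
component can be regenerated without disturbing the rest, and identical
seeds give byte-identical output files.

What the simulator does **not** emulate: sequencing errors and quality
scores, strain-level variation, assembly/binning artifacts (chimeric or
fragmented bins), rRNA carryover, compositional biases of library
preparation. Tests passing on synthetic data therefore validate the
estimators' arithmetic and contracts, not robustness to those real-data
pathologies.

## Worked example

```{r example, eval = FALSE}
dir <- tempfile("community")
sim <- simulate_community(
  dir,
  spec = community_spec(3, total_length_bp = c(6e4, 9e4, 1.2e5),
                        orfs_per_mb = 600, n_contigs = 2),
  seed = 42, dna_depth = 2e4, rna_depth = 2e4)

gs   <- read_genome_bins(sim$paths[["fasta"]], sim$paths[["bins"]])
orfs <- read_gff3(sim$paths[["gff"]], gs)
rna  <- count_library(read_sam(sim$paths[["sam_rna"]]), gs, orfs,
                      stranded = "yes", library_id = "rna")
expr <- expression_table(rna, orfs)
head(expr, 3)

dna  <- count_library(read_sam(sim$paths[["sam_dna"]]), gs, orfs,
                      stranded = "no", library_id = "dna")
community_profile(list(dna, rna), gs)
```

The DNA fractions estimate the Dirichlet composition the community was
drawn from (`truth_abundance.tsv`); at a depth of \(2\times 10^6\) DNA
reads the estimates sit within 0.01 absolute of the truth, which the test
suite checks over 20 replicate seeds.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GFF3 1-based inclusive
  conversion happens only at the I/O boundary, and the 60 nt boundary case
  (GFF `start=11 end=70`) maps to `[10, 70)` with length 60.
* Even-sized genomes take the mean of the two middle RPKMs as the median.
* `log2` of a zero step RPKM is reported NA alongside the zero flag, never
  via a pseudocount.
* Ranking ties in `top_expressed` break lexically by ORF id, making output
  stable across platforms.
* The amino-acid cost association is a two-sided permutation test on the
  sum of biosynthetic-cost ranks of the degraded amino acids
  (`(1 + #{|T*−μ| ≥ |T−μ|}) / (n_perm + 1)`, μ the exact null mean); it is
  NA when a genome degrades none or all 20 amino acids. The default rank
  table (1 = most costly) orders amino acids by the biosynthetic costs
  reported by Akashi & Gojobori (2002), ties broken alphabetically; it is
  an input, so other cost scales can be substituted.
* Infeasible ORF packings (requested ORFs cannot fit without overlap after
  bounded retries) and empty pathways are hard errors, not silent repairs.

## Problem sizes used in the automated checks

The test suite works at desk scale: simulated genomes of 40–120 kb with a
few dozen ORFs for exact-identity checks (20 seeds), full-size 0.5–4 Mb
genomes with count-level simulation (no read emission) at \(2\times10^6\)
DNA reads for abundance recovery (20 seeds), 10,000 randomized read/ORF
instances for the counting oracle, and 10,000 permutations for the cost
test. These sizes were chosen so each property is measured with comfortable
statistical margin while the whole suite stays quick to run.

## Known limitations

* Single time point: no between-sample normalization or differential
  expression — RPKM comparisons are within-library by design.
* BAM/CRAM are out of scope; alignments arrive as SAM text (single-end,
  merged upstream).
* Pathway presence is a flat rule over supplied reaction lists; it does not
  reproduce a full curated inference rule base, taxon-specific pruning, or
  gap-filling.
* Fractional multi-mapper reallocation (EM) is deliberately absent; the
  one-record-per-read contract mirrors random placement upstream.
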