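---
title: "Methods: multi-line RNA-seq diversity analysis with pantx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-line RNA-seq diversity analysis with pantx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pantx)
library(dplyr)
```

## What the package computes

`pantx` implements the computational core of a panel-based RNA-seq diversity
study of homozygous inbred lines (the motivating system is a maize seedling
panel spanning the Stiff Stalk Synthetic and Non-Stiff Stalk Synthetic
heterotic groups plus Iodent, exotic and other germplasm). Five analyses
share one data backbone:

1. **Multi-sample SNP calling** from per-base read-count pileups.
2. **GBS genotyping** (barcode demultiplexing and majority-rule calls) and
   **cross-method concordance** with the RNA-seq calls.
3. **Rogers distances** and a **neighbor-joining tree** of the panel.
4. **Expression classification** from FPKM 95% confidence intervals into
   core and dispensable transcriptomes.
5. **Novel-transcript filtering and presence/absence** analysis with
   heterotic-group-specific sets.

A seeded simulator (`sim_config()`, `simulate_population()` and friends)
generates complete miniature panels with known truth so every stage is
testable without external sequencing data.

## The SNP caller and its rules

The caller's sole input is a table of Phred-prefiltered read counts per
nucleotide at each covered position for each line. Three rules are applied
in order; each is exposed as a function and as a tunable threshold so the
defaults encode the intended analysis exactly:

* **Per-line genotype** (`call_line_genotype()`): a nucleotide is accepted
  iff it has at least 2 supporting reads *and* strictly more than 5.0% of
  the reads at that position. Exactly one accepted nucleotide gives the
  call; zero, or two or more, give missing data. The two-or-more case is
  deliberate: in a homozygous inbred an apparently heterozygous position
  cannot be distinguished from a collapsed paralog with sequence
  divergence, so it is treated as unresolvable. The 5% denominator is the
  sum of the four post-filter base counts at the position — the data model
  carries no separate raw-depth denominator. Zero coverage yields missing,
  forced by absence of evidence.
* **Allele confirmation** (`confirm_alleles()`): an allele must be the
  single non-missing call of at least 2 distinct lines.
* **Locus emission** (`discover_snps()`): a position becomes a SNP locus
  iff at least 2 confirmed alleles remain. A direct consequence is that
  every locus has data in at least four lines. Three or more confirmed
  alleles stay together as one multi-allelic locus (the VCF writer emits
  multiple ALT entries) rather than being split.

One genuinely open point is what to do with a line whose call at an
emitted locus is an allele that itself failed the two-line confirmation.
The confirmation rule is stated for allele *existence*, not per-line
masking, so the call is retained in the matrix as made and flagged in the
`unconfirmed` attribute; downstream consumers can mask those entries if
they prefer. The VCF writer must render them `./.` regardless, since an
unconfirmed allele has no REF/ALT index.

Per-gene statistics (`snp_gene_stats()`) assign a SNP to every gene whose
*exon set* contains it — RNA-seq reads are exonic, so exon containment is
the faithful assignment; gene-span containment is available via `by =
"span"`. Gene length for the per-100-bp density is the summed exon length
of the longest annotated mRNA. The annotation does not dictate which
transcript defines gene length; the longest-mRNA choice is explicit in
`read_gff3_genes()` and documented rather than silently assumed.
Genome-scan densities (`window_density()`) use 1 Mb windows, SNPs binned
by position, genes by midpoint, and a gene counts as expressed when at
least 4 lines have a positive CI lower bound — the same number of lines a
SNP call requires, keeping the two densities comparable.

## GBS genotyping and concordance

`demultiplex()` keeps a read only on a perfect barcode match immediately
followed by the ApeKI cut-site remnant `GC[A/T]GC`; the barcode is
trimmed and the cut site retained (retention is configurable — the
upstream convention is not universal). Barcode sets must be prefix-free:
with perfect-match parsing a prefix collision is inherently ambiguous.
`call_gbs_genotype()` calls a site when one nucleotide holds at least 70%
of the reads (inclusive boundary: 7 of 10 reads is a call), which with a
threshold above 50% can never be ambiguous.

`cross_method_concordance()` compares two call matrices over the data
points — (position, line) pairs — non-missing in both, and flags
"contradiction positions" where more than two lines disagree between
methods, the most literal reading of that diagnostic. Rates are kept at
full precision; any rounding to two decimals is presentation only.

## Distances and the tree

For homozygous inbreds the per-locus Rogers distance
$d_\ell = \sqrt{\tfrac12 \sum_a (p_a - q_a)^2}$ collapses to a 0/1
mismatch indicator, so the pairwise distance is the mismatch proportion
over loci shared (pairwise deletion); `min_shared` defaults to 100 loci,
below which a pair is reported undefined rather than silently noisy.

`neighbor_joining()` is the standard Saitou–Nei algorithm with two
determinism/robustness conventions fixed: Q-matrix ties break at the
lowest (row, column) index pair, and negative branch lengths follow the
Kuhner–Felsenstein convention (clamp to zero, transfer the deficit to the
sister branch, preserving the joined pair's path length). On any matrix
exactly additive on a binary tree with positive lengths the tree is
recovered to numerical tolerance; the test suite verifies this on random
additive trees (path-length error below 1e-9) and cross-checks topologies
against `ape::nj()`, which serves only as an independent reference, never
as the implementation. `group_monophyly()` tests whether each pedigree
group occupies a connected subtree of the unrooted tree.

## Expression classification

A gene is expressed in a line iff the FPKM 95% CI lower bound is strictly
positive; the comparison is to literal zero with no epsilon, because the
upstream quantifier emits exact zeros for undetected genes. The
semi-quantitative bins are NONE (`conf_lo == 0`), LOW (FPKM < 5), MEDIUM
(5 ≤ FPKM ≤ 200, both boundaries inclusive) and HIGH (FPKM > 200).
Core/dispensable accounting needs a complete gene × line grid;
`densify_fpkm()` fills genes absent from a line's table with the literal
(0, 0, 0) record and warns, so totals and per-line percentages have a
well-defined denominator — the total annotated gene count is treated as a
property of the input, not a constant.

## Novel transcripts and PAV

The representative transcript per assembly locus is the longest (minimum
500 bp, ties by transcript id). A transcript is removed as a reference
allele/paralog only when its best alignment exceeds **both** 85% coverage
and 85% identity, strictly; retention is the complement (unaligned, or
below either cutoff). When several alignments per transcript are
supplied, "best" is the maximal coverage × identity product, tie-broken
by coverage. `cutoff_sweep()` re-applies the filter over a 0.70–0.95 grid
and is provably monotone. Presence in a line uses unique-read support
(≥ 1 uniquely mapping read) in the stringent mode; the relaxed mode also
counts multi-mapped reads, which rescues paralog-like transcripts.
Group-specific sets require presence in at least one line of exactly one
group and absence everywhere else; the pairwise mode first restricts the
panel to two groups (e.g. SSS vs NSS) and then applies the same rule. All
lines are treated symmetrically, including any line that contributed the
reference assembly.

## The simulator: what it emulates, and what it does not

Generator defaults encode the emulated study design: 21 lines in groups
SSS = 3, NSS = 8, Iodent = 1, Exotic = 5, Other = 4; gene-expression
classes split 48.7% expressed-in-all / 27.9% expressed-in-a-subset /
remainder never; ~43% of novel transcripts core and ~28% unaligned to the
reference; roughly 2.5 background (removed) transcripts per novel one.
Depth is Poisson with mean 20 and the error model is a uniform
substitution at rate 0.005 per read — deliberately the simplest models
that exercise every rule boundary (5%, 2 reads, 70%). Where the emulated
design does not pin a value we chose once: 30% of SNP loci group-private
(enough structure for the tree to separate groups), two chromosomes, 300
genes and 3,000 SNP loci plus 3,000 monomorphic sites (the substrate for
false-positive calls) — desk-scale sizes that keep a full pipeline run
in seconds. Dropout of lowly expressed genes is modelled as a zero CI
lower bound with the FPKM left positive, not as a zero FPKM, mirroring
how sampling noise actually manifests in CI-based expression calls; the
default dropout rate is 5% of truly-LOW cells.

A single master seed fans out to fixed per-stage offsets (population +1,
base counts +2, FPKM +3, alignments +4, GBS +5, read support +6), so each
stage is independently reproducible and byte-identical under a repeated
seed.

The simulator does **not** model read-level artefacts (FASTQ qualities,
mapping bias), splice structure, linkage disequilibrium beyond
group-private alleles, overlapping genes, or allele-specific expression
(heterozygosity in these inbreds is negligible, so the caller's
missing-data rule absorbs the residue). Passing the recovery tests
therefore demonstrates correctness of the rules and their composition on
data with the stated statistical shape, not robustness to alignment
artefacts in real pileups.

## Verification strategy and problem sizes

Every calling and classification rule is checked against an independently
coded brute-force restatement: exhaustively over all count vectors with
per-base counts ≤ 12, and on thousands of randomized small instances
(≤ 6 lines, ≤ 50 positions/transcripts). Parameter-recovery runs use 20
replicates of a 12-line, 3-group, 2,000-SNP panel at depth 20 and error
0.005, requiring ≥ 95% sensitivity on discoverable loci (both alleles
covered by ≥ 2 reads in ≥ 2 lines), ≤ 1% false discovery, and group
subtree recovery in ≥ 19 of 20 trees. NJ consistency uses 50 random
additive binary trees on 4–12 taxa. These sizes keep the default test run
under a couple of minutes while leaving every rule boundary exercised.

## A short worked example

```{r example}
cfg <- sim_config(n_lines = 6, group_sizes = c(SSS = 3, NSS = 3),
                  n_genes = 40, n_snps = 200, n_invariant_sites = 200,
                  n_novel_transcripts = 20, n_background_transcripts = 40,
                  seed = 42)
truth <- simulate_population(cfg)
gm <- simulate_basecounts(truth) |>
  discover_snps(lines = truth$lines$line_id)
glance(gm)

tree <- rogers_distance_matrix(gm, min_shared = 30) |>
  neighbor_joining()
group_monophyly(tree, truth$lines)

simulate_fpkm_table(truth) |>
  core_dispensable_histogram() |>
  core_dispensable_summary()
```

## Known limitations

* The caller emits loci, not phased haplotypes; indels and simple-sequence
  repeats are out of scope, as are FPKM estimation and the assembly and
  alignment steps upstream of the data model.
* Reference-concordance of a reference-derived line cannot be emulated
  faithfully by the default simulator, which designates no reference
  line; the acceptance script therefore reports genotype accuracy against
  simulation truth instead.
* Percent-style outputs are returned at full precision; round at the
  presentation layer.
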