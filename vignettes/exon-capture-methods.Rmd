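---
title: "Reference-free exon capture: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free exon capture: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excapr)
```

## The problem

Hybridization exon capture enriches a sequencing library for chosen genomic
regions by annealing sheared genomic DNA to tiled oligonucleotide probes.
For most non-model organisms no reference genome exists, so `excapr`
implements the reference-free variant of the workflow: probes are designed
from a de novo *transcriptome* assembly, captured reads are assembled de
novo, and the contigs that are reciprocal best matches of the designed
targets — the *in-target assemblies* — replace the genome as the mapping
reference for every downstream step (QC metrics, error estimation, SNP
discovery).

This vignette explains the models and the tunable parameters, what the
built-in simulator does and does not emulate, and the choices made where the
design was genuinely open.

## Probe design

Targets are exons at least 200 bp long (shorter capture targets work poorly),
plus auxiliary classes with their own tiling densities:

| class              | tiling step | rationale                              |
|--------------------|------------:|----------------------------------------|
| `nuclear_exon`     | 4 bp        | the main target panel                  |
| `genomic_interval` | 2 bp        | divergent-source intervals need density |
| `mito`             | 20 bp       | very high copy number, light tiling    |
| `sry`              | 1 bp        | single short contamination control     |
| `control_gene`     | 4 bp        | qPCR enrichment controls               |

Probes are 60-mers. Because a transcriptome gives no intron sequence, probes
cannot extend across exon boundaries; to compensate, the first and last
`edge_window = 30` offsets of every nuclear exon are tiled at 1-bp steps
(*edge densification*), and a terminal probe flush with the target end is
always emitted. The 30-nt window is half the distance at which interior
coverage plateaus in the edge profile (~80–100 bp from the ends): beyond it
the interior 4-bp tiling alone sustains coverage. Edge densification cannot
remove the edge effect entirely — coverage still tapers where fragments can
only overlap the target from one side — which the edge-profile metric makes
visible.

Repeat-derived probes are *soft-masked*: the 15-mer frequency table of the
whole design reference (transcriptome plus any auxiliary genome, both
strands counted literally) is built once, and any probe containing a 15-mer
with frequency ≥ 50 is excluded. The threshold is deliberately stringent
because a fragmentary, divergent masking reference underestimates repeat
copy number. Masking is monotone in the threshold, and the whole design is
deterministic: identical inputs give byte-identical probe FASTA.

## Read filtration

Stages run in a fixed order with telescoping counts (the output of each
stage is the input of the next), so the filter report always reconciles:

1. **exact duplicate removal** — pairs identical in both mates collapse to
   the first occurrence. No quality-aware representative selection: the
   duplicate definition is exact sequence identity, so every copy carries
   the same bases.
2. **adapter trimming** — leftmost 3' adapter occurrence with ≥ 10 bp
   overlap and ≤ 10% mismatch truncates the read.
3. **quality trimming** — the 3' suffix maximising `sum(Q_min − q_i)` is
   removed (running-sum rule, `Q_min = 20`).
4. **complexity** — a pair is rejected if a 64-bp window's triplet-collision
   (dust-style) score exceeds 7, or ≥ 90% of a mate is one nucleotide.
5. **contaminant screen** — a pair is flagged when ≥ 80% of either mate's
   21-mers occur in the contaminant k-mer table (human/E. coli style
   screen). K-mers rather than alignment keep the step dependency-free and
   are adequate at the divergences involved.
6. **length floor** — both mates must survive at ≥ 36 bp.

Demultiplexing uses 7-nt barcodes; the barcode map is validated so that the
permitted mismatch budget cannot make assignment ambiguous (pairwise
distance must exceed twice the budget).

## Capture evaluation

All metrics use uniquely mapped, non-duplicate reads.

- **sensitivity** — % of targets with ≥ 1 covered base.
- **specificity** — % of aligned reads whose span overlaps a target span by
  ≥ 1 base (the overlap rule is the package's choice; the field usually
  leaves it implicit).
- **coverage** — per-target mean base depth; the threshold report mixes
  conventions deliberately (`≥ 1X` but strictly `> 5X`, `> 10X`) to mirror
  how such results are conventionally phrased.
- **uniformity / edge effect** — positions of 201–600 bp targets are binned
  by distance to the nearer end (20-bp bins); the profile exposes the edge
  taper.
- **reproducibility** — Pearson correlation of `log10(coverage + 1)` across
  shared targets between libraries.
- **GC dependence** — per-target mean coverage in 5% GC bins; extreme GC
  lowers capture efficiency.
- **divergence decay** — per-target divergence (mismatches over alignable
  bases against the in-target contig) binned at 1%; bins with < 3 targets
  are flagged low-support.

Sequencing error is estimated from *haploid* loci (mitochondrial contigs,
X-linked targets in males, SRY), where any within-sample variation is error:
`rate = non-consensus stacked bases / stacked bases`, consensus = per-column
majority, columns below depth 10 skipped so the consensus itself is
reliable. X-linked targets are recognised by a female/male mean-coverage
ratio in [1.9, 2.1] (diploid/haploid dosage); SRY reads in females flag
cross-sample contamination.

## Variant calling

Sites must satisfy depth ∈ [20, 5000] and a Phred-scaled site quality ≥ 30,
where the site quality is an explicit binomial tail: the probability that
all non-majority bases arise from sequencing error at the column's mean
base-quality error rate, capped at 2000. Zygosity at the pooled-species
level: a site is **polymorphic** when the minor allele has ≥ 2 reads and
≥ 20% frequency, **fixed** when the ≥ 90% consensus allele differs from the
reference base. Functional classes come from gene models: CDS codons are
translated in the annotated frame (standard genetic code); intron and UTR
positions are labelled by their containing feature. Codons that span a
splice junction are returned as `unclassified` and excluded from summaries —
the simulator emits frame-aligned exons so its ground truth never produces
them, and real gene models place them in a small minority of sites.

## The simulator

`simulate_gene_space()` builds ancestral genes (exon/intron/UTR structure,
spliced transcripts, proteins back-translated with random synonymous
codons, no internal stops by construction); `evolve_species()` plants
uniform point substitutions at a chosen rate (per contig if desired) plus
heterozygous sites between two haplotypes; `simulate_capture_reads()` draws
~N(250, 50) fragments around targets, captures each with probability

```
p = exp(-lambda * max(0, d_frag - d0)) * max(0, 1 - alpha * (gc - 0.5)^2)
```

with `lambda = 32`, `d0 = 0.05`, `alpha = 2`, then emits 100-bp read pairs
with per-base errors at 4×10⁻⁴ (Phred-consistent constant qualities),
PCR duplicates (verbatim re-emission), contaminant pairs, and 7-nt sample
barcodes, along with truth labels and truth alignments.

`d_frag` is the *planted local divergence level* of the fragment's locus,
not a per-fragment resample of realized mismatches. This is a deliberate
choice: the decay constants are calibrated so that ~9% divergence yields the
observed 3–4-fold coverage drop (`exp(-32 × 0.04) ≈ 0.28`), a relation
stated between divergence *levels* and coverage. Resampling mismatches per
fragment adds a Jensen-type inflation (`E[e^(−λd)] > e^(−λE[d])`) that
systematically weakens the realized fold to ~2.9 without changing the
intended biology; fixing capture probability at the locus divergence level
reproduces the calibrated decay exactly while realized substitutions still
drive the measured divergence, SNPs, and error estimates.

Male X dosage is emulated (half fragment rate, haplotype 1 only), and
off-target reads come from decoy contigs so the planted on-target fraction
is exact. Duplicate and contaminant fractions are planted as exact pair
counts, so truth-label recovery is exact, not approximate.

What the simulator does **not** emulate: indels (available only as an
option, off by default, though real divergent-locus alignments are
indel-rich), position-dependent quality decay and strand bias, GC-dependent
PCR amplification, library-size variation beyond the off-target ratio, and
assembly errors (the "assemblies" it provides are fragmented ground-truth
loci). Passing tests therefore demonstrate the pipeline's bookkeeping and
statistical behaviour under the stated model, not robustness to real
assembler artefacts.

The coverage-level generator `simulate_coverage_matrix()` (used for the
X-linkage screen) models per-target efficiency as lognormal (sdlog 0.7,
matching the wide per-target coverage spread) with within-target,
across-sample noise at CV 7% — capture reproducibility between libraries is
high, and with 20 female and 20 male samples this yields a female/male
ratio standard error of ≈ 0.044 at ratio 2, so the [1.9, 2.1] window
recovers X-linked targets with ≈ 98% power and essentially no autosomal
false positives.

## Numerical and procedural choices

- Alignment scoring defaults: match +1, mismatch −2, gap open −4, gap
  extend −1 (BLAST-like); a gap of length L costs `open + L·ext`. `N` never
  matches, so divergence estimates are conservative. No tool-specific
  scoring was available to inherit, so these are package defaults
  throughout.
- All internal coordinates are 0-based half-open; 1-based appears only in
  SAM/VCF output.
- Exon boundary transfer accepts placements covering ≥ 80% of the reference
  exon at ≥ 70% identity (tolerant of the ≤ 5% congeneric divergence with
  margin), projects exon ends through the alignment (so terminal mismatches
  trimmed by local alignment do not shift boundaries), and resolves
  overlap/colinearity conflicts by greedily keeping higher-scoring exons —
  deterministic and conservative.
- Annotation uses a translated-alignment score threshold (default 50 at
  match = 1) instead of an E-value: desk-scale search has no database-size
  context for E-values.
- Assembly merging replaces the usual multi-tool cascade (cluster, then
  overlap-merge) with one greedy cluster-then-consensus pass at ≥ 99%
  identity over ≥ 40 bp — parameters chosen for same-individual redundancy
  removal, not cross-species clustering. At mismatching columns the longer
  (earlier-processed) member wins.
- Reciprocal-best-hit ties break by score, then alignment length, then
  lexicographic id — fully deterministic.
- Divergence for decay binning is measured over the known in-target span
  (mismatches/alignable bases of the natural gap-free alignment). A fully
  local re-alignment would trim mismatch-dense ends at ~9% divergence and
  bias divergence downward, scattering targets out of their bins.
- Problem sizes in the tests and the acceptance script are desk-scale by
  design: tens of genes, thousands of read pairs, one or two simulated
  libraries, 10⁶ stacked haploid bases for error estimation — large enough
  for the binomial/property checks at their stated tolerances, small enough
  to run in minutes.

## Known limitations

- The local aligner is exact affine-gap dynamic programming; the
  reciprocal-best-hit search prescreens large problems by shared 12-mers
  (a pair with no shared 12-mer cannot reach the identity floor) but still
  aligns every surviving pair exactly, so it is meant for hundreds to a few
  thousand sequences, not genome-scale databases.
- Minus-strand gene models are supported by reflection; multi-isoform
  models and spliced codons are not classified.
- The SAM reader handles the subset the package writes (plus soft clips and
  simple gapped records reduced to their aligned span); it is not a general
  SAM validator.
- Specificity counts single reads, not pairs; with truth alignments both
  mates of a pair are counted independently.
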