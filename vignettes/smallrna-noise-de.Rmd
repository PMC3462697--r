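---
title: "Quantifying miRNAs and calling differential expression without replicates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying miRNAs and calling differential expression without replicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnoise)
```

## The problem

Deeply sequenced small RNA libraries are often produced without biological
replicates — one library per condition, each a pool of many individuals.
mirnoise implements the complete computational chain for comparing two such
libraries: read cleaning, canonical-miRNA annotation by an exact seed rule
with isoMIR merging, RPKM normalization, and a simulation-based
differential-expression (DE) statistic that works with a single library per
condition. The motivating use case is insect developmental transcriptomics —
comparing whole-body miRNA populations between the penultimate
(pre-metamorphic) and last (metamorphic) nymphal instars of the cockroach
*Blattella germanica* — but nothing in the pipeline is specific to that
system.

## Read cleaning

Reads arrive as FASTQ with per-base Phred qualities in 0–40; older Illumina
pipelines encode them at ASCII offset 64 (the package default; offset 33 is a
flag away). Cleaning runs in a fixed order:

1. **Quality filter.** A read is eliminated when at least 80% of its
   positions are below Q20 (`q_min = 20`, `bad_fraction = 0.8`). The boundary
   is inclusive — a read with exactly 80% low-quality bases is removed — and
   `N` calls count as low-quality regardless of score.
2. **End trimming.** Terminal low-quality bases, terminal homopolymer runs of
   ≥ 5 bases, and terminal perfect dinucleotide repeats of ≥ 3 units are
   removed iteratively from both ends until stable. The rules are
   end-anchored (interior bases are never touched), so every output is a
   contiguous substring of its input and the operation is idempotent. The
   thresholds (5 bases, 3 units) are declared package defaults for an
   operation usually described only qualitatively; both are configurable.
   Dinucleotide units must use two *distinct* bases so that rules (b) and (c)
   stay orthogonal. Adapter removal is assumed to have happened upstream.
3. **Collapsing** to unique sequences with counts (descending count,
   lexicographic tie-break, so output order is deterministic).
4. **Length filter**, keeping 10–28 nt inclusive — the window that covers
   mature miRNAs and their shorter degradation-resistant fragments.

Stage accounting (`PreprocessStats`) is conserved by construction: reads
removed by the quality filter plus reads surviving to trimming equal the raw
input, and collapsed counts sum to the reads entering the collapse.

## Annotation: the 17-nt seed rule and isoMIRs

Putative contaminants (rRNA/tRNA/other structured RNA, endosymbiont or viral
genomes) are screened by exact substring match of each cleaned sequence — on
both strands — against user-supplied reference FASTA files. This is a
deliberately strict, alignment-free stand-in for read mapping: for 10–28 nt
queries at zero mismatches, exact substring membership and an aligner agree.

A read is assigned to a catalog mature miRNA by a 5′-anchored,
mismatch-free rule: the *seed* of a catalog entry is its first 17
nucleotides; a read of ≥ 17 nt matches when its first 17 nt equal the seed
exactly, and any additional 3′ bases are ignored (this is what merges 3′
isoMIR length variants into one miRNA); a read shorter than 17 nt matches
when it equals the corresponding seed prefix exactly. Note this "seed" is a
library-annotation device, not the 2–8 nt targeting seed of miRNA–target
biology. Matching treats U and T as identical and is case-insensitive.
Catalog entries shorter than 17 nt cannot define a seed and are rejected
with a warning rather than silently given shorter seeds — a shorter seed
would make the rule more promiscuous for those entries only.

Two open choices are resolved as follows, both configurable:

* **5′ anchoring.** Reads are required to start at mature position 1
  (`max_5p_offset = 0`). The seed definition presupposes a fixed 5′ anchor,
  and 5′ isoMIR variation would silently shift the seed window.
* **Multi-matching reads** (identical seeds in the catalog) are discarded
  with logging by default, avoiding double counting; `all` and `first`
  policies exist for sensitivity analyses.

After annotation, the poorest-represented miRNAs are removed by a
cumulative-tail rule: miRNAs are sorted by ascending summed count across
libraries and the longest prefix whose cumulative count stays within 0.01%
of the summed raw-read totals is dropped. The alternative per-miRNA reading
(drop every miRNA whose own share is < 0.01%) is implemented as
`method = "per_mirna"`; the cumulative reading is the default because it is
the one under which observed low-count miRNAs (a few hundred reads in tens
of millions) survive, as they visibly do in the bundled reference table. The
filter never empties the set: the top-abundance miRNA is always kept. The
kept set is shared across libraries so that contrasts are defined for every
retained miRNA.

## Quantification

Counts are normalized to RPKM, `count × 1e9 / (L × N)`, with two
conventions that matter:

* **N is the raw (pre-filter) read total** of the library, not the clean
  total. Back-solving `L = 1e9·count/(RPKM·N)` on the bundled reference
  table yields effective lengths in the plausible 17–21 nt band for all but
  two or three miRNAs per library only under raw totals — the clean totals
  are ~17× smaller and would imply lengths of hundreds of nucleotides. One row
  (miR-275-3p in library 1, implied length ≈ 8.8 nt) is numerically
  inconsistent with every other row under any convention and is excluded
  from this consistency oracle; the package flags it rather than repairing
  it.
* **L is the count-weighted mean isoMIR length** of the miRNA's observed
  variants (typically ~18–20 nt), not the catalog mature length;
  `effective_length()` computes it from the per-variant breakdown.

The pairwise contrast between libraries is summarized per miRNA by
`M = log2(x1/x2)` and `D = |x1 − x2|`, with `x_i` the RPKM in library *i*.
Zeros are replaced by a pseudo-expression — 0.5 counts converted through the
table's median RPKM-per-count scale — before the ratio only; D always uses
the raw values, so the pseudo-value keeps M finite without disturbing D.
For reporting, M is rounded to 3 decimals and D to 2.

## The no-replicate DE statistic

With one library per condition, biological variance cannot be estimated;
instead technical replicates are *simulated* and each miRNA's observed
signal is ranked against the technical noise:

1. For each condition, draw `nss = 5` replicates from a multinomial with
   probabilities proportional to the observed counts and size
   `round(depth × total)`, with depth uniform in `pnr ± v` (`pnr = 0.2`,
   `v = 0.02`). These constants are the published defaults of the
   simulated-replicate method and are exposed as parameters.
2. Normalize each simulated replicate onto the observed RPKM scale: counts
   are multiplied by the per-miRNA observed RPKM/count factor and divided by
   the replicate's realized depth fraction — algebraically identical to
   RPKM with library total equal to depth × raw total. This convention lets
   the stage run equally from freshly annotated profiles or from an
   externally normalized count/RPKM table.
3. For every within-condition replicate pair (both conditions pooled —
   pooling doubles the cloud at no cost and symmetrizes any
   condition-specific depth effects) and every miRNA, record (|M|, D): the
   **noise cloud**.
4. Each miRNA's DE probability is the fraction of noise pairs its observed
   (|M|, D) strictly dominates on both coordinates. Strict dominance means
   ties count against the signal — the conservative choice. The probability
   is monotone in |M| and D and invariant under common rescaling of all
   RPKMs; it is *not* a p-value and is not multiplicity-corrected.
5. miRNAs with probability > 0.8 are called DE, in the direction of the
   sign of M; each direction's table is ordered by descending |M|.

On the bundled reference table this yields a median split of 3 miRNAs up in
the pre-metamorphic library and ~39 up in the metamorphic one over 11 seeds
— the borderline calls sit at printed probabilities 0.81–0.85 and flip with
the simulation seed, which is why the split is assessed as a median across
seeds rather than from a single run.

Seeding: the condition-2 simulation uses `seed + 1` so the two conditions
get distinct but fully determined streams; every stochastic result carries
its parameters in the returned object.

## The synthetic-data generator

`synth_spec()` / `generate_libraries()` emulate the statistical structure
the analysis assumes, so every stage is testable without any external data:

* ~60 miRNAs with log-normal base abundances (meanlog 6, sdlog 2 on the
  natural-log scale), chosen to reproduce the reference table's dynamic
  range — the most abundant miRNA holds tens of percent of all reads and
  the rarest a few hundred reads in millions.
* 30% of miRNAs carry a planted 4-fold change, random direction. Planting
  is **mass-balanced**: each planted miRNA's expected between-library ratio
  is exactly the fold-change, while up- and down-planted masses are
  equalized so null miRNAs keep identical expected proportions in both
  libraries. Sequencing observes proportions, so naive one-sided planting
  with a heavy-tailed abundance model shifts *every* null miRNA (by up to
  ~1.7 log2 units when the dominant miRNA is planted), making "null"
  ground-truth labels meaningless. Mass-balancing is the standard device
  that keeps the ground truth well-defined; it is a property of the
  generator, not of the inference.
* 3′ isoMIR variation with offsets −2..+2 (probabilities 0.1/0.15/0.5/
  0.15/0.1); 5% contaminant reads drawn as exact substrings of a generated
  decoy reference; 2% low-quality reads built to fail the quality rule.
  Catalog sequences and isoMIR extensions are rejection-sampled to be
  stable under end trimming, so clean synthetic reads survive preprocessing
  unchanged — the generator plants artifacts only where it labels them.

What the generator does *not* emulate: sequencing substitution errors, PCR
duplication, 5′ isoMIR variation (available behind `max_5p_offset` testing
only), adapter read-through, and — by design — compositional shifts between
libraries. Passing recovery tests therefore demonstrate correctness of the
pipeline's accounting and of the DE statistic under its own model, not
robustness to those artifacts in real data.

## Problem sizes and numerical choices

The validation suite runs the DE stage at the reference scale (61 miRNAs,
noise cloud of 1,220 pairs), planted-recovery at the generator's default
500,000 reads per library over 20 seeds at the count level, and full
FASTQ-level end-to-end runs at 4,000–30,000 reads per library — sizes at
which multinomial sampling error is still the dominant term, so the 3-
standard-error recovery checks are meaningful. Volcano plots place D on a
log axis with a floor of 1e-2 RPKM (D spans five orders of magnitude);
result tables are plain TSV with fixed decimal formatting so that re-running
a pipeline with the same seed reproduces files byte-identically.

## Known limitations

* The DE probability ranks signal against *technical* noise only; with a
  single pooled library per condition, biological variability is
  unidentifiable and calls are correspondingly liberal (most of the
  reference table is called DE at threshold 0.8).
* RPKM with raw-total denominators inherits any between-library composition
  shift; the statistic measures relative, not absolute, abundance changes.
* Exact substring contaminant screening cannot remove reads with sequencing
  errors relative to the contaminant reference; at zero mismatches this is
  the faithful counterpart of the strict annotation rule, not a general
  decontaminator.
* The seed matcher is exact by design; a single 5′ SNP or editing event
  unassigns a read.
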