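---
title: "Virus-host crossfire analysis: models, parameters and design notes"
author: "virotope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virus-host crossfire analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virotope)
```

## The scientific problem

Hot-spring phototrophic mats are dominated by a handful of filamentous
cyanobacteria, and the viruses that infect them leave two complementary
genomic records of the ongoing arms race. The host side keeps CRISPR
arrays: direct repeats separated by unique spacers, each spacer a
souvenir of a past infection. The viral side accumulates single
nucleotide variants (SNVs), and where those variants fall inside a
proto-spacer — the viral segment a spacer targets — they can blunt the
host's immunity. Reading both records at once ("crossfire" analysis)
requires a chain of steps: clean the shotgun reads, separate viral from
cellular signal, assign viral reads taxonomically, recover circular
phage genomes, find CRISPR arrays on host contigs, place spacers onto
the phage genome, call SNVs inside proto-spacers, and quantify
everything as abundance and activity ratios.

This package implements that chain at desk scale, with a
synthetic-community generator standing in for raw sequencing data so
every stage is testable against known ground truth.

## The synthetic community

`sim_config()` fixes the study conditions. Its defaults emulate the
system the pipeline was designed around: a 40,740 bp circular
cyanopodovirus genome at 43.9% GC carrying 39 ORFs, organized in two
transcriptional clusters (replication-module genes on the sense strand,
virion-assembly genes on the antisense strand, as in T7-like phages); a
20 kb host contig carrying CRISPR arrays with 36 bp repeats and 36 bp
spacers; 100 bp single-end reads with a per-base substitution error
rate of 10^-3 (Q30).

Design choices worth knowing:

* **Base composition.** Genomes are uniformly random permutations of a
  fixed base multiset whose composition matches `gc_target`
  (`round(L * gc)` G+C bases). Exact-composition sampling keeps the
  realized GC at the target for any genome length, so genome metrics
  are reproducible to the precision at which they are usually printed;
  i.i.d. sampling would leave a residual binomial spread of about a
  quarter of a percentage point at this genome size.
* **Quality model.** Every read carries a constant Phred quality
  `Q = -10 log10(error_rate)`, and per-base errors are drawn at exactly
  `error_rate`. The point of this deliberately rigid model is that the
  SNV caller's error model is then *exact*, so simulated-recovery tests
  measure the caller, not a mismatch between simulator and caller.
* **Spacer planting.** Each phage-derived spacer picks its strand by a
  fair coin; planted mismatches are drawn without replacement from
  interior spacer positions, never the termini, so that recovered
  placement coordinates are unambiguous.
* **SNV planting.** A planted variant with fraction *f* is applied to
  each covering read by an independent Bernoulli draw, i.e. realized
  fractions are binomial around *f* — the same model the caller
  assumes.
* **Reads** are drawn uniformly from both strands at the requested mean
  fold-coverage (`n = depth * L / read_length`, so realized coverage is
  within rounding of the request). Indels, paired ends and
  amplification bias are out of scope.

What the generator does *not* emulate: real error profiles (quality
decay along the read, context-dependent errors), repeat-rich host
backgrounds, strain mixtures beyond biallelic sites, and gapped
variation. A green test suite therefore demonstrates correctness of the
algorithms under the stated model, not performance on arbitrary real
libraries.

The package also ships, as `load_virotope_table()`, the 25-row
reference table of spacer/proto-spacer records (with SNVs, allele
frequencies and codon effects) that the report stage reproduces the
summary counts of. Cells are kept verbatim, including typographic
quirks of the printed original; the en dash encodes an empty cell.

## Read quality control

`qc_pipeline()` applies, in order: adapter trimming, 3' quality
trimming, a 5' hard clip, a length filter, and a DUST low-complexity
filter. Defaults: minimum length 30 bp, quality cutoff Q28, clip 5
bases, adapter overlap at least 10 bp (perfect match), DUST threshold
7.

* Adapter trimming truncates at the leftmost perfect match of an
  adapter prefix against a read region running to the 3' end. No error
  tolerance: overlaps below the minimum are ignored.
* Quality trimming uses the partial-sum rule (the BWA convention):
  scanning from the 3' end accumulating `cutoff - q_i`, the read is cut
  where the running sum is maximal and positive. Ties resolve toward
  trimming less.
* The DUST score is computed over the whole read as a single window:
  with `w` the read length and `c_t` the overlapping-triplet counts,
  `score = 100 * sum c_t (c_t - 1) / 2 / ((w - 2)(w - 3) / 2)`.
  Short-read lengths make sliding 64 bp windows moot; a homopolymer
  scores 100, a read of all-distinct triplets 0. Reads shorter than 4
  bases after trimming score 0 by convention (the formula's denominator
  vanishes).
* The order of operations is fixed as listed. Whether the 5' clip is
  applied before or after adapter removal is a genuinely open choice;
  clipping after adapter removal was chosen so the clip always removes
  biological 5' bases rather than adapter remnants.

## Viral profiling

Recruitment keeps hits with query coverage strictly over 0.65 and
E-value strictly under 10^-3. Taxonomic assignment drops hits with bit
score below 30, then takes the lowest common ancestor of the remaining
hit taxa: the deepest node that is ancestor-or-self of all of them. No
"top-percent" bit-score band is applied — only the stated floor. Reads
with zero hits are "unrecruited", which the package distinguishes from
"unassigned" (hits present but all below the score floor).

Cellular read removal places each read end-to-end on the cellular
references (both strands) using exact 20-mer seeds and an ungapped
substitution-only comparison, discarding reads with at most 5%
mismatching positions. Ignoring indels is a desk-scale simplification:
a seeded ungapped scan can also miss a valid placement when mismatches
are spread so that every seed-length window contains one; with the 5%
budget and 20 bp seeds this requires adversarial spacing that real
substitution errors essentially never produce.

Profiles roll assignments up to a requested rank (assignments above the
rank are excluded from that rank's rows) and standardize by total
library size. Host rollup maps species-level viral assignments to host
phyla through a supplied virus-to-host table; coarser assignments are
tallied as host-unresolved.

## Genome screening

A contig strictly over 5,000 bp is circular iff its prefix recurs as
its suffix — an exact terminal direct repeat of at least 20 bp (both
parameters adjustable; the repeat is capped at half the contig so
prefix and suffix cannot overlap). The duplicated suffix is trimmed,
which makes detection invariant under rotation of the underlying
circle. Exactness (no mismatches in the repeat) is a deliberate choice:
assembler-produced terminal duplications are copies of the same
sequence.

Hallmark flagging is term-based: a contig is flagged iff any ORF
product matches, case-insensitively, a vocabulary shipped as an
editable text list (capsid, terminase, portal, tail, DNA polymerase,
primase, helicase, scaffold). `strand_clusters()` counts adjacent
transcriptional-direction switches over the ORFs in genome order; a
two-cluster genome has exactly one switch.

## CRISPR detection

`find_arrays()` seeds on exact 23-mers (the repeat lower bound)
recurring with a spacing compatible with one repeat plus one spacer
(48-115 bp between instance starts), extends every seeded instance to
the maximal *unanimous* repeat (columns where all instances agree), and
accepts arrays with at least 3 instances whose spacers fall within
25-60 bp. Repeat bounds are 23-55 bp. Overlapping candidates (one array
found from many seeds) are resolved by keeping the candidate with more
repeats, ties to the leftmost.

Unanimous extension is stricter than the declared 1-mismatch-per-
instance tolerance; it makes planted-array recovery exact and
deterministic. A rare chance agreement of all instances one column past
the true repeat can extend a boundary by a base; under a fixed seed
this is deterministic and the recovery tests verify it does not occur
under the shipped conditions. Detection commutes with
reverse-complementing the contig up to coordinate mirroring.

Locus activity counts RNA reads sharing an exact match of at least 31
nt with the locus (either strand) — a desk-scale proxy for read mapping
— and normalizes as RPKM.

## Spacer-to-proto-spacer matching

`match_spacer()` performs an exhaustive end-to-end comparison of the
spacer and its reverse complement at every genome offset, emitting
placements within a total Hamming-distance cap (default 3, matching the
largest mismatch count the reference table reports). Exhaustive search
is exact at these sizes, so there is no seeding heuristic to reason
about. Coordinates and mismatch positions are always reported 1-based
on the genome plus strand, so a spacer and its reverse complement
report the same interval with opposite strand labels — the convention
the reference table uses for its 48°C/66°C spacer pair. Genome `N`
bases count as mismatches; indels are not modeled. For circular
genomes, placements wrapping the origin are included, with positions
reported modulo the genome length.

## SNV calling and annotation

`build_pileup()` tallies per-site A/C/G/T counts from ungapped
alignments, keeping bases at or above Q20 and recording the mean
per-base error probability of the counted bases. `call_snvs()` tests,
at each site with depth at least 10, the top non-reference allele count
k of n against the upper binomial tail `P(X >= k | n, err/3)` — the
factor 3 spreads the pooled error rate over the three possible
erroneous bases — and emits calls at the Bonferroni-corrected level
`alpha / n_tested_sites` (alpha = 0.05). The reported frequency is k/n,
unweighted by quality.

This is a deliberately transparent caller: no strand-bias filter, no
indel model, one tested allele per site. Its value here is that its
statistical behaviour is fully checkable — on null pileups the
family-wise false-positive rate is within alpha, and planted fractions
are recovered within binomial tolerance (both are tested).

Codon effects: the codon index inside an ORF is `floor((pos - start) /
3)` on the plus strand and `floor((end - pos) / 3)` on the minus
strand; codons are read in coding orientation (reverse-complemented for
minus-strand ORFs) and translated by the standard genetic code. ORF
lengths not divisible by 3 are an error, not a guess. Sites outside
every ORF are noncoding. Spacer-allele concordance reads the spacer
base aligned to the SNV position (complemented for minus-strand hits)
and reports that allele's population frequency — alt frequency, or one
minus it for the reference allele.

`make_virotope_report()` joins spacers, placements and SNVs into the
reference table's column layout, one row per (spacer, hit), ordered by
locus then proto-spacer start. `summarize_virotopes()` counts rows,
distinct loci, SNV- and mismatch-bearing rows, and SNV entries by
effect. Entries are counted per (row, listed position): a genomic site
reported under two temperatures counts twice, which is the convention
required to reproduce the printed totals (22 entries = 13 synonymous +
7 nonsynonymous + 2 noncoding). The printed table contains a codon pair
labelled "All silent" that is not silent under the genetic code (and
differs at more than one position) — almost certainly a typographic
slip in the original; the fixture preserves the label as printed while
the package's own classifier always follows the code.

## Abundance and activity

`rpkm()` is `count / (length_kb * total_reads / 1e6)`.
`virus_host_ratio()` divides a viral feature's RPKM by a host marker
gene's RPKM (the marker standing in for host abundance);
`dna_rna_ratio()` divides a feature's metagenomic RPKM by its
metatranscriptomic RPKM. Both are flagged undefined (NA) at zero
denominators, and both are invariant to joint library-size rescaling.
RPKM was used for the marker as well as the virus; log10 is applied
only at reporting, with zero mapped to "below detection".

## Problem sizes and numerical choices

The shipped tests run the matcher-against-oracle comparison on 200
random instances (genomes up to 2 kb, spacers 20-45 nt, caps 0-3), the
caller calibration on 100 replicates of 10 kb null pileups at depth
100, and frequency recovery at depth 1000 — sizes chosen so the whole
suite completes in well under a minute while keeping binomial
tolerances meaningful. Ties in the caller (equal top alt counts)
resolve in base order A, C, G, T; ties in quality trimming resolve
toward trimming less; overlapping CRISPR candidates resolve to more
repeats, then leftmost. Degenerate inputs (empty reads, zero-length
loci, ORFs with incomplete codons, spacers longer than the genome,
taxa missing from the taxonomy) raise errors naming the violated
constraint rather than guessing.

## Known limitations

Real-data totals that depend on the original sequencing libraries
(genome-wide SNV counts per temperature, spacer inventories, figure
abundances) are outside what a synthetic community can certify; the
pipeline reproduces the published *summary* quantities and satisfies
the per-module properties instead. The matcher models substitutions
only; the caller is biallelic per site; the CRISPR detector requires
mismatch-free repeat instances in practice; the cellular filter and
RNA recruitment use exact seeds rather than full alignment. Each of
these is the recorded, tested behaviour — not an approximation left
implicit.
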