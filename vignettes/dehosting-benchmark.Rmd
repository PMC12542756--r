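---
title: "Benchmarking host-read removal with synthetic truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking host-read removal with synthetic truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dehostbench)
```

## Why this benchmark exists

Metagenomic samples from host-associated sites are mostly host DNA.
Dehosting — discarding reads that match a human reference — is the
first step of essentially every metagenomic pipeline, and its quality
depends on two choices: the alignment/classification algorithm and the
reference assembly. Incomplete references are blind to reads from the
regions they lack; in the human case those are overwhelmingly
satellite-repeat regions (pericentromeric `(GGAAT)n` arrays of the
satellite II/III families, acrocentric short arms) that only a complete
telomere-to-telomere assembly resolves. Missed host reads contaminate
the microbial fraction downstream, and historic leakage of such reads
into public microbial assemblies means reference databases themselves
carry human sequence.

Evaluating dehosting methods on real data requires a truth label per
read, which real data does not come with. This package therefore builds
the whole evaluation around *synthetic data with known truth*, plus the
adjudication scheme used to construct truth labels when several methods
disagree on real data. Every component is exercised end to end on
simulated inputs whose correct answers are known by construction.

## The simulation model

`sim_config()` fixes the study conditions. Defaults (all overridable):

| parameter | default | meaning |
|---|---|---|
| `host_contigs` | chr1, 200 kb | host genome size |
| `exclusive_region_spec` | chr1:150000–180000 | sequence absent from the legacy reference |
| `satellite_unit` | `GGAAT` | repeat unit of the satellite arrays |
| `satellite_array_lengths` | 2 × 8 kb | arrays placed inside the exclusive region |
| `host_fraction` | 0.95 | expected host share of reads |
| `read_length` | 75 bp (50 for MGI-like) | single-end read length |
| `substitution_error_rate` | 0.001 /base | sequencing error model |
| `microbe_spec` | 10 microbes + 1 flagged virus | spiked-in community |

Design choices, made once:

* **Background sequence is i.i.d. uniform A/C/G/T** and satellite
  arrays are the only low-complexity structure. This makes "unmappable
  only via the exclusive regions" constructible: a read can evade the
  legacy reference only because its source sequence was deleted, never
  because of accidental background similarity (31-mer collision
  probability between unrelated random sequences is ≪ 1e-9).
* **Substitution-only errors, constant base qualities.** The benchmark
  logic operates on labels; indels and quality models would add realism
  but no discriminating power for any tested property. Reads are drawn
  from both strands.
* **Host fraction 0.95** reflects the typical situation the benchmark
  targets (host content above 90% in most mock and clinical samples,
  up to ~99% in low-biomass ones).
* **The exclusive region is 15% of the host genome** and contains the
  satellite arrays, so the legacy reference's expected sensitivity
  deficit is ~15 percentage points — large enough to measure on every
  sample at 4,000 reads, i.e. a deliberately scaled-down but
  directionally faithful version of the real contrast (where exclusive
  sequence is ~7% of the genome and the sensitivity deficit fractions
  of a point, measured on millions of reads).
* **A flagged viral taxon** emulates the host-associated virus whose
  reads are excluded before benchmarking in the real protocol;
  `confusion()` takes the excluded read set explicitly.
* **The per-microbe dilution series of the original mock design is not
  reproduced**; microbes are sampled by genome length within the
  non-host fraction. The dilution factors were never published at the
  level needed and nothing in the evaluated properties depends on
  relative microbial abundances.

Every generator is deterministic in `(config, seed)`: one master seed
is fanned out through named substreams (`stage_seed`), so stages are
independently reproducible and two runs with the same config produce
byte-identical FASTA/FASTQ/TSV outputs.

## Per-read labels

`labels_from_alignment()` mirrors discard-if-aligned semantics: a read
is host iff it has at least one aligned record that is neither
secondary (0x100) nor supplementary (0x800). Secondary or supplementary
records never confer the label on their own; conflicting primary
records are an error, not a silent choice. `labels_from_kraken()`
labels a read host iff the host clade (Chordata, taxid 7711, both
configurable) appears anywhere in the assigned taxid's lineage,
inclusive. `kmer_classify_reads()` is the built-in stand-in for an
aligner: host iff the read shares ≥ `min_shared` canonical k-mers
(lexicographic minimum of k-mer and reverse complement) with the
reference k-mer set, default k = 31. It exists so that real label
matrices can be produced and tested without external binaries; it is
not a replacement for a production aligner.

## The adjudication cascade

`adjudicate()` fuses a rectangular label matrix into one gold label per
read:

1. **Consensus** — all methods agree.
2. **Category concordance** — at least one alignment-based *and* at
   least one k-mer-based method label the read host. "At least one of
   each" is the implemented reading; requiring exactly one of each
   would be strictly weaker and is never what a concordance rule means
   in practice.
3. **Fallback** — host iff some hit lies in the host clade with
   identity > 90 *and* query coverage > 90 (strict inequalities, both
   configurable). Query coverage is aligned-query-span / read length ×
   100 — the common convention, adopted because no other definition is
   implied by the data formats involved. A read reaching this step
   without having been queried is an error; an empty hit list is a
   valid "no hit".

The test suite checks this cascade against an exhaustive brute-force
enumeration (all label combinations over four methods × three hit
states), a monotonicity property (flipping any single vote toward host
can never demote a gold host label), and the identity that perfect
simulated tools reproduce the synthetic truth exactly.

## Metrics and the comparison framework

`compute_metrics()` reports sensitivity, specificity and the Matthews
correlation coefficient. Zero-denominator cases are flagged
(`*_undefined`) and reported as `NA` (MCC as 0 with a flag) rather than
silently zeroed — silent zeros would leak into the paired statistics as
fake differences. The MCC denominator is evaluated as a product of four
square roots, so read-scale counts (1e9 and beyond) cannot overflow
double precision; agreement with a naive exact evaluation is tested to
1e-12 where the naive form is itself exact.

`compare_all()` implements the comparison framework: Kruskal–Wallis
omnibus over methods, then for each method pair the per-sample paired
differences, their plain median (in percentage points; the
Hodges–Lehmann estimator was deliberately not used — the reported
quantity is the median of the per-sample differences, nothing subtler),
a one-sided Wilcoxon signed-rank test in the direction of the median,
and Benjamini–Hochberg adjustment with the family defined as all pairs
of one metric table. The Shapiro–Wilk gate is computed and logged but
advisory: the nonparametric path always runs.

`wilcoxon_signed_rank()` discards zero differences (the classic
treatment, matching the default of standard statistical environments),
ranks absolute differences with average ranks under ties, and computes
the one-sided p exactly for n ≤ 25 by dynamic-programming enumeration
of all sign assignments (ranks doubled to keep tied half-ranks on an
integer lattice); beyond that, a normal approximation with tie
correction and continuity correction. The exact branch is verified
against full 2^n enumeration and against the signrank distribution in
the untied case; exact and approximate branches agree within 0.01 at
n = 20.

## False-negative characterization

GC content excludes ambiguous bases from numerator and denominator;
all-N reads are flagged undefined. K-mer spectra skip N-containing
windows; k defaults to 5 in the pipeline because the satellite unit is
5 bp long, so the signature of satellite-origin false negatives — the
rotations of `GGAAT` and, for minus-strand reads, of its reverse
complement `ATTCC` — appears directly as the dominant spectrum entries.
`map_read_positions()` is a seed-cluster placement (shared canonical
k-mers, densest positional cluster), adequate for ideogram-style
summaries; reads from repeat arrays legitimately place anywhere within
the array, and the placement of such reads should be read as "this
array", not "this offset". `taxa_tally()` reports the top-n taxa with a
lexicographic tie-break at the cut and an aggregated remainder.

## The contamination screen

`exclusive_regions()` takes whole-genome alignment coverage as PAF
(target = the complete genome) and returns, per contig, the complement
of the merged covered intervals, dropping regions shorter than 100 bp.
On a pure-deletion relationship this recovers the deleted regions
exactly, and a self-alignment yields the empty set — both tested.

`detect_contaminants()` implements the two-k-mer rule: candidate hits
(from real BLAST tabular output, or the built-in matcher) are filtered
to ≥ 100 bp and identity > 90%; each surviving exclusive sequence is
cut into non-overlapping 100 bp segments; a genome is called
contaminated by that sequence only if ≥ 2 segments match it, a segment
matching when ≥ 90 of its bases (`kmer_size × min_identity / 100`)
match inside a hit, counted over the hit∩segment overlap by direct
sequence comparison. Matching bases are counted over the overlap rather
than requiring full containment because an edge substitution trims an
ungapped alignment by a few bases without changing what the segment
matched. Overlapping calls on one target contig are merged before any
length accounting, so contaminant bases are never double-counted in the
ratio. The parenthetical variant of the rule tied to a specific
database ("two species") is treated as an aside, not a separate code
path.

The built-in matcher is exact-16-mer seeding, per-diagonal chaining
(gaps ≤ 100 bp), and ungapped X-drop extension (+1/−2, drop 20) on both
strands, with identity computed over the full extended span. It is a
desk-scale Blastn analogue for substitution-level contamination, not a
general aligner: gapped or rearranged contamination is out of its
scope, and real Blastn tabular output is accepted unchanged.

`contamination_report()` computes contaminant bases / genome length,
flags genomes above 0.01% as severely contaminated, and reports the
fraction of contaminant bases on small contigs or near contig ends.
"Small" (≤ 10 kb) and "edge" (within 1 kb of a contig end) are this
package's defaults — the qualitative observation they quantify does not
come with published numbers — and both are parameters.

Detection guarantees, under this package's conditions: plants are
copied with a deterministic substitution count `round((1−identity)·L)`,
so a 200 bp plant at identity ≥ 0.95 carries ≤ 10 substitutions — too
few to push any 100 bp segment below 90 matching bases or to destroy
every exact 16-mer seed (ten cuts cannot make eleven gaps all shorter
than 16 in 190 bases). Recall is therefore 100% for segment-aligned
plants ≥ 200 bp at identity ≥ 0.95, which the test suite verifies over
50 seeded simulations together with zero false calls on clean genomes.
A 200 bp plant whose source offset is *not* aligned to the 100 bp
segmentation can cover only one full segment and may legitimately be
excluded by the two-k-mer rule; from 300 bp, coverage of ≥ 2 full
segments holds at any offset.

`residual_host_screen()` flags dehosted reads sharing canonical k-mers
(default k = 25) with the exclusive sequences — the host reads a legacy
reference could not remove. Note that the reported fraction is relative
to the *dehosted* read set: under these study conditions (95% host,
15% exclusive) the dehosted set is small and residual-host-dominated,
so the fraction is large by construction; on real data, where the
dehosted set is overwhelmingly microbial, the same quantity is a
fraction of a percent.

## The end-to-end pipeline and problem sizes

`run_benchmark()` chains everything from one YAML-serializable config:
15 samples × 4,000 reads × 75 bp against a 200 kb host genome, two
built-in classifier methods (full and legacy reference) plus two
simulated screeners, adjudication with a truth-derived fallback hit
table, metrics, all pairwise comparisons, FN characterization,
the planted-contamination screen and the residual screen, with one
structured log line per stage and a manifest of file digests. These
problem sizes were chosen so that every measured contrast is far
outside its sampling noise (the legacy sensitivity deficit is ~150
standard errors at 4,000 reads) while the complete run stays under a
minute on one core; scaling `n_reads` or the genome up changes no
qualitative result.

## What passing tests do and do not show

The synthetic benchmark demonstrates that every component implements
its contract: the cascade equals its enumeration oracle, operating
points are recovered within binomial error, the exact test equals
enumeration, regions and plants are recovered exactly, and the
full-vs-legacy contrast comes out in the constructed direction with the
constructed magnitude. It does *not* show anything about the relative
merits of real aligners on real reads: real error profiles, GC bias,
paired-end information, gapped contamination, and real repeat
landscapes are all outside the generator. The package's claim is that
the *evaluation machinery* is correct, so that conclusions drawn with
it on real label matrices and alignments stand on tested ground.

## Known limitations

* The gold standard inherits the bias of its inputs: when all methods
  share a blind spot, the cascade cannot see it (on real data, a small
  fraction of genuinely similar bacterial reads is annotated host for
  this reason; no correction is attempted).
* The built-in matcher is ungapped; indel-mutated contamination
  requires real Blastn input.
* `map_read_positions()` reports seed clusters, not base-accurate
  alignments.
* Paired-end reads, indel errors and quality-aware simulation are out
  of scope by design.
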