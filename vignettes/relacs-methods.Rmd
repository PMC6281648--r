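---
title: "Methods: in silico digestion, barcode decoding and quantitative normalization for multiplexed ChIP-seq"
author: "relacs package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digestion, decoding and normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relacs)
```

## The experimental design this package models

In restriction-enzyme-based multiplexed ChIP-seq, chromatin is fragmented
*inside intact nuclei* by a restriction endonuclease with a very frequent,
degenerate recognition site — the blunt cutter CviKI-1, which cuts RG|CY
(R = A/G, Y = C/T). Each sample's nuclei then receive a hairpin adapter
carrying a sample-specific inline ("nuclear") barcode, ligated to both ends
of every chromatin fragment. Barcoded nuclei are pooled and a single
immunoprecipitation is performed on the pool, which removes between-sample
ChIP variability by construction. After sequencing, each paired-end read
carries the barcode at the 5' end of *both* mates, followed by a fixed
junction base (the T complementary to the A-tail), followed by genomic
insert.

The package implements the computational side of this design:

1. **genome digestion** — where can the enzyme cut, and where can it not;
2. **barcode design** — which barcode sets decode unambiguously;
3. **demultiplexing** — assigning pooled reads back to samples;
4. **quantitative normalization** — comparing samples via their
   multiplexed input controls;
5. **simulation** — a generative model of the whole pipeline with a
   ground-truth manifest, so that 1–4 are testable without any downloads.

## In silico digestion

`scan_sites()` reports every position where the IUPAC motif matches,
recording the cut as the 0-based position of the first base 3' of the
blunt cut (pattern start + cut offset, 2 for RG|CY). Conventions, chosen
once and used everywhere:

* **Coordinates** are 0-based and half-open, matching BED, including all
  written output.
* **Ambiguity**: a genome base matches a pattern code only if it is a
  concrete A/C/G/T inside that code's set. N in the genome never matches
  anything. This is the conservative choice — an N-rich assembly region
  contributes no phantom sites — and makes counts reproducible across
  assemblies with different masking.
* **Strand**: RGCY is its own reverse complement as a degenerate pattern,
  so forward-strand scanning is complete; the cut sites of the two
  orientations coincide because the cut is central. For non-palindromic
  motifs `both_strands = TRUE` scans the reverse complement too and merges
  the deduplicated cut positions.
* **Overlaps**: overlapping matches are all reported (RGCY can overlap
  itself, e.g. `GGCGCT`).

Matching is delegated to `Biostrings` fixed-subject matching, which
implements exactly this ambiguity rule; the test suite holds it against an
independent character-by-character sliding-window oracle on hundreds of
random sequences, exact set equality.

**Fragments and gaps.** Consecutive cut sites define half-open fragments.
A *gap* (blind region) is an inter-site interval strictly longer than a
threshold (default 1000 bp): inserts from such regions are too long for
short-read sequencing, so the assay cannot see them. `gap_report()` returns
the gap set, and the *blind fraction* = gap bases / total genome length.
Two conventions were genuinely open and are both implemented behind the
`include_terminal` flag: chromosome-terminal segments (before the first and
after the last site) are *excluded* from gap statistics by default, since a
terminal segment has only one cut end and its "length" conflates assembly
edges with site depletion. The denominator of the blind fraction is the
full genome length including N runs; excluding N runs would make the
fraction depend on assembly masking conventions.

**Cutability and accessibility.** Site *density* per region class
(`site_density_by_class()`: sites falling in the class / class length in
kbp) measures how cuttable a class is in principle. Site *usage*
(`cut_usage()`: observed fragment ends per site, per class, relative to the
genome-wide mean) measures how often existing sites are actually cut —
in real data a proxy for chromatin accessibility. Observed fragment ends
that do not coincide with any cut position are tallied as violations and
excluded rather than rounded to the nearest site; a non-zero tally signals
that the fragments were not produced by the digestion they are being
compared against.

## Barcode design and the decoding guarantee

Decoding tolerates up to `max_mismatch` substitutions per mate (default 1,
matching the discard policy: more than one mismatch on either mate is
discarded). The decodability criterion is the classic minimum-distance
bound: a set with minimum pairwise Hamming distance $d$ decodes any
$\le t$-error corruption uniquely iff $d \ge 2t + 1$, so the default
validation requires $d \ge 3$. `validate_barcode_set()` checks the bound
and reports the violating pairs; homopolymer runs $\ge 4$ and GC outside
25–75% are warnings only (synthesis and sequencing robustness, not
decodability). The guarantee is not taken on faith: the tests enumerate
every single-substitution corruption of every barcode and require zero
misassignments, and the acceptance checks repeat this at the full set size.

Barcode sequences are always user-supplied (TSV `id<TAB>sequence`); a
seeded generator (`generate_barcodes()`, greedy rejection sampling) builds
sets at a requested distance floor for simulations. The hairpin builder
(`build_hairpin()`) substitutes a barcode into a configurable stem–loop
template with a cleavable-base placeholder and 3' T overhang. The template
default is deliberately schematic: commercial adapter architectures are
proprietary, and nothing downstream depends on the template beyond the
barcode slot.

## Demultiplexing policy

For each mate, the first $L$ bases are compared against every barcode;
the unique barcode at minimal Hamming distance $\le$ budget wins. Ties are
`ambiguous` (discarded — with a validated set a tie cannot arise from
$\le t$ errors), distances just over budget are `mismatch_exceeded`, and
reads far from every barcode (beyond budget + 2) are `no_match`; the
latter two are separated only for diagnostics. N in a read counts as a
mismatch by default.

Both mates are decoded independently and must agree
(`require_mate_agreement = TRUE` by default): each fragment is barcoded at
both ends with the same sample's barcode by construction, so disagreement
indicates a chimera or severe damage. Assignment by mate 1 alone is
available as a flag, since either behaviour is defensible for the original
data. Assigned pairs are trimmed by $L$ + `junction_bases` from the 5' end
of both mates — sequence and quality — keeping files synchronized. The
junction base is trimmed but not checked against a fixed letter: the base
is a T by chemistry, but checking it would couple decoding to a detail of
the library structure that varies between adapter designs.

Every pair is accounted for: totals always satisfy
assigned + discarded = input, unassigned pairs go to `undetermined`
FASTQ files rather than being dropped, and when a truth manifest is
available `contamination_matrix()` tabulates truth × assigned barcodes;
its off-diagonal mass over total assigned is the misassignment rate.

## Input-based normalization

Because every multiplexed sample has a matched input in the same pool,
per-sample scaling factors can be estimated from the inputs and applied to
the ChIPs, making signals quantitatively comparable across samples.

* `bin_counts()` tiles the genome at 10 kb (default) and attributes each
  fragment to the bin containing its midpoint. Midpoint attribution is the
  simplest unbiased rule; per-base coverage extension (as coverage tools
  do) would weight long fragments more, which is a deliberate,
  documented deviation. Fragments with blacklisted midpoints are dropped;
  bins fully inside blacklist regions are masked.
* `input_scaling_factors()` defaults to median-of-ratios: on bins non-zero
  in every sample, each sample's factor is the median of count /
  (geometric mean of the bin across samples), rescaled to geometric
  mean 1. This is the robust standard for count normalization; the test
  suite cross-checks it against an independent reference implementation of
  the same estimator. With fewer than 50 informative bins it falls back to
  total-count ratios with a warning. For technical-replicate inputs drawn
  from identical chromatin the factors should be 1; the acceptance
  computation measures the maximum deviation from unity across four
  simulated replicates (with read emission, 2% sequencing error and full
  demultiplexing in the loop) and a planted 2× depth difference must be
  recovered within 5%.
* `frip()` is the fraction of fragments overlapping any merged peak by
  $\ge 1$ bp, and `frip_rpkm()` divides FRiP by the fraction of the genome
  inside peaks and multiplies by $10^6$, so 1e6 is the no-enrichment
  baseline regardless of peak-set size.
* `normalize_chip()` emits per-bin
  $\log_2((c_i/f_i + p)/(n_i/f'_i + p))$ with pseudocount $p = 1$ by
  default; masked bins propagate as `NA`.

## The simulator and what it does (not) emulate

`simulate_relacs()` generates: an i.i.d. random genome at a configurable
GC (default 0.5); region classes assigned in 5 kb blocks (defaults: "open"
25% of the genome, "closed" 75%); digestion with the configured motif;
candidate fragments restricted to a 30–1000 bp window (a typical
short-insert cleanup range — no published fragment-size distribution is
reproduced, and the window is recorded in the manifest); fragment sampling
with probability proportional to class accessibility weight (default
open:closed = 4:1, times an enrichment multiplier when simulating a ChIP);
flat PCR-duplicate re-emission; barcode + junction + insert read
construction on both mates (75 bp, truncated at short fragments);
i.i.d. substitution errors (uniform over the three alternatives) at a
configurable rate, with barcode-region error counts recorded per mate; and
optional cross-sample chimeras to exercise mate disagreement. Every run is
reproducible from one integer seed recorded in the output, and the truth
manifest links every read pair to its sample, fragment coordinates and
planted errors.

The simulator deliberately does **not** model: indels or quality-dependent
errors (substitutions suffice to exercise a Hamming decoder; qualities are
a fixed placeholder), PCR bias beyond flat duplication, methylation
sensitivity, mappability, or the outer Illumina-index demultiplexing
layer. Consequently, green tests demonstrate correctness of the
algorithms under the stated generative model — not robustness to adapter
read-through, indel-rich platforms, or reference mapping artifacts.

## Problem sizes and numerical choices

The shipped tests run the oracle comparison on 200 random 10 kb sequences,
decode-guarantee enumeration at $L = 8$, $n = 32$, demultiplexing round
trips at 100,000 pairs over 8 barcodes, and scaling-factor recovery on a
5 Mb genome with 4 × 100,000 fragments at 10 kb bins; the acceptance
script uses 4 × 200,000 fragments with read emission and 2% error. These
sizes give sampling noise well below the tolerances being checked (the
median-of-ratios standard error at ~500 informative bins of ~400 counts is
about 0.4%). Whole-genome digestion of hs37d5/mm10 streams one chromosome
at a time through the same code path and needs only the FASTA files on
disk.

Degenerate inputs are handled explicitly rather than by accident:
chromosomes shorter than the motif yield zero sites; a site index with no
sites yields zero gaps (or one whole-chromosome gap when terminal segments
are included); zero-length region classes are omitted from density tables
with a warning; empty read streams produce zero-count statistics; and an
all-zero input sample is an error naming the sample, not a silent NaN.
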