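# relacs

Computational toolkit for **restriction-enzyme-based multiplexed
ChIP-seq**, where chromatin is fragmented inside intact nuclei by a
frequent degenerate blunt cutter (CviKI-1, RG|CY) and every fragment is
tagged at both ends with a sample-specific hairpin "nuclear" barcode
before samples are pooled into a single immunoprecipitation. The package
is for people building or analysing such assays who need the
computational layer without any wet-lab or alignment machinery:

* **In silico digestion** of genomes with degenerate IUPAC motifs:
  cut-site indexes, restriction fragments, gap ("blind region") reports,
  and site-density / site-usage bias tables against chromatin-state
  annotations (cutability vs accessibility).
* **Barcode design**: hairpin adapter construction, and validation of
  barcode sets against the minimum-distance decodability bound
  (min Hamming distance ≥ 2·t + 1 guarantees unique decoding of any
  ≤ t-substitution corruption).
* **Demultiplexing** of paired-end reads by inline barcode: both mates
  decoded independently under a per-mate mismatch budget (default 1),
  mate agreement required, barcode + junction trimmed, every pair
  accounted for, with a truth-aware contamination matrix.
* **Quantitative normalization**: 10 kb midpoint-binned counts,
  input-based median-of-ratios scaling factors (geometric mean 1), FRiP,
  and the FRiP → RPKM conversion `(FRiP / genome-fraction-in-peaks) × 1e6`.
* **A seeded simulator** of the whole experiment — genome, digestion,
  accessibility-weighted fragment sampling, barcoded error-injected read
  pairs, ground-truth manifest — so every stage is testable at desk scale.

Coordinates are 0-based half-open everywhere (BED convention).

## Worked example

```r
library(relacs)

# a small synthetic experiment: 8 barcoded samples, error-free reads
set <- generate_barcodes(8, length = 8, min_distance = 3, seed = 7)
cfg <- sim_config(seed = 11, chrom_length = 2e5, error_rate = 0)
sim <- simulate_relacs(cfg, set = set, n_pairs = 200)
sim
#> Synthetic multiplexed experiment: 1600 read pairs, 8 barcodes,
#> genome 200,000 bp with 3,169 restriction sites

res <- demux_pairs(sim$reads, set)
res$stats$assigned
#> [1] 1600                      # 100% of pairs assigned at zero error
attr(contamination_matrix(res, sim$manifest), "contamination_rate")
#> [1] 0                         # and none to the wrong barcode

gap_report(sim$sites, threshold = 1000)
#> Gap report (> 1000 bp): 0 gaps, 0 bp blind (0.000% of genome)

frip_rpkm(0.20, 0.04)          # FRiP 20% over 4% of the genome in peaks
#> [1] 5e+06                    # 5-fold over the 1e6 background baseline
```

The numbers above are what the calls print: at zero sequencing error a
validated barcode set assigns every pair to its true sample, and a random
200 kb genome has no RG|CY gap longer than 1 kb (sites occur every ~64 bp
on average at GC 0.5).

A thin command-line wrapper over the same functions is installed at
`inst/cli/relacs.R` (subcommands `digest`, `gaps`, `density`,
`barcodes validate|generate`, `demux`, `simulate`, `norm`, `frip`).

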