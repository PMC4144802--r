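# plastdiff

Fine-scale pairwise comparison of chloroplast (plastid) genomes, for
researchers quantifying intraspecific or closely interspecific plastome
divergence: how many SNPs and indels separate two conspecific plastomes,
where they fall across the quadripartite LSC/SSC/IR architecture and the
coding/intron/spacer compartments, what drives length variation in
hypervariable intergenic spacers, and what a calibrated molecular clock
makes of the divergence.

## What it computes

Given two annotated plastomes (FASTA + GenBank features) and an optional
outgroup:

* **Architecture** — de novo detection of the inverted repeats and the
  LSC/SSC partition; derived intergenic spacers named `<left>-<right>`.
* **Alignment** — exact affine-gap DP for regions, unique-k-mer anchored
  chaining for whole genomes, VCF-style left-normalization of gaps, and
  outgroup threading for polarization.
* **Variant catalog** — indels with carrier (which genome holds the extra
  bases), outgroup polarity (insertion/deletion/unknown) and context
  (homopolymer / tandem / other); SNPs with compartment, transition vs
  transversion, and synonymous vs nonsynonymous under the plastid genetic
  code (NCBI table 11). Summary cross-tabs, per-region density ratios
  normalized to the inverted repeat (counted once, length doubled), per-gene
  tables with the Kimura two-parameter distance

  K = −½ · ln[(1 − 2P − Q) · √(1 − 2Q)]

  where P and Q are the transition and transversion proportions.
* **Hypervariable spacer** — tandem-array detection by lagged
  self-comparison with consensus-based extension; hairpin folding of repeat
  units by terminal-inward pairing (A:T, G:C, G:T); A/B loop-form
  classification (`TTCTT` / `TTTAA`); per-position consensus profiles;
  dot-plot matrices.
* **Distances and dating** — pairwise-deletion p-distances
  (p = differences / comparable sites), group mean distances, fold
  differences, and calibration-ratio ages: t = T_cal / fold, with the
  half-width scaled identically.
* **Synthetic data** — a seeded generator for annotated plastome pairs
  (plus outgroup) with homopolymer-enriched spacers, a planted 19 bp
  hairpin-unit tandem array, Ts/Tv-biased substitutions, slippage and
  tandem indels — and a truth catalog for per-event recovery scoring.

## Worked example

Simulate a conspecific plastome pair with outgroup and run the full
pipeline:

```r
library(plastdiff)

report <- run_pipeline(config = simulation_config(seed = 3))
report
#> RunReport: lineageA vs lineageB (outgroup outgroup ) 
#> VariantSummary: 38 indels, 39 SNPs
#>   SNP divergence: 0.14 %
#>   Ts/Tv: whole=0.77 coding=1.4 IGS=0.53 intron=- rRNA=- tRNA=- 
#>   indel density (LSC:SSC:IR): 1.1 : 1 : 0 
#>   SNP density (LSC:SSC:IR): 3.3 : 2 : 1 
#>   truth recovery: 100.0% of 77 planted events
```

The two ~28 kb genomes differ by 39 SNPs (0.14% of sites) and 38 indels;
the density ratios say variation concentrates in the large single-copy
region, and every planted mutation was recovered with the correct carrier
and context. The hotspot spacer analysis finds the planted tandem array
and folds its consensus unit:

```r
arr <- report$repeats$per_genome$lineageA
arr$array
#> RepeatArray: unit 19 bp x 28 copies at [392,924), consensus TATGGATTTCTTGTCCATA, mean identity 0.921
arr$fold
#> HairpinFold: stem 7 bp (1 wobble), loop TTCTT
arr$form_counts
#>     A     B other 
#>    12    10     6
```

The consensus 19-mer folds into a 7 bp stem closing the loop `TTCTT`
(A form); 10 copies carry the alternative `TTTAA` loop (B form).

Calibration-ratio dating from published numbers — a reference split at
28.5 ± 5.5 million years (mya) that is 15× more diverged than the focal
pair — runs directly:

```r
scale_divergence(c(28.5, 5.5), fold = 15, basis = "rbcL")
#> DivergenceEstimate(rbcL): 1.9 ± 0.4 mya (calibration 28.5 ± 5.5 mya / fold 15)
```

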