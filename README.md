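# breakscape

Chromosomal translocations often break the same gene in the same place.
`breakscape` asks, for a single gene with a mapped set of rearrangement
breakpoints, two questions:

1. **Is the clustering real?** Do more breakpoints fall in a region
   (say, one intron) than its share of the gene's length explains?
2. **What co-locates with the hotspot?** Is the clustering associated
   with non-canonical DNA structure signals — G-quadruplex motifs,
   inverted repeats (palindromes/cruciforms) — or with the *fluctuation*
   of DNA secondary-structure folding free energy along the gene?

The package grew out of the analysis of the *TFE3* gene in
translocation renal cell carcinoma, whose per-region tables ship as
fixtures, but every stage is generic: any ordered exon/intron model,
breakpoint table, and (optionally) gene sequence can be analyzed.

## The statistics at its core

With regions *i* = 1..k of length *L<sub>i</sub>* and *N* observed
breakpoints *B<sub>i</sub>*:

* **Length-proportional null.** Expected counts
  *E<sub>i</sub> = N · L<sub>i</sub> / ΣL*, tested with a chi-square
  goodness of fit (df = k − 1), plus per-kb densities
  *1000 · B<sub>i</sub> / L<sub>i</sub>*.
* **Energy landscape.** A sliding 300-bp window (the approximate length
  of transiently exposed single-stranded DNA, e.g. an Okazaki fragment)
  advances 1 nt at a time; each window's minimum folding free energy ΔG
  (kcal/mol, 37 °C, 1 M Na⁺) is assigned to its start coordinate. The
  **stability fluctuation** is |dΔG|(i) = |ΔG(i+30) − ΔG(i)|; positions
  above Q3 + 3·IQR of the profile are called peaks.
* **Motif scanners.** A G4Hunter-style run-scoring window scan, a
  QGRS-style four-G-tract pattern finder (max length 30, min G-group 2,
  loops 0–36), and an inverted-repeat finder (total length 6–30, spacer
  0–10, ≤1 mismatch per arm pair), each validated against brute-force
  enumeration oracles in the test suite.
* **Permutation framework.** For a per-region feature *F<sub>i</sub>*
  (max |dΔG|, or a motif density), the statistic *T = Σ F<sub>i</sub> ·
  B<sub>i</sub>* is compared with 10,000 multinomial redistributions of
  the *N* breakpoints with region probabilities ∝ *L<sub>i</sub>*;
  the one-sided p-value is #(T_perm ≥ T_obs)/10,000.

A synthetic-data module generates genes with planted motifs, a planted
structured/unstructured junction (sharp ΔG transition), and breakpoints
from a hotspot/length-proportional mixture, so the whole pipeline is
testable offline.

## Worked example: the packaged per-region tables

```r
library(breakscape)

model <- tfe3_gene_model()                       # 19 exon/intron regions
B <- assign_breakpoints(tfe3_breakpoints(), model)
B[B > 0]
#> intron1   exon4 intron4   exon5 intron5
#>       2       1       4       1      23

scope <- tfe3_upstream_regions()                 # exon1 ... intron6
lens  <- setNames(model$regions$length, model$regions$name)[scope]
E <- expected_counts(c(lens[["intron5"]], sum(lens) - lens[["intron5"]]),
                     sum(B[scope]))
round(E, 2)
#> [1] 12.19 18.81
chisq_gof(c(B[["intron5"]], sum(B[scope]) - B[["intron5"]]), E)
#> chi-square GoF: X2(1, N = 31) = 15.80, p = 7.03e-05

permutation_test(tfe3_feature_table("max_abs_ddG"), n_perm = 10000, seed = 1)
#> permutation test: T_obs = 839.3, n_perm = 10000, one-sided p = 0.0000
permutation_test(tfe3_feature_table("g4_density"),  n_perm = 10000, seed = 2)
#> permutation test: T_obs = 196.7, n_perm = 10000, one-sided p = 0.9987
```

23 of 31 breakpoints sit in intron 5 against an expectation of 12.19
(χ² = 15.80, p < 0.001): the hotspot is not a length artifact.
Weighting each region's **max |dΔG|** by its breakpoint count puts the
observed statistic in the extreme upper tail of the length-proportional
null (p ≈ 0.0002 at 10,000 permutations; a seed where no permutation
reaches T_obs prints 0.0000), while the G-quadruplex density feature is
*anti*-associated (p ≈ 0.999) — breakpoints track the energy-landscape
fluctuation, not raw motif counts.

## Worked example: a synthetic gene

```r
cfg <- synth_config(region_lengths = c(exon1 = 100, intron1 = 500),
                    hotspot_region = "intron1", cushion_len = 60,
                    at_len = 60, seed = 1)
gen <- generate_gene(cfg)
ep  <- energy_profile(gen$sequence, window_len = 60, step = 2)
fp  <- fluctuation_profile(ep, interval = 15)     # 15 x 2 bp = 30 bp
pk  <- iqr_peaks(fp, gen$model)
pk
#> PeakSet: 28 peak position(s) above Q3 + 3*IQR = 12.74
#> merged intervals:
#>  start end
#>    276 302
#>    310 340
gen$truth$junction
#> [1] 318
colocalize(pk, "intron1", gen$model, flank = 500)$colocalized
#> [1] TRUE
```

The called peak interval straddles the planted structured/unstructured
junction at 318.

## Command line

An executable (`inst/scripts/breakscape`) exposes `synth` and `report`
subcommands; `report` runs every stage whose inputs are present and
writes TSV/JSON/BED outputs plus the resolved configuration:

```sh
breakscape synth  --out bundle --seed 7
breakscape report --regions bundle/regions.tsv \
    --breakpoints bundle/breakpoints.tsv --fasta bundle/gene.fasta \
    --out report --seed 7 --window 300 --interval 30 --n-perm 10000
```

## Documentation

The methods vignette (`vignettes/stability-fluctuation.Rmd`) describes
the model and its assumptions, every tunable parameter with its default
and rationale, what the synthetic generator does and does not emulate,
and the numerical conventions (quantile type, tie handling, boundary
rules).
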