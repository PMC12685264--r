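---
title: "Breakpoint hotspots and DNA stability fluctuation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakpoint hotspots and DNA stability fluctuation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakscape)
```

# The problem and the model

Recurrent chromosomal translocations break a gene at reproducible
positions. Given an ordered exon/intron model of the gene, a table of
per-sample breakpoints, and optionally the gene's sequence, the package
addresses two linked questions.

**Is the clustering more than a length effect?** Under the null that a
breakpoint lands in region $i$ with probability $L_i/\sum L$, the
expected count is $E_i = N L_i/\sum L$. The primary comparison is the
most breakpoint-rich region against the pooled remainder (a 2-category
chi-square goodness of fit, df 1), complemented by per-kb densities
$1000\,B_i/L_i$. The 2-category design follows the biology: fusions
must preserve the downstream functional domains, so only the upstream
regions are plausible breakage targets and the analysis scope defaults
to those regions when the fixture tables are used (`region_scope` in
`run_config()`; all regions otherwise).

**What does the hotspot co-locate with?** For a per-region feature
$F_i$ the association statistic is the breakpoint-weighted sum
$T=\sum_i F_i B_i$. Its null distribution is generated by redistributing
the $N$ breakpoints as a multinomial draw with probabilities
$L_i/\sum L$ — an explicit modelling choice: the "permutation" is an
independent reassignment, not a label shuffle, because the stated null
is a length-proportional point process, not exchangeability of observed
positions. The one-sided p-value is
$\#\{T_{perm} \ge T_{obs}\}/n_{perm}$; ties count toward the numerator
to follow the plain empirical estimator, and an optional
$(r+1)/(n+1)$ add-one variant is available (`plus_one = TRUE`) but off
by default. Three features are wired in: per-region maximum |dΔG|,
G-quadruplex motif density, and palindrome motif density.

# The energy landscape

Transiently single-stranded DNA — e.g. the lagging-strand template —
can fold back on itself. The landscape stage slides a window of
`window_len` (default **300 bp**, an Okazaki-fragment-scale exposure;
step default **1 nt**) along the sense strand, computes each window's
minimum folding free energy ΔG (kcal/mol), and anchors the value at the
window's *start* coordinate. The last window ends at the gene's end; no
flanking context is invented.

The object of interest is not stability itself but its local change:
$$|d\Delta G|(i) = |\Delta G(i+\texttt{interval}) - \Delta G(i)|,$$
with `interval` defaulting to **30 profile steps** (30 bp at step 1).
Sharp structured/unstructured transitions — the proposed fragility
marker — produce high values; uniformly stable or uniformly
unstructured sequence produces none. Peaks are extreme outliers of the
profile: values strictly above $Q3 + 3\times IQR$ ("exceeded the
threshold" is read as strict inequality; at the boundary nothing is
called). Quartiles use linear interpolation between order statistics
(`stats::quantile` type 7), the most common convention; the threshold
is computed per profile, i.e. per gene, so multi-gene screens get
gene-specific thresholds. Each profile value is assigned to the region
containing its start coordinate — mirroring the window-start anchoring
— and the per-region maximum |dΔG| becomes the $F_i$ feature. A region
in which no window starts (past $L-\texttt{window\_len}$) reports 0.

Co-localization of peaks with a hotspot uses a flank of **500 bp**: a
region hotspot associates with any peak in
$[\text{start}-\text{flank},\ \text{end}+\text{flank})$, while a point
hotspot uses a window of *total* width `flank` centered on the point
(±250 bp at the default), matching the "window centered on the
hotspot" convention for single-coordinate hotspots.

## The built-in folding backend

Published analyses of this kind use mfold/RNAfold. Reproducing either
bit-exactly is explicitly out of scope: the |dΔG| statistic needs
*relative* window-to-window stability, and any deterministic
nearest-neighbor model preserves the landscape's transitions. The
shipped backend (`builtin_fold()`, Rcpp) is a dynamic program over
non-crossing Watson-Crick pairs (G·T wobble optional, off by default)
with:

* unified DNA nearest-neighbor stacking free energies at 37 °C, 1 M
  Na⁺, 0 M Mg²⁺ (`dna_nn_params()`; the parameter set is fixed and
  other conditions are an error rather than silently extrapolated);
* hairpin loops ≥ 3 nt, bulge and internal loops up to 30 nt with
  tabulated penalties, linear interpolation between anchors, and
  Jacobson-Stockmayer $1.75\,RT\ln(n/30)$ extrapolation beyond;
* an internal-loop asymmetry penalty (0.3/nt, capped at 3.0);
* **no multibranch loops**: nested stems and simple loops only. This
  keeps the recursion at $O(L^2 \cdot 30^2)$ per window — desk scale
  for 300-nt windows — and biases all windows equally, which is what a
  *difference* statistic requires. Terminal AT penalties and dangling
  ends are likewise omitted, for the same reason.

Every folding test in the suite scores structures by hand from the
same shipped table, so the tested contract is internal consistency of
the model, not agreement with an external folder. For users who want
an external folder, `command_backend()` adapts any program that reads
a sequence on stdin and prints a ΔG, and `energy_profile_from_tsv()`
ingests precomputed per-window values (the `--backend precomputed`
CLI route).

# Motif scanners

All scanners run on the sense strand by default (`both_strands` for
the G4 pattern finder); published per-region counts are treated as
sense-strand counts since strandedness is rarely stated.

**G4Hunter-style window scan.** Per-base scores: a G in a run of $k$
Gs scores $+\min(k,4)$, a C in a run of $k$ Cs scores $-\min(k,4)$,
A/T/N score 0. Window means (default window 25, the published tool's
default) with $|mean| \ge 1.2$ qualify; consecutive qualifying windows
of the same sign merge into one maximal hit carrying the most extreme
mean. The sign doubles as strand evidence, and the scan is exactly
antisymmetric under reverse complement (a tested invariant).

**QGRS-style pattern finder.** Motifs
$G^g N^{l_1} G^g N^{l_2} G^g N^{l_3} G^g$ with equal tract size
$g \ge 2$, loops in $[0, 36]$, span ≤ 30. The published G-score
constant is not available, so the score is a documented analogue —
$40(g-2) - (\max l - \min l) - \bar l$ — that preserves the tool's
ordering principles (more tetrads beat fewer; short, even loops beat
long, uneven ones). Overlaps resolve greedily: highest score first,
leftmost start then shortest motif on ties, giving a deterministic
non-overlapping set.

**Inverted repeats.** Arm-spacer-arm with the second arm the reverse
complement of the first, ≤ 1 mismatching pair per arm pair (indels not
modelled), spacer 0–10. The published "min length 6 / max length 30"
is interpreted as the *total* motif length with arm ≥ 3 — tools differ
here and the convention is configurable (`arm_min`, `min_total`,
`max_total`). Redundancy rules: one hit per interval (fewest
mismatches, then longest arm) and no hit strictly contained in another
valid hit.

On every sequence ≤ 200 bp in the test fixtures, both pattern finders
agree exactly with exhaustive brute-force enumeration oracles that are
kept in the suite.

# The synthetic world

`synth_config()` defaults state the emulated study: twelve regions
with the annotated upstream lengths (total 9,586 bp), 31 breakpoints,
hotspot in intron 5, and hotspot mixture weight $\rho = 0.6$ — chosen
once because $\rho + (1-\rho)L_{hot}/\sum L \approx 0.75$ reproduces
the observed ~74% hotspot share; it was not revisited afterwards.
Background sequence is i.i.d. at GC 0.5 (the studied gene is ~50% GC);
i.i.d. rather than Markov keeps analytic expectations available for
calibration tests.

The planted "sharp ΔG transition" is a three-part block inside the
hotspot: a GC-rich cushion (default 300 bp, one window), a perfect
hairpin (default 30 bp arms, 4 nt loop), and an AT-rich unstructured
block (default 300 bp). `truth$junction` records the hairpin stem
start. The cushion is a deliberate asymmetry: window-start anchoring
produces |dΔG| ramps at *both* edges of any planted structure, and
with neutral flanks the two ramps tie, leaving the global argmax
ambiguous by ~±(window − block) bp. A moderately structured upstream
cushion suppresses the upstream ramp, so the steepest transition —
and, in ≥95% of seeds, the global argmax — sits within 30 bp of the
recorded junction. Planted G4s use the canonical
$G_3N_2G_3N_2G_3N_2G_3$ form so that both G4 scanners must detect
them; planted palindromes are perfect 6-bp-arm inverted repeats.
Planting avoids the structured block and other planted motifs; a
density that cannot be placed is an error, not a silent truncation.

What the generator does **not** emulate: sequencing noise, fusion
transcripts and splicing, mappability, replication timing, R-loops, or
any correlation between motifs and breakpoints beyond the hotspot
mixture. A green end-to-end test therefore establishes that the
pipeline recovers planted enrichment and planted energy transitions
under its own stated null — not that the biological mechanism is true.

# Numerical choices and conventions

* Coordinates: 0-based half-open transcript coordinates internally;
  1-based inclusive genomic coordinates at I/O, converted on load. A
  breakpoint on the first base of a region belongs to that region.
  Minus-strand genes are reverse-complemented on FASTA load so region
  ordinals run 5'→3'.
* Ambiguous bases: N is excluded from GC/AT denominators and counted
  separately; scanners treat N as unmatchable; the folding backend
  rejects non-ACGT input outright.
* Region names: the `introN` spelling found in published tables is
  normalized to `intronN` everywhere.
* RNG: every stochastic routine takes an explicit seed, draws in a
  fixed order, and restores the caller's RNG state; the three
  permutation tests in a report use independent streams
  (`seed + 1, 2, 3`). p-values are reported at full precision plus the
  4-decimal rounding used in print-outs.
* Degenerate inputs: a single-region permutation table warns and
  returns p = 1; an all-zero breakpoint table is an error; a constant
  fluctuation profile yields IQR 0 and no peaks (strict inequality).

# Test scaling

Three heavy invariants run scaled down purely for runtime, with the
statistic definitions and the stated thresholds unchanged: the
profile/no-caching check uses 10 random 150-bp sequences at window 60
(instead of 50 × 400 bp at window 300); the 50-seed end-to-end
recovery uses quarter-length regions, window 100, step 10 and 1,000
permutations; the 100-seed junction-recovery Monte Carlo uses a
compact 600-bp gene at window 60, step 2. The fluctuation `interval`
is counted in profile steps, so 30 bp is preserved under coarser
steps (e.g. 3 steps × 10 bp).

# Known limitations

* The folding model is intentionally reduced (no multiloops, no
  terminal corrections, no pseudoknots or ensemble energies); absolute
  ΔG values are not comparable to mfold/RNAfold outputs, only the
  landscape shape is.
* Published per-region max |dΔG| values depend on the original
  folder and genome sequence and are therefore consumed as data
  (fixtures), not recomputed.
* The permutation framework tests co-localization, not causation, and
  applies no multiple-testing correction across the three features
  (matching the source analysis).
* Junction recovery is specified for stems ≤ 30 bp; much longer stems
  widen the |dΔG| plateau and the argmax may sit anywhere on it.
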