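Package: breakscape
Title: Breakpoint Hotspot Enrichment and DNA Secondary-Structure
    Stability Fluctuation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether chromosomal rearrangement
    breakpoints cluster in regions of a gene beyond what region length
    alone explains, and whether hotspots co-localize with non-canonical
    DNA structure signals. Implements region-level chi-square
    goodness-of-fit enrichment with per-kilobase densities, G-quadruplex
    and inverted-repeat (palindrome/cruciform) motif scanners, a
    sliding-window DNA folding free-energy landscape with a local
    stability-fluctuation statistic (|dDeltaG|) and interquartile-range
    outlier peak calling, and a length-weighted permutation test of
    breakpoint/feature co-localization. A synthetic gene generator with
    planted motifs, a planted structured/unstructured junction, and
    mixture-sampled breakpoints supports fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
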