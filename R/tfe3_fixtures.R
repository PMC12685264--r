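#' @title Packaged TFE3 fixtures
#' @description The published per-region tables for the human TFE3 gene
#'   (GRCh37 annotation of transcript NM_006521.6) ship with the
#'   package as plain TSV files: the 19-region exon/intron structure
#'   with lengths, the printed per-region base counts and AT/GC
#'   fractions, the 31-sample breakpoint table, and the per-region
#'   feature summary (max |dDeltaG|, G-quadruplex and palindrome counts
#'   and densities). They make the headline statistics recomputable
#'   without any sequence download. Region names are canonicalized from
#'   the printed "introN" spelling to "intronN".
#' @name tfe3_fixtures
NULL

tfe3_file <- function(name) {
  system.file("extdata", name, package = "breakscape", mustWork = TRUE)
}

#' @rdname tfe3_fixtures
#' @return `tfe3_gene_model()`: the 19-region [gene_model()] (lengths
#'   only; the locus sits on the minus strand of chrX but the fixture
#'   carries no genomic coordinates).
#' @export
tfe3_gene_model <- function() {
  load_gene_model(tfe3_file("tfe3_regions.tsv"), gene_name = "TFE3",
                  assembly = "GRCh37", strand = "-")
}

#' @rdname tfe3_fixtures
#' @return `tfe3_breakpoints()`: the 31-record `BreakpointSet` with the
#'   published per-region assignments (region resolution; the DNA-seq
#'   coordinates are kept as annotation).
#' @export
tfe3_breakpoints <- function() {
  load_breakpoints(tfe3_file("tfe3_breakpoints.tsv"))
}

#' @rdname tfe3_fixtures
#' @return `tfe3_composition_table()`: data.frame of printed per-region
#'   A/C/G/T counts and AT/GC fractions.
#' @export
tfe3_composition_table <- function() {
  tb <- read.delim(tfe3_file("tfe3_composition.tsv"),
                   stringsAsFactors = FALSE)
  tb$name <- normalize_region_name(tb$name)
  tb
}

#' @rdname tfe3_fixtures
#' @param feature feature column: `"max_abs_ddG"`, `"g4_density"` or
#'   `"palindrome_density"`.
#' @param regions region subset; defaults to the analysis scope
#'   upstream of exon 7 (all fusions retain exons 7-10).
#' @return `tfe3_feature_table()`: a [region_feature_table()] over the
#'   requested regions.
#' @export
tfe3_feature_table <- function(feature = c("max_abs_ddG", "g4_density",
                                           "palindrome_density"),
                               regions = tfe3_upstream_regions()) {
  feature <- match.arg(feature)
  load_feature_table(tfe3_file("tfe3_features.tsv"), feature,
                     regions = regions)
}

#' @rdname tfe3_fixtures
#' @return `tfe3_upstream_regions()`: the 12 region names upstream of
#'   exon 7 (`exon1` ... `intron6`), the default analysis scope.
#' @export
tfe3_upstream_regions <- function() {
  c("exon1", "intron1", "exon2", "intron2", "exon3", "intron3",
    "exon4", "intron4", "exon5", "intron5", "exon6", "intron6")
}
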