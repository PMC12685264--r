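#' @title Gene models, breakpoints and base composition
#' @description Domain types and I/O for an ordered exon/intron gene
#'   structure, breakpoint tables, and per-region base composition.
#' @name gene_model
NULL

# canonicalize region names; some published tables abbreviate "intronN"
# as "introN"
normalize_region_name <- function(x) {
  sub("^intro([0-9]+)$", "intron\\1", trimws(as.character(x)))
}

#' Construct a validated gene model
#'
#' A gene model is an ordered table of exon/intron regions in transcript
#' (5'->3') order. Regions must be contiguous and non-overlapping, kinds
#' must alternate exon/intron starting with an exon, and every region
#' must be at least 1 bp long. Internally the model carries 0-based
#' half-open transcript offsets; genomic coordinates, when present, are
#' 1-based inclusive as printed in annotation tables.
#'
#' @param regions data.frame with columns `name`, `kind` (`exon` or
#'   `intron`), and `length` (bp); optionally `ordinal`, `genomic_start`,
#'   `genomic_end` (1-based inclusive).
#' @param gene_name gene symbol used in output tracks.
#' @param assembly free-text assembly label (e.g. `"GRCh37"`).
#' @param strand `"+"` or `"-"`; on `"-"`, genomic coordinates run
#'   antiparallel to transcript order.
#' @return object of class `GeneModel`.
#' @export
gene_model <- function(regions, gene_name = "gene", assembly = NA_character_,
                       strand = c("+", "-")) {
  strand <- match.arg(strand)
  stopifnot(is.data.frame(regions))
  need <- c("name", "kind")
  miss <- setdiff(need, names(regions))
  if (length(miss))
    stop("region table lacks column(s): ", paste(miss, collapse = ", "))
  rg <- as.data.frame(regions, stringsAsFactors = FALSE)
  rg$name <- normalize_region_name(rg$name)
  rg$kind <- tolower(trimws(as.character(rg$kind)))

  if (!"length" %in% names(rg)) {
    if (!all(c("genomic_start", "genomic_end") %in% names(rg)))
      stop("region table needs a `length` column or genomic coordinates")
    rg$length <- abs(rg$genomic_end - rg$genomic_start) + 1L
  }
  rg$length <- as.integer(rg$length)

  for (i in seq_len(nrow(rg))) {
    if (is.na(rg$name[i]) || !nzchar(rg$name[i]) ||
        is.na(rg$kind[i]) || is.na(rg$length[i]))
      stop("malformed region row at line ", i)
  }
  bad <- which(!rg$kind %in% c("exon", "intron"))
  if (length(bad))
    stop("region kind must be exon/intron; offending row ", bad[1])
  if (any(rg$length < 1L))
    stop("every region length must be >= 1")
  if (anyDuplicated(rg$name))
    stop("duplicate region name(s): ",
         paste(unique(rg$name[duplicated(rg$name)]), collapse = ", "))
  if (rg$kind[1] != "exon")
    stop("region kinds must alternate exon/intron starting with an exon")
  if (nrow(rg) > 1 && any(rg$kind[-1] == rg$kind[-nrow(rg)]))
    stop("region kinds must alternate exon/intron starting with an exon")

  if (!"ordinal" %in% names(rg) || all(is.na(rg$ordinal))) {
    ord <- integer(nrow(rg))
    cnt <- c(exon = 0L, intron = 0L)
    for (i in seq_len(nrow(rg))) {
      cnt[rg$kind[i]] <- cnt[rg$kind[i]] + 1L
      ord[i] <- cnt[[rg$kind[i]]]
    }
    rg$ordinal <- ord
  }
  rg$ordinal <- as.integer(rg$ordinal)
  if (any(rg$ordinal < 1L)) stop("ordinals must be positive")

  has_coord <- all(c("genomic_start", "genomic_end") %in% names(rg)) &&
    !anyNA(rg$genomic_start) && !anyNA(rg$genomic_end)
  if (has_coord) {
    rg$genomic_start <- as.integer(rg$genomic_start)
    rg$genomic_end <- as.integer(rg$genomic_end)
    if (any(rg$genomic_end - rg$genomic_start + 1L != rg$length))
      stop("genomic_end - genomic_start + 1 must equal length for every region")
    if (nrow(rg) > 1) {
      ok <- if (strand == "+")
        all(rg$genomic_start[-1] == rg$genomic_end[-nrow(rg)] + 1L)
      else
        all(rg$genomic_end[-1] == rg$genomic_start[-nrow(rg)] - 1L)
      if (!ok) stop("regions are not contiguous/non-overlapping in ",
                    "transcript order on strand ", strand)
    }
  } else {
    rg$genomic_start <- rep(NA_integer_, nrow(rg))
    rg$genomic_end <- rep(NA_integer_, nrow(rg))
  }

  rg$transcript_start <- cumsum(c(0L, rg$length[-nrow(rg)]))
  rg$transcript_end <- rg$transcript_start + rg$length
  rg <- rg[, c("name", "kind", "ordinal", "length",
               "genomic_start", "genomic_end",
               "transcript_start", "transcript_end")]
  structure(list(gene_name = gene_name, assembly = assembly,
                 strand = strand, regions = rg),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s, strand %s): %d regions, %d bp\n",
              x$gene_name,
              ifelse(is.na(x$assembly), "unplaced", x$assembly),
              x$strand, nrow(x$regions), total_length(x)))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Total transcript length of a gene model (optionally a region subset)
#' @param model a `GeneModel`.
#' @param regions optional character vector of region names.
#' @export
total_length <- function(model, regions = NULL) {
  rg <- model$regions
  if (!is.null(regions)) {
    regions <- normalize_region_name(regions)
    miss <- setdiff(regions, rg$name)
    if (length(miss)) stop("unknown region(s): ", paste(miss, collapse = ", "))
    rg <- rg[rg$name %in% regions, ]
  }
  sum(rg$length)
}

#' Read a gene model from a tab-delimited region table
#'
#' Expects a header with at least `name` and `kind` plus either `length`
#' or `genomic_start`/`genomic_end` (1-based inclusive); rows in
#' transcript order. `introN` names are normalized to `intronN`.
#'
#' @param path TSV file path.
#' @inheritParams gene_model
#' @return a `GeneModel`.
#' @export
load_gene_model <- function(path, gene_name = sub("\\.[^.]*$", "", basename(path)),
                            assembly = NA_character_, strand = "+") {
  tb <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "")),
    error = function(e) stop("cannot parse region table ", path, ": ",
                             conditionMessage(e)))
  gene_model(tb, gene_name = gene_name, assembly = assembly, strand = strand)
}

#' Serialize a gene model back to the region-table TSV format
#' @param model a `GeneModel`.
#' @param path output file.
#' @export
write_gene_model <- function(model, path) {
  rg <- model$regions[, c("name", "kind", "ordinal", "length",
                          "genomic_start", "genomic_end")]
  if (all(is.na(rg$genomic_start)))
    rg <- rg[, c("name", "kind", "ordinal", "length")]
  write.table(rg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the gene sequence from a single-record FASTA
#'
#' When the FASTA carries the reference plus strand but the gene is on
#' the minus strand, pass `strand = "-"` to obtain the transcribed
#' (sense) sequence: the record is reverse-complemented so that region
#' ordinals run 5'->3' in transcript order.
#'
#' @param path FASTA file with exactly one record (the gene locus).
#' @param strand strand of the gene on the reference.
#' @return upper-case character string over A/C/G/T/N.
#' @export
load_gene_sequence <- function(path, strand = c("+", "-")) {
  strand <- match.arg(strand)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1)
    stop("expected a single FASTA record in ", path, ", found ", length(ss))
  if (strand == "-") ss <- Biostrings::reverseComplement(ss)
  toupper(as.character(ss[[1]]))
}

#' Base composition of a nucleotide sequence
#'
#' Exact A/C/G/T counts with GC and AT fractions. Ambiguous bases (N)
#' are counted separately and excluded from the fraction denominators,
#' so `gc_fraction + at_fraction == 1` whenever no N is present.
#'
#' @param sequence non-empty string over A/C/G/T/N (case-insensitive).
#' @return a `CompositionSummary` (one-row data.frame with counts,
#'   `gc_fraction`, `at_fraction`, `n_ambiguous`).
#' @export
composition <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  s <- toupper(sequence)
  cnt <- counts_acgtn(s)
  bad <- nchar(s) - sum(cnt)
  if (bad > 0) {
    chars <- unique(strsplit(s, "", fixed = TRUE)[[1]])
    stop("sequence alphabet must be ACGTN; offending symbol(s): ",
         paste(setdiff(chars, c("A", "C", "G", "T", "N")), collapse = ", "))
  }
  denom <- sum(cnt[c("A", "C", "G", "T")])
  if (denom == 0) stop("sequence contains no unambiguous bases")
  out <- data.frame(n_A = cnt[["A"]], n_C = cnt[["C"]], n_G = cnt[["G"]],
                    n_T = cnt[["T"]], n_ambiguous = cnt[["N"]],
                    gc_fraction = (cnt[["G"]] + cnt[["C"]]) / denom,
                    at_fraction = (cnt[["A"]] + cnt[["T"]]) / denom)
  class(out) <- c("CompositionSummary", class(out))
  out
}

counts_acgtn <- function(s) {
  v <- Biostrings::letterFrequency(Biostrings::BString(s),
                                   letters = c("A", "C", "G", "T", "N"))
  setNames(as.integer(v), c("A", "C", "G", "T", "N"))
}

#' Extract per-region sequences from the gene sequence
#' @param sequence gene sequence (transcript orientation).
#' @param model matching `GeneModel`; `nchar(sequence)` must equal the
#'   model's total length.
#' @return named character vector, one entry per region.
#' @export
region_sequences <- function(sequence, model) {
  if (nchar(sequence) != total_length(model))
    stop("sequence length (", nchar(sequence), ") does not match model (",
         total_length(model), ")")
  rg <- model$regions
  setNames(substring(sequence, rg$transcript_start + 1L, rg$transcript_end),
           rg$name)
}

#' Per-region base composition table
#' @inheritParams region_sequences
#' @return data.frame, one row per region, Table-3-style.
#' @export
composition_by_region <- function(sequence, model) {
  seqs <- region_sequences(sequence, model)
  out <- do.call(rbind, lapply(seqs, composition))
  cbind(data.frame(name = model$regions$name,
                   kind = model$regions$kind,
                   length = model$regions$length), out, row.names = NULL)
}

#' Construct a breakpoint set
#'
#' Each record needs a `region_name` or a `genomic_coord` (or both);
#' `resolution` says which is authoritative (`"base"`: the coordinate;
#' `"region"`: the name).
#'
#' @param records data.frame with columns `sample_id` and at least one of
#'   `region_name`, `genomic_coord`; optional `resolution`
#'   (`base`/`region`) and `source` (`dna_seq`/`rna_seq`).
#' @return object of class `BreakpointSet` (validated data.frame).
#' @export
breakpoint_set <- function(records) {
  stopifnot(is.data.frame(records))
  rc <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(rc)) stop("records need a sample_id column")
  if (!"region_name" %in% names(rc))
    rc$region_name <- rep(NA_character_, nrow(rc))
  if (!"genomic_coord" %in% names(rc))
    rc$genomic_coord <- rep(NA_integer_, nrow(rc))
  rc$region_name <- normalize_region_name(rc$region_name)
  blank <- !is.na(rc$region_name) &
    (!nzchar(rc$region_name) | rc$region_name == "NA")
  rc$region_name[blank] <- NA
  rc$genomic_coord <- as.integer(rc$genomic_coord)
  if (!"resolution" %in% names(rc))
    rc$resolution <- ifelse(is.na(rc$region_name), "base", "region")
  if (!"source" %in% names(rc))
    rc$source <- rep(NA_character_, nrow(rc))
  bad <- is.na(rc$region_name) & is.na(rc$genomic_coord)
  if (any(bad))
    stop("record(s) without region_name or genomic_coord: sample ",
         paste(rc$sample_id[bad], collapse = ", "))
  if (!all(rc$resolution %in% c("base", "region")))
    stop("resolution must be 'base' or 'region'")
  rc <- rc[, c("sample_id", "region_name", "genomic_coord",
               "resolution", "source")]
  class(rc) <- c("BreakpointSet", "data.frame")
  rc
}

#' Read a breakpoint table
#' @param path TSV with header
#'   `sample_id region_name genomic_coord resolution source`.
#' @return a `BreakpointSet`.
#' @export
load_breakpoints <- function(path) {
  tb <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  breakpoint_set(tb)
}

#' @rdname load_breakpoints
#' @param bps a `BreakpointSet`.
#' @export
write_breakpoints <- function(bps, path) {
  write.table(as.data.frame(bps), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# map a 1-based inclusive genomic coordinate to a 0-based transcript offset
genomic_to_transcript <- function(coord, model) {
  rg <- model$regions
  if (all(is.na(rg$genomic_start)))
    stop("gene model carries no genomic coordinates")
  lo <- pmin(rg$genomic_start, rg$genomic_end)
  hi <- pmax(rg$genomic_start, rg$genomic_end)
  hit <- which(coord >= lo & coord <= hi)
  if (!length(hit)) return(NA_integer_)
  i <- hit[1]
  off <- if (model$strand == "+") coord - rg$genomic_start[i]
         else rg$genomic_end[i] - coord
  rg$transcript_start[i] + off
}

# region containing a 0-based transcript offset (half-open containment:
# a breakpoint on the first base of a region belongs to that region)
region_of_offset <- function(offset, model) {
  rg <- model$regions
  i <- findInterval(offset, rg$transcript_start)
  if (i < 1 || offset >= rg$transcript_end[i]) return(NA_character_)
  rg$name[i]
}

#' Count breakpoints per region
#'
#' Records with base resolution are mapped through their genomic
#' coordinate (the model must carry genomic coordinates); region
#' resolution records are mapped by name. A coordinate falling on the
#' first base of a region belongs to that region (half-open containment
#' in transcript space). When a record carries both a name and a
#' coordinate and the model has coordinates, the two must agree.
#'
#' @param bps a `BreakpointSet`.
#' @param model a `GeneModel`.
#' @return named integer vector `B` over the model's regions;
#'   `sum(B)` equals `nrow(bps)`.
#' @export
assign_breakpoints <- function(bps, model) {
  stopifnot(inherits(bps, "BreakpointSet"), inherits(model, "GeneModel"))
  rg <- model$regions
  B <- setNames(integer(nrow(rg)), rg$name)
  has_coords <- !all(is.na(rg$genomic_start))
  for (i in seq_len(nrow(bps))) {
    nm <- bps$region_name[i]
    cd <- bps$genomic_coord[i]
    by_coord <- bps$resolution[i] == "base" || is.na(nm)
    if (by_coord) {
      t <- genomic_to_transcript(cd, model)
      if (is.na(t))
        stop("breakpoint coordinate ", cd, " of sample ", bps$sample_id[i],
             " lies outside the gene span")
      reg <- region_of_offset(t, model)
    } else {
      if (!nm %in% rg$name)
        stop("breakpoint region '", nm, "' of sample ", bps$sample_id[i],
             " is not in the gene model")
      reg <- nm
      if (!is.na(cd) && has_coords) {
        t <- genomic_to_transcript(cd, model)
        if (is.na(t) || region_of_offset(t, model) != nm)
          stop("sample ", bps$sample_id[i], ": genomic_coord ", cd,
               " is inconsistent with region_name ", nm)
      }
    }
    B[reg] <- B[reg] + 1L
  }
  B
}
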