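#' @title Synthetic genes, sequences and breakpoints
#' @description Generators emulating the statistical structure the
#'   analysis assumes: a gene with configurable exon/intron lengths,
#'   i.i.d. background sequence at a target GC, a planted
#'   structured/unstructured junction producing a sharp DeltaG
#'   transition inside the hotspot, planted G-quadruplex and palindrome
#'   motifs at set densities, and breakpoints drawn from a mixture of a
#'   hotspot-enriched and a length-proportional component. Everything is
#'   deterministic per seed, so the whole pipeline is testable without
#'   downloads.
#' @name synthetic_data
NULL

#' Configuration for the synthetic gene generator
#'
#' Defaults state the emulated world: the 12 upstream regions of the
#' studied gene (lengths as annotated), 31 breakpoints, a hotspot in
#' intron 5, and a hotspot mixture weight of 0.6 (roughly the observed
#' 74\% hotspot share once the length-proportional component is added).
#'
#' @param region_lengths named vector of region lengths in bp (names
#'   `exon1`, `intron1`, ...; all >= 50).
#' @param hotspot_region name of the hotspot region.
#' @param hotspot_enrichment mixture weight `rho` in \[0, 1\]: each
#'   breakpoint is drawn uniformly inside the hotspot with probability
#'   `rho`, else length-proportionally over all regions.
#' @param n_breakpoints number of breakpoints `N` (default 31).
#' @param stem_len hairpin stem (arm) length of the planted structured
#'   block; 0 plants nothing (flat-profile control).
#' @param loop_len hairpin loop length (default 4).
#' @param cushion_len GC-rich moderately structured segment placed
#'   immediately upstream of the hairpin (default 300, one analysis
#'   window) so that the upstream DeltaG ramp is shallow and the
#'   steepest stability transition sits at the hairpin stem start.
#' @param at_len AT-rich unstructured segment placed immediately
#'   downstream of the hairpin (default 300).
#' @param junction 0-based coordinate of the hairpin stem start; default
#'   centers the planted layout inside the hotspot.
#' @param g4_density,palindrome_density planted motifs per kb per region
#'   (defaults 1 and 1).
#' @param base_gc background GC fraction (default 0.5).
#' @param seed default seed used by the generator functions.
#' @return `SynthConfig` list.
#' @export
synth_config <- function(region_lengths = c(
                           exon1 = 246, intron1 = 2542, exon2 = 113,
                           intron2 = 1047, exon3 = 303, intron3 = 665,
                           exon4 = 245, intron4 = 83, exon5 = 104,
                           intron5 = 3769, exon6 = 117, intron6 = 352),
                         hotspot_region = "intron5",
                         hotspot_enrichment = 0.6,
                         n_breakpoints = 31,
                         stem_len = 30, loop_len = 4,
                         cushion_len = 300, at_len = 300,
                         junction = NULL,
                         g4_density = 1, palindrome_density = 1,
                         base_gc = 0.5, seed = NULL) {
  stopifnot(all(region_lengths >= 50),
            hotspot_enrichment >= 0, hotspot_enrichment <= 1,
            n_breakpoints >= 0, stem_len >= 0, loop_len >= 3,
            g4_density >= 0, palindrome_density >= 0,
            base_gc > 0, base_gc < 1)
  if (is.null(names(region_lengths)))
    stop("region_lengths must be named")
  hotspot_region <- normalize_region_name(hotspot_region)
  if (!hotspot_region %in% normalize_region_name(names(region_lengths)))
    stop("hotspot region '", hotspot_region, "' absent from region_lengths")
  structure(list(region_lengths = region_lengths,
                 hotspot_region = hotspot_region,
                 hotspot_enrichment = hotspot_enrichment,
                 n_breakpoints = n_breakpoints,
                 stem_len = stem_len, loop_len = loop_len,
                 cushion_len = cushion_len, at_len = at_len,
                 junction = junction,
                 g4_density = g4_density,
                 palindrome_density = palindrome_density,
                 base_gc = base_gc, seed = seed),
            class = "SynthConfig")
}

sample_bases <- function(n, gc) {
  if (n <= 0) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# region table implied by a config (kinds parsed from the names)
synth_model <- function(cfg) {
  nm <- normalize_region_name(names(cfg$region_lengths))
  kind <- ifelse(grepl("^exon", nm), "exon", "intron")
  L <- sum(cfg$region_lengths)
  ends <- cumsum(as.integer(cfg$region_lengths))
  gene_model(data.frame(name = nm, kind = kind,
                        length = as.integer(cfg$region_lengths),
                        genomic_start = c(1L, ends[-length(ends)] + 1L),
                        genomic_end = ends),
             gene_name = "synthgene", assembly = "synthetic", strand = "+")
}

#' Generate a synthetic gene
#'
#' Background bases are i.i.d. at `base_gc`. When `stem_len > 0` a
#' structured block is planted inside the hotspot region: a GC-rich
#' cushion, then a perfect inverted repeat of `stem_len` bp arms around
#' a small loop (a strong hairpin), then an AT-rich unstructured block.
#' Anchored at window starts, the folding profile's steepest transition
#' then falls at the hairpin stem start, recorded as `truth$junction`.
#' G4 motifs (canonical `G3 N2 G3 N2 G3 N2 G3`) and perfect 6-bp-arm
#' palindromes are planted at the configured per-kb densities, avoiding
#' the structured block and each other.
#'
#' @param cfg a [synth_config()].
#' @param seed overrides `cfg$seed`.
#' @return list with `sequence` (character), `model` ([gene_model()]
#'   with genomic coordinates 1..L), and `truth` (`SynthTruth` list:
#'   `junction`, `block` start/end, planted motif coordinates,
#'   per-region generative probabilities).
#' @export
generate_gene <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "SynthConfig"))
  model <- synth_model(cfg)
  L <- total_length(model)
  rg <- model$regions
  hot <- match(cfg$hotspot_region, rg$name)
  with_seed(seed, {
    ch <- sample_bases(L, cfg$base_gc)
    occupied <- data.frame(start = integer(0), end = integer(0))
    junction <- NA_integer_
    block <- NULL
    if (cfg$stem_len > 0) {
      blen <- 2L * cfg$stem_len + cfg$loop_len
      span <- cfg$cushion_len + blen + cfg$at_len
      hs <- rg$transcript_start[hot]; he <- rg$transcript_end[hot]
      junction <- cfg$junction
      if (is.null(junction))
        junction <- hs + (he - hs - span) %/% 2 + cfg$cushion_len
      b0 <- junction - cfg$cushion_len          # block start (0-based)
      if (b0 < hs || b0 + span > he)
        stop("planted structured block does not fit inside the hotspot")
      arm <- sample_bases(cfg$stem_len, 0.9)
      hair <- c(arm, rep("T", cfg$loop_len),
                strsplit(revcomp_chr(paste(arm, collapse = "")), "")[[1]])
      blockseq <- c(sample_bases(cfg$cushion_len, 0.8), hair,
                    sample_bases(cfg$at_len, 0.05))
      ch[(b0 + 1):(b0 + span)] <- blockseq
      block <- c(start = b0, end = b0 + span)
      occupied <- rbind(occupied,
                        data.frame(start = b0, end = b0 + span))
    }
    g4_motif <- strsplit("GGGATGGGATGGGATGGG", "")[[1]]
    planted_g4 <- plant_motifs(ch, rg, cfg$g4_density, occupied,
                               function() g4_motif)
    ch <- planted_g4$ch; occupied <- planted_g4$occupied
    planted_pal <- plant_motifs(ch, rg, cfg$palindrome_density, occupied,
                                function() {
      a <- sample_bases(6, 0.5)
      c(a, strsplit(revcomp_chr(paste(a, collapse = "")), "")[[1]])
    })
    ch <- planted_pal$ch
    p_len <- rg$length / sum(rg$length)
    probs <- (1 - cfg$hotspot_enrichment) * p_len
    probs[hot] <- probs[hot] + cfg$hotspot_enrichment
    truth <- structure(list(
      junction = junction, block = block,
      g4 = planted_g4$placed, palindrome = planted_pal$placed,
      region_probs = setNames(probs, rg$name)), class = "SynthTruth")
    list(sequence = paste(ch, collapse = ""), model = model, truth = truth)
  })
}

# plant motif instances at `density` per kb per region, uniformly at
# random, rejecting overlaps with `occupied` intervals (small margin)
plant_motifs <- function(ch, rg, density, occupied, make_motif) {
  placed <- data.frame(start = integer(0), end = integer(0))
  for (r in seq_len(nrow(rg))) {
    n_r <- round(density * rg$length[r] / 1000)
    for (m in seq_len(n_r)) {
      motif <- make_motif()
      w <- length(motif)
      lo <- rg$transcript_start[r]; hi <- rg$transcript_end[r] - w
      if (hi < lo)
        stop("motifs requested denser than placeable in ", rg$name[r])
      done <- FALSE
      for (try in 1:200) {
        s0 <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        clash <- any(s0 - 2L < occupied$end & s0 + w + 2L > occupied$start)
        if (!clash) {
          ch[(s0 + 1):(s0 + w)] <- motif
          occupied <- rbind(occupied,
                            data.frame(start = s0, end = s0 + w))
          placed <- rbind(placed, data.frame(start = s0, end = s0 + w))
          done <- TRUE
          break
        }
      }
      if (!done)
        stop("motifs requested denser than placeable in ", rg$name[r])
    }
  }
  list(ch = ch, occupied = occupied, placed = placed)
}

#' Sample breakpoints from the hotspot/length-proportional mixture
#'
#' Draws `N` breakpoints independently: with probability `rho`
#' (`hotspot_enrichment`) uniformly inside the hotspot region, otherwise
#' a length-proportional region draw with a uniform position inside the
#' chosen region. Records carry base-resolution genomic coordinates on
#' the synthetic model's 1..L axis.
#'
#' @param model [gene_model()] from [generate_gene()].
#' @param cfg the matching [synth_config()].
#' @param seed overrides `cfg$seed` (pass a different seed than the one
#'   used for the sequence to decouple the two draws).
#' @return a `BreakpointSet`.
#' @export
sample_breakpoints <- function(model, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "SynthConfig"))
  rg <- model$regions
  hot <- match(cfg$hotspot_region, rg$name)
  if (is.na(hot)) stop("hotspot region '", cfg$hotspot_region,
                       "' absent from the model")
  N <- cfg$n_breakpoints
  with_seed(seed, {
    from_hot <- runif(N) < cfg$hotspot_enrichment
    reg <- integer(N)
    reg[from_hot] <- hot
    n_bg <- sum(!from_hot)
    if (n_bg > 0)
      reg[!from_hot] <- sample.int(nrow(rg), n_bg, replace = TRUE,
                                   prob = rg$length)
    pos <- rg$transcript_start[reg] +
      vapply(rg$length[reg], function(l) sample.int(l, 1L), integer(1)) - 1L
    breakpoint_set(data.frame(
      sample_id = sprintf("synth%03d", seq_len(N)),
      region_name = rg$name[reg],
      genomic_coord = pos + 1L,       # model coordinates are 1..L
      resolution = "base", source = "dna_seq",
      stringsAsFactors = FALSE))
  })
}

#' Write a synthetic bundle (FASTA + region TSV + breakpoints + truth)
#'
#' Emits the full self-contained input set for a pipeline run:
#' `gene.fasta`, `regions.tsv`, `breakpoints.tsv`, `truth.json`.
#' Identical config and seed produce byte-identical files.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @param seed overrides `cfg$seed`.
#' @return invisibly, the named vector of file paths.
#' @export
write_synth_bundle <- function(cfg, dir, seed = cfg$seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(seed)) stop("a seed is required for a reproducible bundle")
  gen <- generate_gene(cfg, seed = seed)
  bps <- sample_breakpoints(gen$model, cfg, seed = seed + 1L)
  paths <- c(fasta = file.path(dir, "gene.fasta"),
             regions = file.path(dir, "regions.tsv"),
             breakpoints = file.path(dir, "breakpoints.tsv"),
             truth = file.path(dir, "truth.json"))
  ss <- Biostrings::DNAStringSet(gen$sequence)
  names(ss) <- gen$model$gene_name
  Biostrings::writeXStringSet(ss, paths[["fasta"]])
  write_gene_model(gen$model, paths[["regions"]])
  write_breakpoints(bps, paths[["breakpoints"]])
  jsonlite::write_json(
    list(junction = gen$truth$junction, block = gen$truth$block,
         g4 = gen$truth$g4, palindrome = gen$truth$palindrome,
         region_probs = as.list(gen$truth$region_probs), seed = seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
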