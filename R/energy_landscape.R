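#' @title Folding free-energy landscape and stability fluctuation
#' @description Sliding-window minimum folding free-energy (DeltaG)
#'   profile of a gene sequence, the local thermodynamic stability
#'   fluctuation statistic |dDeltaG| (absolute DeltaG difference between
#'   windows a fixed interval apart), IQR-outlier peak calling, and
#'   peak/hotspot co-localization.
#' @name energy_landscape
NULL

#' Built-in DNA folding free energy (kcal/mol)
#'
#' Dynamic-programming minimum free energy over non-crossing base pairs
#' (Watson-Crick, optional G.T wobble) with unified nearest-neighbor
#' stacking energies at 37 degC / 1 M NaCl, hairpin loops of at least
#' 3 nt, and tabulated bulge/internal loop penalties with logarithmic
#' extrapolation (see [dna_nn_params()]). Multibranch loops are not
#' modeled. Sequences that cannot form any favorable structure return 0;
#' the result is never positive.
#'
#' @param seq nucleotide string over A/C/G/T, length >= 8.
#' @param temp,na_molar simulated conditions; only the shipped 37 degC /
#'   1 M parameter set is available and other values are an error.
#' @param params parameter list from [dna_nn_params()].
#' @param wobble allow G.T wobble pairs (default FALSE).
#' @return DeltaG in kcal/mol (<= 0); deterministic.
#' @export
builtin_fold <- function(seq, temp = 37, na_molar = 1.0,
                         params = dna_nn_params(), wobble = FALSE) {
  if (temp != 37 || na_molar != 1.0)
    stop("only the 37 degC / 1 M Na+ parameter set is shipped")
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) < 8)
    stop("seq must be a single ACGT string of length >= 8")
  hp <- params$hairpin
  hp[!is.finite(hp)] <- 1e6
  .fold_dna_cpp(seq, params$stack, hp, params$bulge, params$internal,
                params$lxc, params$asym, params$asym_max,
                params$wobble_stack, params$min_hairpin, params$max_loop,
                wobble)
}

#' Folding backends
#'
#' A backend is a list with a `name`, a free-text `parameter_set`
#' description, and a `fold(seq)` function returning DeltaG in kcal/mol
#' (deterministic, <= 0). `builtin_backend()` wraps [builtin_fold()];
#' `command_backend()` adapts any external folder invoked as a shell
#' command reading one sequence on stdin and printing one number
#' (so e.g. an RNAfold/mfold wrapper script can be plugged in).
#'
#' @param params parameters for the built-in folder.
#' @param wobble allow G.T wobble pairs.
#' @return a `FoldingBackend` list.
#' @export
builtin_backend <- function(params = dna_nn_params(), wobble = FALSE) {
  structure(list(
    name = "builtin",
    parameter_set = "unified DNA NN, 37 degC, [Na+]=1.0 M, [Mg2+]=0.0 M",
    fold = function(seq) builtin_fold(seq, params = params, wobble = wobble)),
    class = "FoldingBackend")
}

#' @rdname builtin_backend
#' @param command shell command; receives the window sequence on stdin
#'   and must print a single DeltaG value (kcal/mol).
#' @param name backend label stored in the profile.
#' @export
command_backend <- function(command, name = "command") {
  structure(list(
    name = name,
    parameter_set = command,
    fold = function(seq) {
      out <- system(command, input = seq, intern = TRUE)
      v <- if (length(out))
        suppressWarnings(as.numeric(out[length(out)])) else NA_real_
      if (is.na(v)) stop("backend '", name, "' did not print a number")
      min(v, 0)
    }), class = "FoldingBackend")
}

#' Sliding-window folding free-energy profile
#'
#' Folds every window of `window_len` bases advancing by `step` and
#' assigns each DeltaG to the 0-based coordinate of the window's
#' starting nucleotide. The last window ends at the sequence end; no
#' padded context is used.
#'
#' @param seq gene sequence (transcript orientation).
#' @param backend a `FoldingBackend` (default [builtin_backend()]).
#' @param window_len window size in bp (default 300, the approximate
#'   length of transiently exposed single-stranded DNA such as an
#'   Okazaki fragment).
#' @param step start-to-start spacing in bp (default 1).
#' @return an `EnergyProfile`: data.frame with `pos` (0-based window
#'   start) and `dG`, plus attributes `window_len`, `step`,
#'   `backend_name`.
#' @export
energy_profile <- function(seq, backend = builtin_backend(),
                           window_len = 300, step = 1) {
  L <- nchar(seq)
  if (L < window_len)
    stop("sequence (", L, " bp) shorter than the window (", window_len, ")")
  starts <- seq.int(0L, L - window_len, by = step)
  dG <- vapply(starts, function(i) {
    backend$fold(substr(seq, i + 1L, i + window_len))
  }, numeric(1))
  stopifnot(all(dG <= 0))
  structure(data.frame(pos = starts, dG = dG),
            window_len = as.integer(window_len), step = as.integer(step),
            backend_name = backend$name,
            class = c("EnergyProfile", "data.frame"))
}

#' Build an energy profile from a precomputed per-window DeltaG table
#'
#' Ingests the output of an external folder (e.g. mfold run offline) as
#' a 2-column TSV `pos  dG` with 0-based window start coordinates.
#'
#' @param path TSV file with columns `pos` and `dG`.
#' @inheritParams energy_profile
#' @export
energy_profile_from_tsv <- function(path, window_len = 300, step = 1) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pos", "dG") %in% names(tb)))
    stop("expected columns pos and dG in ", path)
  structure(data.frame(pos = as.integer(tb$pos), dG = pmin(tb$dG, 0)),
            window_len = as.integer(window_len), step = as.integer(step),
            backend_name = "precomputed-file",
            class = c("EnergyProfile", "data.frame"))
}

#' Thermodynamic stability fluctuation |dDeltaG|
#'
#' `values[i] = |dG[i + interval] - dG[i]|` over the energy profile:
#' the absolute change in folding free energy between two windows
#' `interval` profile steps apart (with the default step of 1, a 30-bp
#' coordinate interval). High values mark sharp transitions between
#' structured and unstructured sequence.
#'
#' @param ep an [energy_profile()].
#' @param interval offset in profile positions (default 30).
#' @return a `FluctuationProfile`: data.frame with `pos` (coordinate of
#'   the left window) and `value` (>= 0).
#' @export
fluctuation_profile <- function(ep, interval = 30) {
  n <- nrow(ep)
  if (n <= interval)
    stop("profile too short (", n, " values) for interval ", interval)
  idx <- seq_len(n - interval)
  structure(data.frame(pos = ep$pos[idx],
                       value = abs(ep$dG[idx + interval] - ep$dG[idx])),
            interval = as.integer(interval),
            step = attr(ep, "step"),
            class = c("FluctuationProfile", "data.frame"))
}

#' IQR-outlier peaks of the fluctuation profile
#'
#' A profile value is a peak when it strictly exceeds
#' `Q3 + multiplier * IQR`, with quartiles computed over all profile
#' values using linear interpolation between order statistics
#' (`stats::quantile` type 7). Adjacent above-threshold positions are
#' reported raw and merged into intervals. When a gene model is given,
#' each profile value is assigned to the region containing its start
#' coordinate and the per-region maximum |dDeltaG| is reported (0 for a
#' region in which no window starts, e.g. past the last full window).
#'
#' @param fp a [fluctuation_profile()].
#' @param model optional [gene_model()] on the same coordinate axis.
#' @param multiplier IQR multiplier (default 3, extreme outliers).
#' @return a `PeakSet` list: `threshold`, `q3`, `iqr`, `peaks`
#'   (data.frame pos/value), `intervals` (merged start/end half-open),
#'   `region_max` (data.frame region/max_abs_ddG, when `model` given).
#' @export
iqr_peaks <- function(fp, model = NULL, multiplier = 3) {
  if (!nrow(fp)) stop("empty fluctuation profile")
  qs <- quantile(fp$value, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- qs[2] - qs[1]
  thr <- qs[2] + multiplier * iqr
  hit <- fp$value > thr
  peaks <- fp[hit, , drop = FALSE]
  rownames(peaks) <- NULL
  intervals <- if (any(hit)) {
    step <- attr(fp, "step")
    if (is.null(step)) step <- 1L
    r <- rle(hit)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1
    data.frame(start = fp$pos[s[r$values]],
               end = fp$pos[e[r$values]] + step)
  } else data.frame(start = integer(0), end = integer(0))
  region_max <- NULL
  if (!is.null(model)) {
    rg <- model$regions
    idx <- findInterval(fp$pos, rg$transcript_start)
    ok <- idx >= 1 & fp$pos < rg$transcript_end[pmax(idx, 1)]
    mx <- tapply(fp$value[ok], factor(rg$name[idx[ok]], levels = rg$name),
                 max)
    mx[is.na(mx)] <- 0   # no window starts in the region: no fluctuation
    region_max <- data.frame(region = rg$name,
                             max_abs_ddG = as.numeric(mx))
  }
  structure(list(threshold = thr, q3 = qs[2], iqr = iqr,
                 multiplier = multiplier, peaks = peaks,
                 intervals = intervals, region_max = region_max),
            class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet: %d peak position(s) above Q3 + %g*IQR = %.4g\n",
              nrow(x$peaks), x$multiplier, x$threshold))
  if (nrow(x$intervals)) {
    cat("merged intervals:\n")
    print(x$intervals, row.names = FALSE)
  }
  invisible(x)
}

#' Peak / breakpoint-hotspot co-localization
#'
#' For a region hotspot the association window is
#' `[region_start - flank, region_end + flank)`; for a point hotspot a
#' window of total width `flank` centered on the point (so the default
#' `flank = 500` means +/- 250 bp around a point). Reports whether any
#' peak falls inside the window and the distance from each peak to the
#' hotspot.
#'
#' @param peaks a [iqr_peaks()] result.
#' @param hotspot either a region name (requires `model`) or a single
#'   numeric coordinate on the profile axis.
#' @param model [gene_model()] used to resolve a region-name hotspot.
#' @param flank window extension in bp (default 500).
#' @return list with `colocalized` (logical), `window` (start/end),
#'   `distances` (bp from each peak to the hotspot region/point;
#'   empty when there are no peaks), `nearest` (minimum distance or NA).
#' @export
colocalize <- function(peaks, hotspot, model = NULL, flank = 500) {
  stopifnot(inherits(peaks, "PeakSet"))
  if (is.character(hotspot)) {
    if (is.null(model)) stop("a region hotspot needs a gene model")
    hotspot <- normalize_region_name(hotspot)
    rg <- model$regions
    i <- match(hotspot, rg$name)
    if (is.na(i)) stop("unknown hotspot region: ", hotspot)
    win <- c(rg$transcript_start[i] - flank, rg$transcript_end[i] + flank)
    core <- c(rg$transcript_start[i], rg$transcript_end[i])
  } else {
    stopifnot(is.numeric(hotspot), length(hotspot) == 1)
    win <- c(hotspot - flank / 2, hotspot + flank / 2)
    core <- c(hotspot, hotspot + 1)
  }
  pos <- peaks$peaks$pos
  if (!length(pos))
    return(list(colocalized = FALSE, window = win,
                distances = numeric(0), nearest = NA_real_))
  inside <- pos >= win[1] & pos < win[2]
  dist <- pmax(core[1] - pos, pos - core[2] + 1, 0)
  list(colocalized = any(inside), window = win,
       distances = dist, nearest = min(dist))
}

#' Export a profile as 2-column TSV (and peaks as BED)
#' @param x an `EnergyProfile` or `FluctuationProfile`.
#' @param path output file.
#' @export
write_profile <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param peaks a `PeakSet`.
#' @param chrom name used in the BED chrom column (the gene name).
#' @export
write_peaks_bed <- function(peaks, path, chrom = "gene") {
  iv <- peaks$intervals
  if (nrow(iv)) {
    bed <- data.frame(chrom = chrom, start = iv$start, end = iv$end,
                      name = sprintf("peak%d", seq_len(nrow(iv))),
                      score = 0, strand = "+")
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else file.create(path)
  invisible(path)
}

#' Export motif hits as BED6
#' @param hits a `MotifHit` data.frame.
#' @param path output file.
#' @param chrom BED chrom column value.
#' @export
write_hits_bed <- function(hits, path, chrom = "gene") {
  if (nrow(hits)) {
    bed <- data.frame(chrom = chrom, start = hits$start, end = hits$end,
                      name = hits$motif_kind, score = hits$score,
                      strand = hits$strand)
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else file.create(path)
  invisible(path)
}
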