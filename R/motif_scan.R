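#' @title Non-canonical DNA structure motif scanners
#' @description Re-implementations of the motif predictors used for
#'   G-quadruplex and palindrome/cruciform annotation: a per-base
#'   run-scoring window scan (G4Hunter style), a four-G-tract pattern
#'   finder with a G-score (QGRS style), and an inverted-repeat finder
#'   with spacer and mismatch tolerance. Coordinates are 0-based
#'   half-open on the scanned (sense) strand.
#' @name motif_scan
NULL

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chr <- function(s) {
  paste(rev(DNA_COMPLEMENT[strsplit(toupper(s), "", fixed = TRUE)[[1]]]),
        collapse = "")
}

seq_chars <- function(seq) {
  s <- toupper(seq)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("sequence alphabet must be ACGTN; offending symbol(s): ",
         paste(bad, collapse = ", "))
  ch
}

new_motif_hits <- function(kind, start, end, strand, score, detail,
                           max_len = Inf) {
  df <- data.frame(motif_kind = rep(kind, length(start)),
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, score = as.numeric(score),
                   detail = detail, stringsAsFactors = FALSE)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  stopifnot(all(df$start < df$end), all(df$end - df$start <= max_len))
  class(df) <- c("MotifHit", "data.frame")
  df
}

#' G4Hunter-style window scan
#'
#' Per-base scores follow the published run-scoring rule: a G inside a
#' run of `k` consecutive Gs scores `+min(k, 4)`, a C in a run of `k` Cs
#' scores `-min(k, 4)`, A/T (and N) score 0. Windows whose mean score
#' has absolute value at least `threshold` are merged (consecutive
#' qualifying window starts of the same sign) into maximal hits; each
#' hit carries the most extreme window mean as its score. Positive
#' scores mark G-rich (sense strand) candidates, negative scores C-rich
#' (antisense) candidates.
#'
#' @param seq nucleotide string.
#' @param window_len sliding window length (published default 25).
#' @param threshold absolute window mean needed to qualify (default 1.2).
#' @return `MotifHit` data.frame of kind `g4_window`.
#' @export
g4hunter_scan <- function(seq, window_len = 25, threshold = 1.2) {
  if (window_len < 1) stop("window_len must be >= 1")
  ch <- seq_chars(seq)
  L <- length(ch)
  if (L < window_len) stop("window (", window_len,
                           ") longer than sequence (", L, ")")
  r <- rle(ch)
  per_run <- ifelse(r$values == "G", pmin(r$lengths, 4),
                    ifelse(r$values == "C", -pmin(r$lengths, 4), 0))
  base_score <- rep(per_run, r$lengths)
  cs <- c(0, cumsum(base_score))
  means <- (cs[(window_len + 1):(L + 1)] - cs[1:(L - window_len + 1)]) /
    window_len
  qual <- abs(means) >= threshold
  if (!any(qual))
    return(new_motif_hits("g4_window", integer(0), integer(0),
                          character(0), numeric(0), character(0)))
  sign_grp <- ifelse(qual, sign(means), 0)
  r2 <- rle(sign_grp)
  ends_idx <- cumsum(r2$lengths)
  starts_idx <- ends_idx - r2$lengths + 1
  keep <- r2$values != 0
  hs <- starts_idx[keep]; he <- ends_idx[keep]
  score <- mapply(function(a, b) {
    m <- means[a:b]; m[which.max(abs(m))]
  }, hs, he)
  new_motif_hits("g4_window",
                 start = hs - 1L, end = he - 1L + window_len,
                 strand = ifelse(score > 0, "+", "-"),
                 score = score,
                 detail = sprintf("window_mean=%.4f", score))
}

# length of the G-run starting at each position (0 when the base is not G)
g_run_from <- function(ch) {
  L <- length(ch)
  run <- integer(L)
  k <- 0L
  for (i in seq(L, 1)) {
    k <- if (ch[i] == "G") k + 1L else 0L
    run[i] <- k
  }
  run
}

qgrs_score <- function(g, l1, l2, l3) {
  # vectorized over candidates: rewards larger tracts, short even loops
  40 * (g - 2) - (pmax(l1, l2, l3) - pmin(l1, l2, l3)) -
    (l1 + l2 + l3) / 3
}

#' QGRS-style G-quadruplex pattern finder
#'
#' Finds motifs of the form `G{g} N{l1} G{g} N{l2} G{g} N{l3} G{g}` with
#' equal tract size `g >= min_g_group`, each loop within
#' `[loop_min, loop_max]`, and total span at most `max_len`. Overlapping
#' candidates are reduced to the highest-scoring non-overlapping set
#' (greedy by score, leftmost start breaking ties). The G-score rewards
#' larger tracts and short, even loops:
#' `40*(g-2) - (max(l) - min(l)) - mean(l)` (an uncalibrated analogue of
#' the QGRS G-score; the published constant is not reproduced).
#'
#' @param seq nucleotide string.
#' @param max_len maximum motif span (default 30).
#' @param min_g_group minimum G-tract size (default 2).
#' @param loop_min,loop_max loop length bounds (defaults 0 and 36).
#' @param both_strands also scan the reverse complement, reporting hits
#'   on `-` with coordinates on the input strand.
#' @return `MotifHit` data.frame of kind `g4_pattern`.
#' @export
qgrs_scan <- function(seq, max_len = 30, min_g_group = 2,
                      loop_min = 0, loop_max = 36, both_strands = FALSE) {
  if (min_g_group < 2) stop("min_g_group must be >= 2")
  if (max_len < 4 * min_g_group) stop("max_len cannot hold four G-tracts")
  if (loop_min < 0 || loop_max < loop_min) stop("invalid loop bounds")
  cand <- qgrs_candidates(seq, max_len, min_g_group, loop_min, loop_max)
  if (both_strands) {
    L <- nchar(seq)
    rc <- qgrs_candidates(revcomp_chr(seq), max_len, min_g_group,
                          loop_min, loop_max)
    if (nrow(rc)) {
      tmp <- rc$start
      rc$start <- L - rc$end
      rc$end <- L - tmp
      rc$strand <- "-"
      cand <- rbind(cand, rc)
    }
  }
  sel <- select_nonoverlapping(cand)
  new_motif_hits("g4_pattern", sel$start, sel$end, sel$strand, sel$score,
                 sel$detail, max_len = max_len)
}

qgrs_candidates <- function(seq, max_len, min_g_group, loop_min, loop_max) {
  ch <- seq_chars(seq)
  L <- length(ch)
  run <- g_run_from(ch)
  out <- list()
  g_max <- min(max_len %/% 4, max(run, 0))
  g <- min_g_group
  while (g <= g_max) {
    S <- which(run >= g)           # 1-based tract start positions
    budget <- max_len - 4 * g      # total loop budget
    if (budget >= 3 * loop_min && length(S) >= 4) {
      for (p1 in S) {
        lim <- p1 + max_len - 1
        s2 <- S[S >= p1 + g + loop_min & S <= p1 + g + loop_max & S <= lim]
        for (p2 in s2) {
          l1 <- p2 - p1 - g
          s3 <- S[S >= p2 + g + loop_min & S <= p2 + g + loop_max & S <= lim]
          for (p3 in s3) {
            l2 <- p3 - p2 - g
            s4 <- S[S >= p3 + g + loop_min & S <= p3 + g + loop_max &
                      S + g - 1 <= lim]
            for (p4 in s4) {
              l3 <- p4 - p3 - g
              out[[length(out) + 1L]] <-
                c(p1 - 1L, p4 + g - 1L, g, l1, l2, l3)
            }
          }
        }
      }
    }
    g <- g + 1L
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      detail = character(0), stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2], strand = "+",
             score = qgrs_score(m[, 3], m[, 4], m[, 5], m[, 6]),
             detail = sprintf("g=%d;loops=%d,%d,%d",
                              m[, 3], m[, 4], m[, 5], m[, 6]),
             stringsAsFactors = FALSE)
}

# greedy highest-score-first non-overlapping selection,
# leftmost-start (then shortest) tie-break
select_nonoverlapping <- function(cand) {
  if (!nrow(cand)) return(cand)
  o <- order(-cand$score, cand$start, cand$end)
  cand <- cand[o, , drop = FALSE]
  kept_s <- numeric(0); kept_e <- numeric(0); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < kept_e & cand$end[i] > kept_s)) {
      keep[i] <- TRUE
      kept_s <- c(kept_s, cand$start[i])
      kept_e <- c(kept_e, cand$end[i])
    }
  }
  cand[keep, , drop = FALSE]
}

#' Inverted repeat (palindrome/cruciform) finder
#'
#' Reports arm-spacer-arm motifs in which the second arm is the reverse
#' complement of the first with at most `max_mismatch` mismatching
#' pairs, spacer length within `[spacer_min, spacer_max]`, and total
#' motif length (arm + spacer + arm) within `[min_total, max_total]`.
#' The published "min length 6 / max length 30" is interpreted as the
#' total motif length with an arm of at least `arm_min` (default 3).
#' Only maximal non-redundant hits are reported: a motif strictly
#' contained in another valid motif is dropped, and coincident intervals
#' reachable by several arm/spacer decompositions are reported once
#' (fewest mismatches, then longest arm).
#'
#' @param seq nucleotide string.
#' @param min_total,max_total bounds on the total motif length.
#' @param spacer_min,spacer_max bounds on the spacer length.
#' @param max_mismatch maximum mismatching arm pairs (indels not
#'   allowed).
#' @param arm_min minimum arm length.
#' @return `MotifHit` data.frame of kind `palindrome`; score is
#'   `arm - mismatches` (longer perfect arms score higher).
#' @export
palindrome_scan <- function(seq, min_total = 6, max_total = 30,
                            spacer_min = 0, spacer_max = 10,
                            max_mismatch = 1, arm_min = 3) {
  stopifnot(min_total >= 2, max_total >= min_total, spacer_min >= 0,
            spacer_max >= spacer_min, max_mismatch >= 0, arm_min >= 1)
  ch <- seq_chars(seq)
  L <- length(ch)
  comp <- unname(DNA_COMPLEMENT[ch])
  cand <- list()
  for (a in seq(arm_min, max((max_total - spacer_min) %/% 2, arm_min))) {
    for (s in seq(spacer_min, spacer_max)) {
      d <- 2L * a + s
      if (d < min_total || d > max_total || d > L) next
      n <- L - d + 1L
      mm <- integer(n)
      for (k in 0:(a - 1L)) {
        # N never matches anything (comp of N is N but we require ACGT)
        lhs <- ch[(1L + k):(n + k)]
        rhs <- comp[(d - k):(L - k)]
        mm <- mm + as.integer(lhs != rhs | lhs == "N")
      }
      ok <- which(mm <= max_mismatch)
      if (length(ok))
        cand[[length(cand) + 1L]] <-
          data.frame(start = ok - 1L, end = ok - 1L + d, arm = a,
                     spacer = s, mm = mm[ok])
    }
  }
  if (!length(cand))
    return(new_motif_hits("palindrome", integer(0), integer(0),
                          character(0), numeric(0), character(0)))
  cand <- do.call(rbind, cand)
  # one record per interval: fewest mismatches, then longest arm
  cand <- cand[order(cand$start, cand$end, cand$mm, -cand$arm), ]
  cand <- cand[!duplicated(cand[, c("start", "end")]), ]
  # maximality: drop intervals strictly contained in another candidate.
  # After sorting by (start asc, end desc), non-first rows of a start
  # group are contained in the first; with one row per start, a row is
  # contained iff some earlier (smaller) start reaches at least as far.
  cand <- cand[order(cand$start, -cand$end), ]
  cand <- cand[!duplicated(cand$start), , drop = FALSE]
  prev_max <- cummax(c(-1L, cand$end))[seq_len(nrow(cand))]
  cand <- cand[cand$end > prev_max, , drop = FALSE]
  new_motif_hits("palindrome", cand$start, cand$end, "+",
                 score = cand$arm - cand$mm,
                 detail = sprintf("arm=%d;spacer=%d;mismatches=%d",
                                  cand$arm, cand$spacer, cand$mm),
                 max_len = max_total)
}

#' Per-region motif counts and densities
#'
#' A hit is counted in the region containing its start coordinate;
#' `density_per_kb = 1000 * count / length_bp`.
#'
#' @param hits `MotifHit` data.frame (transcript coordinates).
#' @param model a [gene_model()].
#' @return data.frame with `region_name`, `motif_kind`, `count`,
#'   `density_per_kb`, one row per region x motif kind.
#' @export
motif_density <- function(hits, model) {
  rg <- model$regions
  kinds <- unique(as.character(hits$motif_kind))
  if (!length(kinds)) kinds <- "none"
  out <- expand.grid(region_name = rg$name, motif_kind = kinds,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$count <- 0L
  if (nrow(hits)) {
    if (any(hits$start < 0 | hits$start >= total_length(model)))
      stop("motif hit start outside the gene model span")
    idx <- findInterval(hits$start, rg$transcript_start)
    tab <- table(factor(rg$name[idx], levels = rg$name),
                 factor(hits$motif_kind, levels = kinds))
    for (k in kinds)
      out$count[out$motif_kind == k] <- as.integer(tab[, k])
  }
  out$density_per_kb <- 1000 * out$count /
    rg$length[match(out$region_name, rg$name)]
  out
}
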