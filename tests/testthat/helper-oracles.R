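# Independent oracles and small generators shared across the suite.
# The oracles are deliberately naive (exhaustive enumeration, hand
# arithmetic) and are written against the documented contracts, not
# against the package internals.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(COMP[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# exhaustive inverted-repeat enumeration over all (position, arm,
# spacer) triples, then the documented redundancy rules: one record per
# interval (fewest mismatches, then longest arm) and no interval
# strictly contained in another valid interval
oracle_palindromes <- function(seq, min_total = 6, max_total = 30,
                               spacer_min = 0, spacer_max = 10,
                               max_mismatch = 1, arm_min = 3) {
  ch <- strsplit(toupper(seq), "")[[1]]
  L <- length(ch)
  rows <- list()
  for (i in seq_len(L)) {
    for (a in arm_min:((max_total - spacer_min) %/% 2)) {
      for (s in spacer_min:spacer_max) {
        total <- 2 * a + s
        if (total < min_total || total > max_total) next
        if (i + total - 1 > L) next
        arm1 <- ch[i:(i + a - 1)]
        arm2 <- ch[(i + a + s):(i + total - 1)]
        mm <- sum(arm1 != COMP[rev(arm2)] | arm1 == "N")
        if (mm <= max_mismatch)
          rows[[length(rows) + 1]] <-
            data.frame(start = i - 1, end = i - 1 + total, arm = a,
                       spacer = s, mm = mm)
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      arm = integer(0), spacer = integer(0),
                      mm = integer(0)))
  cand <- do.call(rbind, rows)
  cand <- cand[order(cand$start, cand$end, cand$mm, -cand$arm), ]
  cand <- cand[!duplicated(cand[, c("start", "end")]), ]
  contained <- vapply(seq_len(nrow(cand)), function(j) {
    any(cand$start <= cand$start[j] & cand$end >= cand$end[j] &
          !(cand$start == cand$start[j] & cand$end == cand$end[j]))
  }, logical(1))
  out <- cand[!contained, ]
  out[order(out$start, out$end), ]
}

# exhaustive four-G-tract enumeration with the documented score and an
# independently coded greedy non-overlapping selection
oracle_qgrs <- function(seq, max_len = 30, min_g = 2,
                        loop_min = 0, loop_max = 36) {
  ch <- strsplit(toupper(seq), "")[[1]]
  L <- length(ch)
  tract <- function(p, g) p + g - 1 <= L && all(ch[p:(p + g - 1)] == "G")
  rows <- list()
  for (g in min_g:(max_len %/% 4)) {
    for (p1 in seq_len(L)) {
      if (!tract(p1, g)) next
      for (l1 in loop_min:loop_max) {
        p2 <- p1 + g + l1
        if (p2 + 3 * g - 1 > L || p2 + g - 1 - p1 + 1 > max_len) break
        if (!tract(p2, g)) next
        for (l2 in loop_min:loop_max) {
          p3 <- p2 + g + l2
          if (p3 + 2 * g - 1 > L || p3 + g - 1 - p1 + 1 > max_len) break
          if (!tract(p3, g)) next
          for (l3 in loop_min:loop_max) {
            p4 <- p3 + g + l3
            span <- p4 + g - p1
            if (p4 + g - 1 > L || span > max_len) break
            if (!tract(p4, g)) next
            loops <- c(l1, l2, l3)
            rows[[length(rows) + 1]] <- data.frame(
              start = p1 - 1, end = p1 - 1 + span,
              score = 40 * (g - 2) - (max(loops) - min(loops)) -
                sum(loops) / 3)
          }
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0)))
  cand <- do.call(rbind, rows)
  cand <- cand[order(-cand$score, cand$start, cand$end), ]
  keep <- rep(FALSE, nrow(cand))
  for (j in seq_len(nrow(cand))) {
    ok <- TRUE
    if (any(keep)) {
      k <- which(keep)
      ok <- all(cand$end[j] <= cand$start[k] | cand$start[j] >= cand$end[k])
    }
    keep[j] <- ok
  }
  out <- cand[keep, ]
  out[order(out$start, out$end), ]
}

# hand nearest-neighbor arithmetic for a single hairpin: sum of the
# stacking steps along the stem plus the tabulated loop penalty
oracle_hairpin_dG <- function(arm, loop_len, params = dna_nn_params()) {
  b <- strsplit(toupper(arm), "")[[1]]
  steps <- sum(vapply(seq_len(length(b) - 1), function(i) {
    params$stack[b[i], b[i + 1]]
  }, numeric(1)))
  steps + params$hairpin[loop_len]
}

# toy energy/fluctuation profiles built without the folding engine
fake_energy_profile <- function(values, step = 1L, window_len = 300L) {
  structure(data.frame(pos = seq(0L, by = step, length.out = length(values)),
                       dG = values),
            window_len = as.integer(window_len), step = as.integer(step),
            backend_name = "fake",
            class = c("EnergyProfile", "data.frame"))
}

# small scaled-down synthetic world used by the heavier tests: quarter
# region lengths, one-window cushions (runtime, not statistics, is the
# reason for the scaling)
scaled_lengths <- c(exon1 = 62, intron1 = 636, exon2 = 50, intron2 = 262,
                    exon3 = 76, intron3 = 166, exon4 = 61, intron4 = 50,
                    exon5 = 50, intron5 = 942, exon6 = 50, intron6 = 88)

scaled_cfg <- function(seed, rho = 0.6, stem_len = 30) {
  synth_config(region_lengths = scaled_lengths, hotspot_enrichment = rho,
               stem_len = stem_len, cushion_len = 100, at_len = 100,
               seed = seed)
}

# run the scaled synthetic pipeline and return the permutation p-value
# for the per-region max |ddG| feature
scaled_e2e_p <- function(seed, rho, stem_len, n_perm = 1000,
                         window = 100, step = 10) {
  cfg <- scaled_cfg(seed, rho = rho, stem_len = stem_len)
  gen <- generate_gene(cfg)
  ep <- energy_profile(gen$sequence, window_len = window, step = step)
  fp <- fluctuation_profile(ep, interval = max(1L, 30L %/% step))
  pk <- iqr_peaks(fp, gen$model)
  B <- assign_breakpoints(sample_breakpoints(gen$model, cfg,
                                             seed = seed + 10000L),
                          gen$model)
  tb <- region_feature_table(gen$model$regions$name,
                             gen$model$regions$length,
                             B, pk$region_max$max_abs_ddG)
  list(p = permutation_test(tb, n_perm = n_perm,
                            seed = seed + 20000L)$p_value,
       B = B, model = gen$model)
}
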