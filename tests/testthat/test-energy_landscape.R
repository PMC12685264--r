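test_that("builtin fold matches hand nearest-neighbor arithmetic", {
  expect_equal(builtin_fold(strrep("A", 50)), 0)
  # designed hairpin: 10-bp GC stem + TTTT tetraloop, scored by hand
  arm <- "GCGCGCGCGC"
  hp <- paste0(arm, "TTTT", oracle_revcomp(arm))
  want <- oracle_hairpin_dG(arm, 4)
  expect_equal(builtin_fold(hp), want)
  # extending the stem by one GC pair is strictly more stable
  hp2 <- paste0("G", hp, "C")
  expect_lt(builtin_fold(hp2), builtin_fold(hp))
  expect_equal(builtin_fold(hp2), oracle_hairpin_dG(paste0("G", arm), 4))
  expect_error(builtin_fold("ACGTNACG"), "ACGT")
  expect_error(builtin_fold("ACGT"), "length")
  expect_error(builtin_fold(strrep("A", 50), temp = 25), "37")
})

test_that("fold is deterministic and never positive", {
  set.seed(3)
  for (rep in 1:10) {
    s <- rand_seq(80, gc = runif(1, 0.2, 0.8))
    d1 <- builtin_fold(s)
    expect_identical(d1, builtin_fold(s))
    expect_lte(d1, 0)
  }
})

test_that("energy profile windows behave as specified", {
  ep <- energy_profile(strrep("A", 400), window_len = 300)
  expect_identical(nrow(ep), 101L)
  expect_true(all(ep$dG == 0))
  expect_identical(nrow(energy_profile(strrep("AT", 150),
                                       window_len = 300)), 1L)
  expect_error(energy_profile(strrep("A", 100), window_len = 300),
               "shorter")
})

test_that("profile equals direct per-window folds (no caching artifacts)", {
  set.seed(13)
  for (rep in 1:10) {
    s <- rand_seq(150, gc = 0.6)
    ep <- energy_profile(s, window_len = 60, step = 7)
    direct <- vapply(ep$pos, function(i) {
      builtin_fold(substr(s, i + 1, i + 60))
    }, numeric(1))
    expect_identical(ep$dG, direct)
  }
})

test_that("a planted hairpin block is the profile minimum", {
  set.seed(17)
  arm <- strrep("GC", 12)
  block <- paste0(arm, "TTTT", oracle_revcomp(arm))
  s <- paste0(rand_seq(300, 0.4), block, rand_seq(300, 0.4))
  ep <- energy_profile(s, window_len = 100, step = 5)
  argmin <- ep$pos[which.min(ep$dG)]
  # the minimal window must cover the planted block (starts 300..352)
  expect_gte(argmin, 300 - 100 + nchar(block))
  expect_lte(argmin, 300)
})

test_that("|ddG| equals hand-computed values on toy profiles", {
  # constant -> all zero
  fp <- fluctuation_profile(fake_energy_profile(rep(-5, 50)), interval = 30)
  expect_true(all(fp$value == 0))
  expect_identical(nrow(fp), 20L)
  # linear ramp dG = -0.1*i -> |ddG| = 3 everywhere
  fp2 <- fluctuation_profile(fake_energy_profile(-0.1 * (0:99)),
                             interval = 30)
  expect_equal(fp2$value, rep(3, 70))
  # step profile: 0 below 100, -12 from 100 on
  fp3 <- fluctuation_profile(fake_energy_profile(
    c(rep(0, 100), rep(-12, 60))), interval = 30)
  expect_equal(max(fp3$value), 12)
  expect_identical(range(fp3$pos[fp3$value == 12]), c(70L, 99L))
  expect_error(fluctuation_profile(fake_energy_profile(rep(0, 10)),
                                   interval = 30), "too short")
})

test_that("|ddG| is invariant to constant dG shifts", {
  set.seed(23)
  v <- -runif(80, 0, 20)
  f1 <- fluctuation_profile(fake_energy_profile(v), interval = 10)
  f2 <- fluctuation_profile(fake_energy_profile(v - 7.3), interval = 10)
  expect_equal(f1$value, f2$value)
})

test_that("IQR peak calling matches hand quartile arithmetic", {
  # constant profile: IQR 0, threshold equals the constant, strict >
  fpc <- structure(data.frame(pos = 0:39, value = rep(2, 40)),
                   interval = 1L, step = 1L,
                   class = c("FluctuationProfile", "data.frame"))
  pk <- iqr_peaks(fpc)
  expect_identical(nrow(pk$peaks), 0L)
  expect_equal(pk$threshold, 2)
  # toy vector [1 x9, 100]: sorted order stats give Q1 = Q3 = 1, IQR 0
  fp <- structure(data.frame(pos = 0:9, value = c(rep(1, 9), 100)),
                  interval = 1L, step = 1L,
                  class = c("FluctuationProfile", "data.frame"))
  pk2 <- iqr_peaks(fp)
  expect_equal(pk2$q3, 1)
  expect_equal(pk2$iqr, 0)
  expect_identical(pk2$peaks$pos, 9L)
  expect_equal(pk2$peaks$value, 100)
  # scale equivariance: peak positions unchanged under c > 0
  set.seed(31)
  v <- c(runif(60), 9, runif(10))
  mk <- function(vals) structure(
    data.frame(pos = seq_along(vals) - 1L, value = vals),
    interval = 1L, step = 1L,
    class = c("FluctuationProfile", "data.frame"))
  expect_identical(iqr_peaks(mk(v))$peaks$pos,
                   iqr_peaks(mk(3.7 * v))$peaks$pos)
  expect_error(iqr_peaks(mk(numeric(0))), "empty")
})

test_that("peak calling is deterministic and regions get their maxima", {
  set.seed(37)
  cfg <- scaled_cfg(1)
  gen <- generate_gene(cfg)
  ep <- energy_profile(gen$sequence, window_len = 100, step = 10)
  fp <- fluctuation_profile(ep, interval = 3)
  p1 <- iqr_peaks(fp, gen$model)
  p2 <- iqr_peaks(fp, gen$model)
  expect_identical(p1, p2)
  expect_true(all(p1$peaks$value > p1$threshold))
  # per-region max dominates every value assigned to the region
  rg <- gen$model$regions
  idx <- findInterval(fp$pos, rg$transcript_start)
  for (r in seq_len(nrow(rg))) {
    vals <- fp$value[idx == r]
    if (length(vals))
      expect_gte(p1$region_max$max_abs_ddG[r], max(vals))
  }
})

test_that("co-localization windows follow the stated conventions", {
  mk_peaks <- function(pos) {
    fp <- structure(data.frame(pos = c(pos, 0:9),
                               value = c(50, rep(1, 10))),
                    interval = 1L, step = 1L,
                    class = c("FluctuationProfile", "data.frame"))
    iqr_peaks(fp)
  }
  m <- gene_model(data.frame(name = c("exon1", "intron1"),
                             kind = c("exon", "intron"),
                             length = c(1000, 1000)))
  pk <- mk_peaks(1500L)
  # peak inside the hotspot region: true at any flank >= 0
  expect_true(colocalize(pk, "intron1", m, flank = 0)$colocalized)
  expect_equal(colocalize(pk, "intron1", m, flank = 0)$nearest, 0)
  # point hotspot: flank is the total window width (+/- flank/2)
  expect_false(colocalize(mk_peaks(1000L), 1600, flank = 500)$colocalized)
  expect_true(colocalize(mk_peaks(1000L), 1600, flank = 1300)$colocalized)
  # empty peak set
  fp0 <- structure(data.frame(pos = 0:9, value = rep(1, 10)),
                   interval = 1L, step = 1L,
                   class = c("FluctuationProfile", "data.frame"))
  res <- colocalize(iqr_peaks(fp0), 5, flank = 500)
  expect_false(res$colocalized)
  expect_identical(res$distances, numeric(0))
  expect_error(colocalize(iqr_peaks(fp0), "exon9", m), "unknown")
})

test_that("external backends plug into the profile contract", {
  bk <- command_backend("awk 'END{print -3.5}'", name = "stub")
  expect_equal(bk$fold("ACGTACGT"), -3.5)
  ep <- energy_profile(strrep("ACGT", 30), backend = bk,
                       window_len = 40, step = 20)
  expect_true(all(ep$dG == -3.5))
  expect_identical(attr(ep, "backend_name"), "stub")
  tf <- withr::local_tempfile(lines = c("pos\tdG", "0\t-1.5", "1\t-2.5"))
  ep2 <- energy_profile_from_tsv(tf, window_len = 300)
  expect_equal(ep2$dG, c(-1.5, -2.5))
  expect_error(
    command_backend("true")$fold("ACGT"), "did not print")
})
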