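test_that("the packaged 19-region table loads and sums as printed", {
  m <- tfe3_gene_model()
  expect_s3_class(m, "GeneModel")
  expect_equal(nrow(m$regions), 19L)
  # hand sum of the 12 printed upstream lengths:
  # 246+2542+113+1047+303+665+245+83+104+3769+117+352
  expect_identical(total_length(m, tfe3_upstream_regions()), 9586L)
  expect_identical(m$regions$transcript_start[1], 0L)
  expect_identical(diff(m$regions$transcript_start),
                   m$regions$length[-19])
})

test_that("gene model validation catches malformed input", {
  expect_s3_class(gene_model(data.frame(name = "exon1", kind = "exon",
                                        length = 1)),
                  "GeneModel")
  expect_error(gene_model(data.frame(name = c("exon1", "exon1"),
                                     kind = c("exon", "intron"),
                                     length = c(10, 10))),
               "duplicate")
  expect_error(gene_model(data.frame(name = c("exon1", "exon2"),
                                     kind = c("exon", "exon"),
                                     length = c(10, 10))),
               "alternate")
  expect_error(gene_model(data.frame(name = c("intron1", "exon1"),
                                     kind = c("intron", "exon"),
                                     length = c(10, 10))),
               "alternate")
  expect_error(gene_model(data.frame(name = "exon1", kind = "exon",
                                     length = 0)),
               ">= 1")
  expect_error(gene_model(data.frame(name = c("exon1", "intron1"),
                                     kind = c("exon", "intron"),
                                     length = c(10, 5),
                                     genomic_start = c(1, 11),
                                     genomic_end = c(10, 14))),
               "length")
  tf <- withr::local_tempfile(lines = c("name\tkind\tlength",
                                        "exon1\texon\tnot_a_number"))
  expect_error(suppressWarnings(load_gene_model(tf)),
               "malformed region row at line 1")
})

test_that("load -> serialize -> load round-trips, with and without coords", {
  m1 <- tfe3_gene_model()
  tf <- withr::local_tempfile()
  write_gene_model(m1, tf)
  m2 <- load_gene_model(tf, gene_name = "TFE3", assembly = "GRCh37",
                        strand = "-")
  expect_identical(m1, m2)

  ends <- cumsum(c(20L, 35L, 15L))
  m3 <- gene_model(data.frame(name = c("exon1", "intron1", "exon2"),
                              kind = c("exon", "intron", "exon"),
                              length = c(20, 35, 15),
                              genomic_start = c(1L, ends[1] + 1L,
                                                ends[2] + 1L),
                              genomic_end = ends),
                   gene_name = "toy")
  tf2 <- withr::local_tempfile()
  write_gene_model(m3, tf2)
  expect_identical(load_gene_model(tf2, gene_name = "toy"), m3)
})

test_that("composition matches the printed per-region fractions", {
  # intron 5 row: A=1059 C=959 G=864 T=887
  s <- paste0(strrep("A", 1059), strrep("C", 959), strrep("G", 864),
              strrep("T", 887))
  expect_equal(round(composition(s)$gc_fraction, 6), 0.483683)
  # exon 1 row: A=39 C=105 G=69 T=33 (length 246)
  s1 <- paste0(strrep("A", 39), strrep("C", 105), strrep("G", 69),
               strrep("T", 33))
  expect_equal(round(composition(s1)$gc_fraction, 6), 0.707317)
  expect_equal(composition("ATAT")$gc_fraction, 0)
  expect_equal(composition("GCGC")$gc_fraction, 1)
  # every row of the printed table, to 6 decimals
  tb <- tfe3_composition_table()
  for (i in seq_len(nrow(tb))) {
    s <- paste0(strrep("A", tb$n_A[i]), strrep("C", tb$n_C[i]),
                strrep("G", tb$n_G[i]), strrep("T", tb$n_T[i]))
    cs <- composition(s)
    expect_equal(round(cs$gc_fraction, 6), round(tb$gc_fraction[i], 6))
    expect_equal(round(cs$at_fraction, 6), round(tb$at_fraction[i], 6))
    expect_identical(cs$n_A + cs$n_C + cs$n_G + cs$n_T,
                     as.integer(tb$length[i]))
  }
})

test_that("composition rejects bad input and handles ambiguity", {
  expect_error(composition(""), "non-empty")
  expect_error(composition("ACGTX"), "X")
  cs <- composition("ACGTNN")
  expect_identical(cs$n_ambiguous, 2L)
  expect_equal(cs$gc_fraction + cs$at_fraction, 1)
})

test_that("composition is order-invariant", {
  set.seed(11)
  for (rep in 1:5) {
    s <- rand_seq(200, gc = runif(1, 0.2, 0.8))
    sh <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_identical(composition(s), composition(sh))
  }
})

test_that("the 31 packaged breakpoints distribute as published", {
  B <- assign_breakpoints(tfe3_breakpoints(), tfe3_gene_model())
  expect_identical(sum(B), 31L)
  expect_identical(B[["intron5"]], 23L)
  expect_identical(B[["intron4"]], 4L)
  expect_identical(B[["intron1"]], 2L)
  expect_identical(B[["exon4"]], 1L)
  expect_identical(B[["exon5"]], 1L)
  expect_identical(sum(B > 0), 5L)
})

test_that("coordinate assignment follows half-open containment", {
  m <- gene_model(data.frame(name = c("exon1", "intron1"),
                             kind = c("exon", "intron"),
                             length = c(10, 10),
                             genomic_start = c(1L, 11L),
                             genomic_end = c(10L, 20L)))
  bset <- function(coord)
    breakpoint_set(data.frame(sample_id = "s1", genomic_coord = coord,
                              resolution = "base"))
  # first base of intron1 belongs to intron1; last base of exon1 to exon1
  expect_identical(assign_breakpoints(bset(11L), m)[["intron1"]], 1L)
  expect_identical(assign_breakpoints(bset(10L), m)[["exon1"]], 1L)
  expect_identical(assign_breakpoints(bset(1L), m)[["exon1"]], 1L)
  expect_identical(assign_breakpoints(bset(20L), m)[["intron1"]], 1L)
  expect_error(assign_breakpoints(bset(21L), m), "s1")
  # minus strand: transcript order runs from high to low coordinates
  mm <- gene_model(data.frame(name = c("exon1", "intron1"),
                              kind = c("exon", "intron"),
                              length = c(10, 10),
                              genomic_start = c(11L, 1L),
                              genomic_end = c(20L, 10L)),
                   strand = "-")
  expect_identical(assign_breakpoints(bset(20L), mm)[["exon1"]], 1L)
  expect_identical(assign_breakpoints(bset(10L), mm)[["intron1"]], 1L)
})

test_that("breakpoint bookkeeping is conservative and validated", {
  m <- tfe3_gene_model()
  empty <- breakpoint_set(data.frame(sample_id = character(0),
                                     region_name = character(0)))
  expect_identical(sum(assign_breakpoints(empty, m)), 0L)
  bad <- breakpoint_set(data.frame(sample_id = "x",
                                   region_name = "intron99"))
  expect_error(assign_breakpoints(bad, m), "intron99")
  expect_error(breakpoint_set(data.frame(sample_id = "x")),
               "region_name or genomic_coord")
  # conservation on random region-resolution sets
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    bp <- breakpoint_set(data.frame(
      sample_id = paste0("s", seq_len(n)),
      region_name = sample(m$regions$name, n, replace = TRUE)))
    expect_identical(sum(assign_breakpoints(bp, m)), n)
  }
})

test_that("region name normalization accepts the printed spelling", {
  expect_identical(breakscape:::normalize_region_name("intro5"), "intron5")
  expect_identical(breakscape:::normalize_region_name("intron5"), "intron5")
  expect_identical(breakscape:::normalize_region_name("exon5"), "exon5")
})

test_that("FASTA loading reverse-complements minus-strand genes", {
  tf <- withr::local_tempfile(lines = c(">toy", "AACCGGTTACGT"))
  expect_identical(load_gene_sequence(tf), "AACCGGTTACGT")
  expect_identical(load_gene_sequence(tf, strand = "-"), "ACGTAACCGGTT")
  tf2 <- withr::local_tempfile(lines = c(">a", "ACGT", ">b", "ACGT"))
  expect_error(load_gene_sequence(tf2), "single")
})

test_that("region sequences and per-region composition line up", {
  m <- gene_model(data.frame(name = c("exon1", "intron1"),
                             kind = c("exon", "intron"),
                             length = c(4, 6)))
  seqs <- region_sequences("GGCCAATTAA", m)
  expect_identical(unname(seqs), c("GGCC", "AATTAA"))
  tb <- composition_by_region("GGCCAATTAA", m)
  expect_equal(tb$gc_fraction, c(1, 0))
  expect_error(region_sequences("GGCC", m), "does not match")
})
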