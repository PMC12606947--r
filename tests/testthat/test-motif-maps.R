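test_that("motif scanning matches IUPAC semantics and brute force", {
  expect_equal(scan_motif("GGAATAAAGG", "AWUAAA"), 3L)  # 1-based
  expect_equal(scan_motif("GGATTAAAGG", "AWUAAA"), 3L)  # W = A/T
  expect_equal(scan_motif("GGGGGG", "AWUAAA"), integer(0))
  # reverse-complement orientation: AWUAAA -> TTTAWT on the sense strand
  expect_equal(scan_motif("TTTATT", motif_spec("AWUAAA",
                                               "reverse_complement")), 1L)
  expect_equal(scan_motif("UGUAUGUA", "UGUA"), c(1L, 5L))  # RNA input
  # overlapping matches are all reported
  expect_equal(scan_motif("AAAAAA", "AA"), 1:5)

  set.seed(31)
  for (i in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(20:200, 1),
                      replace = TRUE), collapse = "")
    for (pat in c("UGUA", "AWUAAA", "TGWA", "RYN")) {
      expect_equal(scan_motif(s, pat), oracle_scan(s, pat),
                   info = paste(pat, substr(s, 1, 20)))
    }
  }
})

test_that("window frequency gives a plateau of width = window for planted motifs", {
  # motif start at position 50 of every sequence
  seqs <- vapply(1:4, function(i) {
    paste0(strrep("C", 49), "TGTA", strrep("G", 47))
  }, character(1))
  wf <- window_frequency(seqs, motif_spec("UGUA"), offsets = 1:100,
                         window = 10, smooth = 1)
  plateau <- wf$offset[wf$raw == 1]
  expect_length(plateau, 10)  # window width
  # window at offset x spans [x-5, x+5): start 50 is caught for x in 46..55
  expect_equal(range(plateau), c(46, 55))
  expect_true(all(wf$raw[wf$offset < 46 | wf$offset > 55] == 0))

  # fractional frequency: motif in 2 of 4 sequences
  seqs2 <- c(seqs[1:2], strrep("C", 100), strrep("G", 100))
  wf2 <- window_frequency(seqs2, motif_spec("UGUA"), offsets = 1:100,
                          window = 10, smooth = 1)
  expect_equal(wf2$raw[wf2$offset == 50], 0.5)
  # no matches anywhere -> all zero
  wf0 <- window_frequency(c(strrep("C", 60), strrep("G", 60)),
                          motif_spec("UGUA"), window = 10)
  expect_true(all(wf0$raw == 0))
})

test_that("positional hypergeometric test is two-tailed and symmetric", {
  out <- positional_hypergeom(c(5, 8, 0), c(5, 2, 0), 10, 10)
  expect_equal(out$p[1], 1.0)
  expect_equal(out$p[2], oracle_fisher2x2(8, 2, 2, 8), tolerance = 1e-9)
  expect_equal(round(out$p[2], 4), 0.0230)
  # swapping positive and negative sets preserves p, flips sign
  swapped <- positional_hypergeom(c(5, 2, 0), c(5, 8, 0), 10, 10)
  expect_equal(swapped$p, out$p)
  expect_equal(swapped$sign[2], -out$sign[2])
  # empty negative set -> missing p
  none <- positional_hypergeom(c(1, 2), c(0, 0), 10, 0)
  expect_true(all(is.na(none$p)))
})

test_that("GC profile counts G/C fractions and smoothing preserves the mean", {
  all_g <- rep(strrep("G", 30), 3)
  expect_true(all(gc_profile(all_g)$gc == 1))
  gcgc <- rep(strrep("GC", 15), 3)
  atat <- rep(strrep("AT", 15), 3)
  expect_true(all(gc_profile(gcgc, smooth = 1)$raw -
                    gc_profile(atat, smooth = 1)$raw == 1))
  # a full-width centered window reproduces the overall mean at the center
  set.seed(8)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 41, replace = TRUE),
          collapse = ""), character(1))
  prof <- gc_profile(seqs, smooth = 41)
  raw <- gc_profile(seqs, smooth = 1)$raw
  expect_equal(prof$gc[21], mean(raw))
  # and an interior window is the plain mean of its span
  prof5 <- gc_profile(seqs, smooth = 5)
  expect_equal(prof5$gc[10], mean(raw[8:12]))
  # ambiguous bases drop out of numerator and denominator
  amb <- gc_profile(c("GN", "GN"), smooth = 1)
  expect_equal(amb$raw, c(1, NA_real_))
})

test_that("linker measurement counts intervening nucleotides", {
  # UGUA at BED [10,14), hexamer AATAAA at BED [64,70): linker 50
  seq <- paste0(strrep("C", 10), "TGTA", strrep("C", 50), "AATAAA",
                strrep("C", 50), strrep("G", 30))
  genome <- tiny_genome(c(chr = seq))
  pas <- gr("chr", 80L, 80L, "+")
  out <- motif_distance_distribution(pas, NULL, genome,
                                     search_radius = 79)
  expect_equal(out$linkers, 50L)
  # no UGUA within radius -> PAS skipped
  seq2 <- paste0(strrep("C", 64), "AATAAA", strrep("C", 80))
  out2 <- motif_distance_distribution(gr("chr", 80L, 80L, "+"), NULL,
                                      tiny_genome(c(chr = seq2)),
                                      search_radius = 79)
  expect_length(out2$linkers, 0L)
})

test_that("binding filter keeps only PAS with a proximal peak", {
  seq <- paste0(strrep("C", 10), "TGTA", strrep("C", 50), "AATAAA",
                strrep("C", 120))
  genome <- tiny_genome(c(chr = seq))
  pas <- gr("chr", c(80L, 150L), c(80L, 150L), "+")
  peaks <- gr("chr", 70L, 90L, "+")  # near the first PAS only
  out <- motif_distance_distribution(pas, peaks, genome,
                                     search_radius = 79,
                                     binding_radius = 30)
  expect_equal(out$linkers, 50L)  # second PAS had no proximal binding
})

test_that("planted linkers are recovered from the simulated genome", {
  cfg <- sim_config(n_genes = 60, fraction_lengthened = 0.5,
                    fraction_shortened = 0, seed = 13)
  sim <- simulate_genome(cfg)
  pas <- sim$truth$pas
  lab <- setNames(sim$truth$genes$label, sim$truth$genes$gene_id)
  mk_gr <- function(rows) gr(rows$chrom, rows$genomic_pos,
                             rows$genomic_pos, rows$strand)
  reg <- pas[pas$pas_index == 2 & lab[pas$gene_id] == "lengthened_by_RBP", ]
  ctl <- pas[pas$pas_index == 2 & lab[pas$gene_id] == "non_changing", ]
  d_reg <- motif_distance_distribution(mk_gr(reg), NULL, sim$genome)
  d_ctl <- motif_distance_distribution(mk_gr(ctl), NULL, sim$genome)
  expect_equal(median(d_reg$linkers), cfg$linker_regulated)
  expect_equal(median(d_ctl$linkers), cfg$linker_default)
  # a CDF of an all-identical linker set is a step at the planted value
  expect_equal(d_ctl$ecdf(cfg$linker_default - 1), 0)
  expect_equal(d_ctl$ecdf(cfg$linker_default),
               mean(d_ctl$linkers == cfg$linker_default))
})
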