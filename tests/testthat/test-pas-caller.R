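test_that("cluster calling merges runs above the per-position threshold", {
  counts <- setNames(c(5, 12, 15, 20, 11, 9, 13, 14, 11, 0, 30), 100:110)
  cl <- call_clusters(cov_track(counts))
  expect_equal(GenomicRanges::start(cl), c(101L, 106L, 110L))
  expect_equal(GenomicRanges::end(cl), c(104L, 108L, 110L))
  expect_equal(cl$total, c(58, 38, 30))

  expect_length(call_clusters(cov_track(setNames(rep(10, 20), 1:20))), 0L)
  one <- call_clusters(cov_track(c(`500` = 30)))
  expect_equal(GenomicRanges::width(one), 1L)
  expect_equal(one$total, 30)

  # min_total drops or flags
  low <- cov_track(c(`10` = 11, `11` = 5))
  expect_length(call_clusters(low), 0L)
  kept <- call_clusters(low, keep_filtered = TRUE)
  expect_equal(kept$flags, "fail_low_total")
})

test_that("cluster caller and PAS assignment match a brute-force scan", {
  set.seed(101)
  for (rep in 1:40) {
    L <- sample(50:1000, 1)
    counts <- rpois(L, lambda = sample(c(2, 8, 15), 1))
    names(counts) <- seq_len(L) + 1000L
    strand <- sample(c("+", "-"), 1)
    track <- cov_track(counts, strand = strand)
    cl <- assign_pas(call_clusters(track), track)
    oc <- oracle_clusters(counts)
    if (is.null(oc)) {
      expect_length(cl, 0L)
      next
    }
    expect_equal(GenomicRanges::start(cl), oc$start)
    expect_equal(GenomicRanges::end(cl), oc$end)
    expect_equal(cl$total, oc$total)
    expect_equal(cl$pas,
                 mapply(oracle_pas, oc$start, oc$end,
                        MoreArgs = list(counts_by_pos = counts,
                                        strand = strand)))
  }
})

test_that("PAS ties resolve to the 3'-most position per strand", {
  track_p <- cov_track(c(`200` = 15, `201` = 15))
  cl <- assign_pas(call_clusters(track_p), track_p)
  expect_equal(cl$pas, 201L)
  track_m <- cov_track(c(`200` = 15, `201` = 15), strand = "-")
  cl <- assign_pas(call_clusters(track_m), track_m)
  expect_equal(cl$pas, 200L)
  track_a <- cov_track(c(`101` = 12, `102` = 15, `103` = 20, `104` = 11))
  cl <- assign_pas(call_clusters(track_a), track_a)
  expect_equal(cl$pas, 103L)
})

test_that("internal-priming filters follow the A-run and A-window rules", {
  mk <- function(downstream, strand = "+") {
    # cluster at positions 11..13 with PAS at 13 (plus) or 11 (minus)
    if (strand == "+") {
      genome <- tiny_genome(c(chr = paste0(strrep("G", 13), downstream,
                                           strrep("G", 20))))
      cl <- gr("chr", 11L, 13L, "+", total = 100, flags = "", pas = 13L)
    } else {
      genome <- tiny_genome(c(chr = paste0(strrep("G", 20),
                                           revcomp_chr(downstream),
                                           strrep("G", 13))))
      n <- 20 + nchar(downstream)
      cl <- gr("chr", n + 1L, n + 3L, "-", total = 100, flags = "",
               pas = n + 1L)
    }
    filter_internal_priming(cl, genome)$flags
  }
  # 7 consecutive A directly after the PAS (also the cluster end here)
  expect_match(mk("AAAAAAAGCC"), "fail_consecutive_A")
  # 6 consecutive A passes that rule, but 9 A in the 10-nt window fails
  f <- mk("AAAAAAGAAA")
  expect_false(grepl("fail_consecutive_A", f))
  expect_match(f, "fail_A_rich_window")
  expect_equal(mk("GCGCGCGCGC"), "")
  # strand-aware: same transcript-sense sequences on the minus strand
  expect_match(mk("AAAAAAAGCC", "-"), "fail_consecutive_A")
  expect_equal(mk("GCGCGCGCGC", "-"), "")
})

test_that("hexamer filter searches the sense-strand cluster sequence", {
  genome <- tiny_genome(c(chr = paste0("GGGG", "AATAAA", "GG",
                                       "ATTAAA", "GGGG",
                                       "AAGAAA", "GGGG")))
  ok1 <- gr("chr", 5L, 10L, "+", total = 1, flags = "")
  ok2 <- gr("chr", 13L, 18L, "+", total = 1, flags = "")
  bad <- gr("chr", 23L, 28L, "+", total = 1, flags = "")
  expect_equal(filter_hexamer(ok1, genome)$flags, "")
  expect_equal(filter_hexamer(ok2, genome)$flags, "")
  expect_equal(filter_hexamer(bad, genome)$flags, "fail_no_hexamer")
  # minus strand: AATAAA in transcript sense = TTTATT on the plus strand
  genome_m <- tiny_genome(c(chr = "GGGGTTTATTGGGG"))
  cl_m <- gr("chr", 5L, 10L, "-", total = 1, flags = "")
  expect_equal(filter_hexamer(cl_m, genome_m)$flags, "")
  # upstream flank extends the search on the transcript 5' side
  genome_f <- tiny_genome(c(chr = paste0("G", "AATAAA", strrep("G", 20))))
  cl_f <- gr("chr", 10L, 12L, "+", total = 1, flags = "")
  expect_equal(filter_hexamer(cl_f, genome_f)$flags, "fail_no_hexamer")
  expect_equal(filter_hexamer(cl_f, genome_f, flank_upstream = 8)$flags, "")
})

test_that("reference filter honors strand and slack", {
  ref <- gr("chr", 105L, 105L, "+")
  cl <- gr("chr", 100L, 110L, "+", total = 1, flags = "")
  expect_equal(filter_reference(cl, ref)$flags, "")
  far <- gr("chr", 200L, 210L, "+", total = 1, flags = "")
  expect_equal(filter_reference(far, ref)$flags, "fail_not_in_reference")
  near <- gr("chr", 110L, 120L, "+", total = 1, flags = "")
  expect_equal(filter_reference(near, ref)$flags, "fail_not_in_reference")
  expect_equal(filter_reference(near, ref, slack = 10)$flags, "")
  wrong_strand <- gr("chr", 100L, 110L, "-", total = 1, flags = "")
  expect_equal(filter_reference(wrong_strand, ref)$flags,
               "fail_not_in_reference")
})

test_that("terminal-exon assignment uses the PAS position and nearest 3' end", {
  exons <- gr("chr", c(100L, 150L), c(200L, 400L), "+",
              gene_id = c("G1", "G2"))
  cl <- gr("chr", rep(160L, 3), rep(170L, 3), "+",
           total = rep(1, 3), flags = rep("", 3))
  cl$pas <- c(165L, 50L, 165L)
  cl <- cl[1:2]
  out <- assign_terminal_exon(cl, exons)
  # PAS 165 in both exons: G1's 3' end (200) is nearer downstream than 400
  expect_equal(out$terminal_exon_id[1], "G1")
  expect_true(is.na(out$terminal_exon_id[2]))  # intergenic PAS
  # cluster interval overlapping an exon does not count if the PAS is out
  cl3 <- gr("chr", 195L, 215L, "+", total = 1, flags = "")
  cl3$pas <- 210L
  expect_equal(assign_terminal_exon(cl3, exons)$terminal_exon_id, "G2")
})

test_that("relative usage sums to one per exon-sample; zero totals go missing", {
  cl <- gr("chr", c(100L, 300L, 500L), c(110L, 310L, 510L), "+",
           total = c(30, 70, 10), flags = rep("", 3))
  cl$pas <- c(105L, 305L, 505L)
  cl$terminal_exon_id <- c("G1", "G1", "G2")
  counts <- matrix(c(30, 70, 10,
                     0, 0, 5), ncol = 2,
                   dimnames = list(NULL, c("s1", "s2")))
  usage <- compute_relative_usage(cl, counts)
  expect_equal(usage$s1[1:2], c(0.30, 0.70))
  expect_equal(usage$s1[3], 1.0)
  expect_true(all(is.na(usage$s2[1:2])))  # exon total 0 -> missing, not 0
  expect_equal(usage$s2[3], 1.0)
  # conservation where defined
  sums <- tapply(usage$s1, usage$terminal_exon_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("planted decoys are all flagged and compliant true PAS never are", {
  cfg <- sim_config(n_genes = 40, decoy_fraction = 0.5, seed = 5)
  sim <- simulate_genome(cfg)
  reads <- simulate_three_prime_reads(cfg, sim)
  res <- call_pas_clusters(reads, sim$genome, sim$exons,
                           sim$pas_reference, hexamer_flank = 30)
  cl <- res$clusters
  is_decoy <- vapply(seq_along(cl), function(i) {
    any(sim$truth$decoys$strand ==
          as.character(GenomicRanges::strand(cl))[i] &
          abs(sim$truth$decoys$genomic_pos - cl$pas[i]) <= 5)
  }, logical(1))
  ip_flag <- grepl("fail_consecutive_A|fail_A_rich_window", cl$flags)
  expect_true(all(ip_flag[is_decoy]))   # 100% of decoys flagged
  expect_false(any(ip_flag[!is_decoy])) # 0% of true PAS flagged
  # and every true PAS survives the full funnel
  expect_equal(length(res$clean), 2L * cfg$n_genes)
})
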