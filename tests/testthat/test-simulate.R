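small_cfg <- function(..., seed = 11) {
  sim_config(n_genes = 24, fraction_lengthened = 0.25,
             fraction_shortened = 0.25, seed = seed, ...)
}

test_that("generators are byte-identical under a fixed seed", {
  s1 <- simulate_apa_experiment(small_cfg())
  s2 <- simulate_apa_experiment(small_cfg())
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$reads, s2$reads)
  expect_identical(as.data.frame(s1$peaks), as.data.frame(s2$peaks))
  expect_identical(s1$dms, s2$dms)
  expect_identical(s1$dpdui, s2$dpdui)
  s3 <- simulate_genome(small_cfg(seed = 12))
  expect_false(identical(as.character(s3$genome),
                         as.character(s1$genome)))
})

# genomic range covering `w` nt upstream of a truth-PAS row
genomic_pos_range <- function(row, w) {
  if (row$strand == "+") (row$genomic_pos - w):row$genomic_pos
  else row$genomic_pos:(row$genomic_pos + w)
}

test_that("planted exon geometry: distinct pPAS 5' of dPAS, elements present", {
  sim <- simulate_genome(small_cfg())
  pas <- sim$truth$pas
  for (g in unique(pas$gene_id)) {
    rows <- pas[pas$gene_id == g, ]
    expect_equal(nrow(rows), 2L)
    # transcript order: pPAS strictly 5' of dPAS
    expect_true(rows$transcript_pos[1] < rows$transcript_pos[2])
    # hexamer ends 10-20 nt upstream of cleavage
    expect_true(all(rows$hexamer_gap >= 10 & rows$hexamer_gap <= 20))
    # the planted hexamer and UGUA are really in the genome at the
    # planted spacing
    for (i in seq_len(nrow(rows))) {
      up <- fetch_sequence(sim$genome, rows$chrom[i],
                           min(genomic_pos_range(rows[i, ], 200)),
                           max(genomic_pos_range(rows[i, ], 200)),
                           rows$strand[i])
      expect_true(grepl("AATAAA", up, fixed = TRUE))
      expect_true(grepl("TGTA", up, fixed = TRUE))
    }
  }
  # reference list contains exactly the true PAS positions
  expect_setequal(GenomicRanges::start(sim$pas_reference), pas$genomic_pos)
})

test_that("decoy planting: A-runs only where decoys are planted", {
  sim0 <- simulate_genome(small_cfg(decoy_fraction = 0))
  expect_false(grepl("AAAAAAA", as.character(sim0$genome[[1]])))
  expect_equal(nrow(sim0$truth$decoys), 0L)

  sim1 <- simulate_genome(small_cfg(decoy_fraction = 1))
  expect_equal(nrow(sim1$truth$decoys), 24L)
  gseq <- as.character(sim1$genome[[1]])
  for (i in seq_len(nrow(sim1$truth$decoys))) {
    d <- sim1$truth$decoys[i, ]
    run <- if (d$strand == "+") {
      substr(gseq, d$genomic_pos + 1, d$genomic_pos + 10)
    } else {
      revcomp_chr(substr(gseq, d$genomic_pos - 10, d$genomic_pos - 1))
    }
    expect_equal(run, strrep("A", 10))
  }
})

test_that("read counts conserve the drawn totals and planted usage shift", {
  cfg <- small_cfg(reads_per_exon_mean = 500, decoy_fraction = 0)
  sim <- simulate_genome(cfg)
  reads <- simulate_three_prime_reads(cfg, sim)
  expect_length(reads, 2 * 3 * 3)  # condition x fraction x replicate

  # empirical distal usage shift of lengthened genes near shift_magnitude
  pas <- sim$truth$pas
  usage_at <- function(track, gene) {
    rows <- pas[pas$gene_id == gene, ]
    cnt <- vapply(seq_len(nrow(rows)), function(j) {
      sel <- track$strand == rows$strand[j] &
        abs(track$pos - rows$genomic_pos[j]) <= 5
      sum(track$count[sel])
    }, numeric(1))
    cnt[2] / sum(cnt)
  }
  lengthened <- sim$truth$genes$gene_id[sim$truth$genes$label ==
                                          "lengthened_by_RBP"]
  d_ctrl <- vapply(lengthened, usage_at,
                   track = reads[["control_whole_rep1"]], numeric(1))
  d_kd <- vapply(lengthened, usage_at,
                 track = reads[["kd_whole_rep1"]], numeric(1))
  shift <- mean(d_ctrl - d_kd)
  se <- sd(d_ctrl - d_kd) / sqrt(length(lengthened))
  expect_lt(abs(shift - cfg$shift_magnitude), 3 * se + 0.02)

  # zero depth gives empty tracks
  cfg0 <- small_cfg(reads_per_exon_mean = 0, decoy_fraction = 0)
  sim0 <- simulate_genome(cfg0)
  reads0 <- simulate_three_prime_reads(cfg0, sim0)
  expect_true(all(vapply(reads0, nrow, integer(1)) == 0L))
})

test_that("regulator peaks concentrate at the planted offset; background is flat", {
  cfg <- sim_config(n_genes = 100, fraction_lengthened = 0.5,
                    fraction_shortened = 0, clip_enrichment_sd = 0.01,
                    seed = 3)
  sim <- simulate_genome(cfg)
  peaks <- simulate_clip_peaks(cfg, sim)
  reg <- peaks[peaks$rbp_id == "RBP_regulator" & peaks$replicate == "rep1"]
  pas <- sim$truth$pas
  lab <- setNames(sim$truth$genes$label, sim$truth$genes$gene_id)
  dpas <- pas[pas$pas_index == 2 & lab[pas$gene_id] == "lengthened_by_RBP", ]
  # with sd ~ 0, every planted peak center sits at the configured offset
  centers <- (GenomicRanges::start(reg) + GenomicRanges::end(reg)) / 2
  planted <- vapply(seq_len(nrow(dpas)), function(i) {
    offs <- transcript_offset(centers, dpas$genomic_pos[i], dpas$strand[i])
    any(abs(offs - cfg$clip_enrichment_center) <= 1)
  }, logical(1))
  expect_true(all(planted))

  # background RBP: offsets from dPAS show no mode around the planted
  # offset beyond binomial fluctuation
  bg <- peaks[peaks$rbp_id == "RBP_background"]
  bg_centers <- (GenomicRanges::start(bg) + GenomicRanges::end(bg)) / 2
  all_dpas <- pas[pas$pas_index == 2, ]
  hits <- 0L
  for (i in seq_len(nrow(all_dpas))) {
    offs <- transcript_offset(bg_centers, all_dpas$genomic_pos[i],
                              all_dpas$strand[i])
    hits <- hits + sum(abs(offs - cfg$clip_enrichment_center) <= 25)
  }
  # each of 200 uniform peaks lands in the 51-nt window around -50 of its
  # own gene's dPAS with p ~ 51/2000; across genes expected ~5
  p_win <- 51 / cfg$utr_length
  n_bg <- length(bg)
  expect_lt(hits, n_bg * p_win + 4 * sqrt(n_bg * p_win) + 3)
})

test_that("DMS rates are bounded, zero when planted rate is zero", {
  cfg <- small_cfg(dms_structured_rate = 0)
  sim <- simulate_genome(cfg)
  dms <- simulate_dms(cfg, sim)
  expect_true(all(dms$rate >= 0 & dms$rate <= 1))
  expect_true(all(dms$base %in% c("A", "C")))
  # structured motif adenosines have rate exactly 0
  pas <- sim$truth$pas
  st <- pas[pas$structured & pas$pas_index == 2, ]
  for (i in seq_len(nrow(st))) {
    hex_lo_t <- st$transcript_pos[i] - st$hexamer_gap[i] - 6
    offs <- (hex_lo_t:(hex_lo_t + 5)) - st$transcript_pos[i]
    gpos <- genomic_position(offs, st$genomic_pos[i], st$strand[i])
    sel <- dms$pos %in% gpos & dms$strand == st$strand[i] & dms$base == "A"
    expect_true(all(dms$rate[sel] == 0))
  }
})

test_that("dPDUI table equals the planted shift when noise is zero", {
  cfg <- small_cfg(dpdui_noise_sd = 0)
  sim <- simulate_genome(cfg)
  ed <- simulate_expression_and_dpdui(cfg, sim)
  lab <- sim$truth$genes$label
  reg <- lab != "non_changing"
  expect_equal(abs(ed$dpdui$dPDUI[reg]),
               rep(cfg$shift_magnitude, sum(reg)))
  expect_true(all(abs(ed$dpdui$dPDUI[!reg]) < 1e-9))
  expect_true(all(ed$dpdui$adjusted_p[reg] < 0.05))
  # expressed transcripts have median control TPM >= 1 except the planted
  # low-expression subset
  med <- apply(ed$expression$tpm, 1, median)
  expect_gt(mean(med >= 1), 0.7)
})
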