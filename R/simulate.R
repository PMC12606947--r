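## Synthetic 3' end sequencing / eCLIP / DMS experiment with planted ground
## truth. The generator emulates the statistical structure the analysis
## assumes: multinomial PAS usage with planted knockdown shifts, read 3' end
## jitter giving clusters width, A-rich internal-priming decoys, positionally
## enriched regulator peaks, planted UGUA-to-hexamer linkers, and
## low-accessibility "structured" motifs.

#' Configuration for the synthetic APA experiment
#'
#' Defaults describe the study conditions the rest of the package is tested
#' under: 200 terminal exons with 2 PAS each, 50 regulated (25 lengthened +
#' 25 shortened) with a usage shift of 0.30, triplicate knockdown/control
#' pairs in whole-cell, nuclear, and cytoplasmic fractions at ~300 reads per
#' exon, 20% of exons carrying an A-rich internal-priming decoy, regulator
#' CLIP peaks centered 50 nt upstream of the distal PAS (sd 15 nt), planted
#' UGUA-to-hexamer linkers of 120 nt (regulated distal PAS) versus 50 nt
#' (all others), and DMS mutation rates of 0.01 (structured motifs) versus
#' 0.10 (open).
#'
#' @param n_genes Number of terminal exons.
#' @param pas_per_exon PAS per terminal exon (>= 2).
#' @param fraction_lengthened,fraction_shortened Fractions of genes whose
#'   3'UTRs the regulator lengthens / shortens (knockdown shifts usage
#'   toward the proximal / distal PAS respectively).
#' @param shift_magnitude Usage shift (fraction) planted in regulated genes.
#' @param reads_per_exon_mean Poisson mean of 3' end reads per exon and
#'   sample.
#' @param n_replicates Replicate pairs per condition.
#' @param fractions Cellular fractions profiled.
#' @param decoy_fraction Fraction of exons carrying a genomic A-run decoy.
#' @param decoy_reads_mean Poisson mean of decoy reads per sample.
#' @param decoy_sample_fraction Fraction of samples in which a decoy
#'   receives reads.
#' @param clip_enrichment_center Planted regulator peak-center offset from
#'   the distal PAS (nt, transcript orientation; negative = upstream).
#' @param clip_enrichment_sd SD (nt) of the planted peak-center offset.
#' @param clip_peak_width Width (nt) of simulated peaks.
#' @param clip_background_rate Expected background peaks per exon.
#' @param linker_regulated,linker_default Planted UGUA-to-hexamer linker
#'   lengths (nt) for regulated-lengthened distal PAS and all other PAS.
#' @param dms_structured_rate,dms_open_rate Mean DMS mutation rates for
#'   structured versus open motif adenosines.
#' @param dms_coverage_mean Poisson mean DMS coverage per position.
#' @param dpdui_noise_sd SD of Gaussian noise added to the simulated dPDUI
#'   table.
#' @param fraction_unexpressed Fraction of (non-changing) genes simulated
#'   below the expression threshold.
#' @param cytoplasm_only_shift If \code{TRUE}, plant usage shifts in the
#'   cytoplasmic fraction only (nuclear keeps control usage in knockdown),
#'   exercising the compartment comparison; by default both compartments
#'   share usage vectors (PAS choice happens in the nucleus).
#' @param utr_length Terminal-exon length (nt); must be >= 1000 *
#'   \code{pas_per_exon}.
#' @param spacer Intergenic spacer (nt).
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_genes = 200,
                       pas_per_exon = 2,
                       fraction_lengthened = 0.125,
                       fraction_shortened = 0.125,
                       shift_magnitude = 0.30,
                       reads_per_exon_mean = 300,
                       n_replicates = 3,
                       fractions = c("whole", "nuclear", "cytoplasmic"),
                       decoy_fraction = 0.2,
                       decoy_reads_mean = 10,
                       decoy_sample_fraction = 1.0,
                       clip_enrichment_center = -50,
                       clip_enrichment_sd = 15,
                       clip_peak_width = 30,
                       clip_background_rate = 0.3,
                       linker_regulated = 120,
                       linker_default = 50,
                       dms_structured_rate = 0.01,
                       dms_open_rate = 0.10,
                       dms_coverage_mean = 200,
                       dpdui_noise_sd = 0.02,
                       fraction_unexpressed = 0.1,
                       cytoplasm_only_shift = FALSE,
                       utr_length = 2000,
                       spacer = 600,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(pas_per_exon >= 2,
            fraction_lengthened >= 0, fraction_shortened >= 0,
            fraction_lengthened + fraction_shortened <= 1,
            shift_magnitude > 0, shift_magnitude < 1,
            decoy_fraction >= 0, decoy_fraction <= 1)
  if (utr_length < 1000 * pas_per_exon) {
    stop("terminal exon too short for ", pas_per_exon,
         " PAS with planted elements: need utr_length >= ",
         1000 * pas_per_exon)
  }
  class(cfg) <- "sim_config"
  cfg
}

## beta draw with fixed mean in [0,1]; mean 0 or 1 degenerates exactly
rbeta_mean <- function(n, m, k = 30) {
  if (m <= 0) return(rep(0, n))
  if (m >= 1) return(rep(1, n))
  rbeta(n, m * k, (1 - m) * k)
}

#' Simulate the genome, terminal-exon annotation, and reference PAS list
#'
#' Each terminal exon carries \code{pas_per_exon} true PAS; each PAS has a
#' sense-strand AATAAA hexamer ending 10-20 nt upstream of the cleavage
#' position and a TGTA (UGUA) element whose end lies exactly the planted
#' linker length upstream of the hexamer start. The 20 nt directly
#' downstream of every true cleavage site are A-free, so compliant true PAS
#' never trip the internal-priming filters. Decoy exons additionally carry
#' a 10-nt genomic A-run at a non-PAS position. Background A-runs of 6+ nt
#' are broken. Genes alternate strands.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list: \code{genome} (DNAStringSet), \code{exons} (GRanges with
#'   \code{gene_id}, \code{cds_end}), \code{pas_reference} (width-1 GRanges
#'   of the true cleavage positions), and \code{truth} (a \code{sim_truth}
#'   list; see Details).
#' @details \code{truth} carries \code{genes} (gene_id, label, strand,
#'   decoy flag), \code{pas} (per-PAS genomic/transcript positions, planted
#'   hexamer gap, linker, structured label), \code{usage_control} /
#'   \code{usage_kd} (per-gene usage vectors over PAS), and \code{decoys}
#'   (genomic decoy positions).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  k <- config$pas_per_exon
  L <- config$utr_length
  n <- config$n_genes
  n_len <- round(n * config$fraction_lengthened)
  n_sho <- round(n * config$fraction_shortened)
  label <- rep("non_changing", n)
  if (n_len > 0) label[seq_len(n_len)] <- "lengthened_by_RBP"
  if (n_sho > 0) label[n_len + seq_len(n_sho)] <- "shortened_by_RBP"
  gene_id <- sprintf("g%04d", seq_len(n))
  strand <- rep(c("+", "-"), length.out = n)
  decoy <- runif(n) < config$decoy_fraction

  exon_start <- config$spacer + (seq_len(n) - 1L) * (L + config$spacer) + 1L
  exon_end <- exon_start + L - 1L
  chrom_len <- max(exon_end) + config$spacer

  ## transcript-offset layout (0-based from exon 5' end)
  pas_t <- 900 + (seq_len(k) - 1L) * 1000   # cleavage offsets
  hex_gap <- matrix(sample(10:20, n * k, replace = TRUE), n, k)

  ## usage vectors: distal = last PAS
  base_prox <- runif(n, 0.25, 0.75)
  base_prox[label == "lengthened_by_RBP"] <- 1 - (0.35 + config$shift_magnitude)
  base_prox[label == "shortened_by_RBP"] <- 1 - 0.35
  usage_from_prox <- function(prox_total) {
    u <- matrix(0, n, k)
    u[, k] <- 1 - prox_total
    u[, seq_len(k - 1L)] <- prox_total / (k - 1L)
    u
  }
  usage_control <- usage_from_prox(base_prox)
  kd_prox <- base_prox
  kd_prox[label == "lengthened_by_RBP"] <-
    base_prox[label == "lengthened_by_RBP"] + config$shift_magnitude
  kd_prox[label == "shortened_by_RBP"] <-
    base_prox[label == "shortened_by_RBP"] - config$shift_magnitude
  usage_kd <- usage_from_prox(kd_prox)

  ## background sequence with A-runs >= 6 broken
  seq_chars <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  is_a <- seq_chars == "A"
  run <- rle(is_a)
  long <- which(run$values & run$lengths >= 6L)
  if (length(long)) {
    ends <- cumsum(run$lengths)
    for (i in long) {
      s <- ends[i] - run$lengths[i] + 1L
      brk <- seq(s + 5L, ends[i], by = 6L)
      seq_chars[brk] <- "C"
    }
  }

  plant <- function(gpos_range, sense_seq, strand) {
    ## write sense_seq (transcript sense) into genome at 1-based range
    chars <- strsplit(sense_seq, "")[[1]]
    if (strand == "-") {
      chars <- rev(chartr("ACGT", "TGCA", chars))
    }
    seq_chars[gpos_range] <<- chars
  }

  pas_rows <- list()
  decoy_rows <- list()
  linker <- matrix(config$linker_default, n, k)
  linker[label == "lengthened_by_RBP", k] <- config$linker_regulated
  structured <- matrix(FALSE, n, k)
  structured[label == "lengthened_by_RBP", k] <- TRUE

  for (i in seq_len(n)) {
    map <- function(t) genomic_position(t, anchor = if (strand[i] == "+")
      exon_start[i] else exon_end[i], strand = strand[i])
    for (j in seq_len(k)) {
      t_pas <- pas_t[j]
      g <- hex_gap[i, j]
      hex_lo <- t_pas - g - 6L        # hexamer transcript offsets [hex_lo, hex_lo+5]
      ugua_lo <- hex_lo - linker[i, j] - 4L
      down <- paste(sample(c("C", "G", "T"), 20, replace = TRUE),
                    collapse = "")
      ## C-flanked elements so planted hexamers never seed genomic A-runs
      plant_span <- function(t_lo, sense_seq) {
        r <- sort(map(c(t_lo, t_lo + nchar(sense_seq) - 1L)))
        plant(r[1]:r[2], sense_seq, strand[i])
      }
      plant_span(hex_lo - 1L, "CAATAAAC")
      plant_span(ugua_lo, "TGTA")
      plant_span(t_pas + 1L, down)
      ## keep the planted linker unambiguous: break stray UGUA between
      ## the planted UGUA and the cleavage site
      region_t <- (ugua_lo + 4L):(t_pas - 1L)
      gpos <- map(region_t)
      chars <- seq_chars[gpos]
      if (strand[i] == "-") chars <- chartr("ACGT", "TGCA", chars)
      m <- gregexpr("TGTA", paste(chars, collapse = ""), fixed = TRUE)[[1]]
      if (m[1L] != -1L) {
        for (mm in m) {
          cand <- region_t[mm]:(region_t[mm] + 3L)
          cand <- cand[!cand %in% ((hex_lo - 1L):(hex_lo + 6L))]
          gp <- map(cand[1L])
          seq_chars[gp] <- if (strand[i] == "+") "C" else "G"
        }
      }
      ## keep the cluster footprint itself A-run free but untouched otherwise
      pas_rows[[length(pas_rows) + 1L]] <- data.frame(
        gene_id = gene_id[i], pas_index = j,
        transcript_pos = t_pas, genomic_pos = map(t_pas),
        chrom = "chrS", strand = strand[i],
        hexamer_gap = g, linker = linker[i, j],
        structured = structured[i, j]
      )
    }
    if (decoy[i]) {
      t_dec <- pas_t[1L] + 500L
      run_range <- sort(map(c(t_dec + 1L, t_dec + 10L)))
      plant(run_range[1]:run_range[2], strrep("A", 10), strand[i])
      decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
        gene_id = gene_id[i], transcript_pos = t_dec,
        genomic_pos = map(t_dec), chrom = "chrS", strand = strand[i]
      )
    }
  }

  genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(genome) <- "chrS"

  exons <- GenomicRanges::GRanges("chrS",
                                  IRanges::IRanges(exon_start, exon_end),
                                  strand = strand)
  exons$gene_id <- gene_id
  exons$cds_end <- ifelse(strand == "+", exon_start + 100L, exon_end - 100L)

  pas_df <- do.call(rbind, pas_rows)
  pas_reference <- GenomicRanges::GRanges(
    pas_df$chrom, IRanges::IRanges(pas_df$genomic_pos, pas_df$genomic_pos),
    strand = pas_df$strand
  )
  pas_reference$name <- paste0(pas_df$gene_id, ":", pas_df$pas_index)
  pas_reference$score <- 0

  truth <- list(
    genes = data.frame(gene_id = gene_id, label = label, strand = strand,
                       decoy = decoy),
    pas = pas_df,
    usage_control = usage_control,
    usage_kd = usage_kd,
    decoys = if (length(decoy_rows)) do.call(rbind, decoy_rows) else
      data.frame(gene_id = character(), transcript_pos = integer(),
                 genomic_pos = integer(), chrom = character(),
                 strand = character())
  )
  class(truth) <- "sim_truth"

  list(genome = genome, exons = exons, pas_reference = pas_reference,
       truth = truth)
}

## sample names in fixed order
sim_sample_grid <- function(config) {
  g <- expand.grid(rep = seq_len(config$n_replicates),
                   fraction = config$fractions,
                   condition = c("control", "kd"),
                   stringsAsFactors = FALSE)
  g$sample_id <- with(g, paste(condition, fraction, paste0("rep", rep),
                               sep = "_"))
  g
}

#' Simulate per-sample 3' end read coverage
#'
#' Per exon and sample, the total read count is Poisson with mean
#' \code{reads_per_exon_mean}; reads distribute multinomially over the
#' exon's PAS using the condition's usage vector, and each read 3' end is
#' jittered uniformly within +/- 5 nt of the true cleavage site so clusters
#' have width. Decoy positions receive reads (jitter +/- 2 nt) in a
#' configurable fraction of samples.
#'
#' @param config A \code{\link{sim_config}}.
#' @param sim Output of \code{\link{simulate_genome}}.
#' @return Named list of coverage tracks (one per sample), ordered
#'   control-then-knockdown, fraction, replicate.
#' @export
simulate_three_prime_reads <- function(config, sim) {
  set.seed(config$seed + 1L)
  truth <- sim$truth
  grid <- sim_sample_grid(config)
  k <- config$pas_per_exon
  exons <- sim$exons
  n <- length(exons)
  pas_pos <- matrix(truth$pas$genomic_pos, n, k, byrow = TRUE)
  strand <- truth$genes$strand

  tracks <- vector("list", nrow(grid))
  names(tracks) <- grid$sample_id
  for (s in seq_len(nrow(grid))) {
    cond <- grid$condition[s]
    frac <- grid$fraction[s]
    usage <- if (cond == "control") truth$usage_control else {
      if (config$cytoplasm_only_shift && frac != "cytoplasmic")
        truth$usage_control else truth$usage_kd
    }
    pos_parts <- list()
    strand_parts <- list()
    for (i in seq_len(n)) {
      total <- rpois(1L, config$reads_per_exon_mean)
      if (total == 0L) next
      counts <- as.integer(rmultinom(1L, total, usage[i, ]))
      for (j in seq_len(k)) {
        if (counts[j] == 0L) next
        jit <- sample(-5:5, counts[j], replace = TRUE)
        pos_parts[[length(pos_parts) + 1L]] <-
          genomic_position(jit, pas_pos[i, j], strand[i])
        strand_parts[[length(strand_parts) + 1L]] <-
          rep(strand[i], counts[j])
      }
    }
    ## decoy reads
    if (nrow(truth$decoys)) {
      for (d in seq_len(nrow(truth$decoys))) {
        if (runif(1) > config$decoy_sample_fraction) next
        nd <- rpois(1L, config$decoy_reads_mean)
        if (nd == 0L) next
        jit <- sample(-2:2, nd, replace = TRUE)
        pos_parts[[length(pos_parts) + 1L]] <-
          genomic_position(jit, truth$decoys$genomic_pos[d],
                           truth$decoys$strand[d])
        strand_parts[[length(strand_parts) + 1L]] <-
          rep(truth$decoys$strand[d], nd)
      }
    }
    pos_all <- unlist(pos_parts)
    if (is.null(pos_all)) pos_all <- integer(0)
    df <- data.frame(chrom = rep("chrS", length(pos_all)),
                     strand = as.character(unlist(strand_parts)),
                     pos = pos_all, count = rep(1, length(pos_all)))
    df <- collapse_coverage(df)
    attr(df, "sample_id") <- grid$sample_id[s]
    tracks[[s]] <- df
  }
  tracks
}

#' Simulate CLIP peak sets for a regulator and a background RBP
#'
#' Regulator peaks (two replicates) are centered
#' Normal(\code{dPAS + clip_enrichment_center}, \code{clip_enrichment_sd})
#' in transcript coordinates on regulated-lengthened genes, with uniform
#' background peaks elsewhere; the high-confidence subset marks replicate-1
#' peaks whose center is reproduced within 20 nt by a replicate-2 peak.
#' The background RBP has no positional mode.
#'
#' @param config A \code{\link{sim_config}}.
#' @param sim Output of \code{\link{simulate_genome}}.
#' @return GRanges of peaks with metadata \code{rbp_id}, \code{replicate},
#'   \code{score}, and logical \code{high}.
#' @export
simulate_clip_peaks <- function(config, sim) {
  set.seed(config$seed + 2L)
  truth <- sim$truth
  exons <- sim$exons
  k <- config$pas_per_exon
  n <- length(exons)
  dpas <- truth$pas$genomic_pos[truth$pas$pas_index == k]
  strand <- truth$genes$strand
  lengthened <- truth$genes$label == "lengthened_by_RBP"
  hw <- floor(config$clip_peak_width / 2)

  mk_peak <- function(center, strand, rbp, rep_id) {
    GenomicRanges::GRanges("chrS",
                           IRanges::IRanges(center - hw, center + hw),
                           strand = strand,
                           rbp_id = rbp, replicate = rep_id,
                           score = round(runif(length(center), 1, 100), 2))
  }

  peaks <- list()
  for (rep_id in c("rep1", "rep2")) {
    ## regulator: one planted peak per lengthened gene
    idx <- which(lengthened)
    if (length(idx)) {
      off <- round(rnorm(length(idx), config$clip_enrichment_center,
                         config$clip_enrichment_sd))
      centers <- genomic_position(off, dpas[idx], strand[idx])
      peaks[[length(peaks) + 1L]] <-
        mk_peak(centers, strand[idx], "RBP_regulator", rep_id)
    }
    ## regulator background on other genes
    bg_n <- rpois(1L, config$clip_background_rate * sum(!lengthened))
    if (bg_n > 0L) {
      gi <- sample(which(!lengthened), bg_n, replace = TRUE)
      centers <- round(runif(bg_n, GenomicRanges::start(exons)[gi] + hw,
                             GenomicRanges::end(exons)[gi] - hw))
      peaks[[length(peaks) + 1L]] <-
        mk_peak(centers, strand[gi], "RBP_regulator", rep_id)
    }
    ## background RBP: uniform over all exons
    gi <- seq_len(n)
    centers <- round(runif(n, GenomicRanges::start(exons) + hw,
                           GenomicRanges::end(exons) - hw))
    peaks[[length(peaks) + 1L]] <-
      mk_peak(centers, strand, "RBP_background", rep_id)
  }
  gr <- do.call(c, peaks)

  ## high-confidence subset: rep1 peaks reproduced by rep2 within 20 nt
  gr$high <- FALSE
  for (rbp in unique(gr$rbp_id)) {
    i1 <- which(gr$rbp_id == rbp & gr$replicate == "rep1")
    i2 <- which(gr$rbp_id == rbp & gr$replicate == "rep2")
    if (!length(i1) || !length(i2)) next
    c1 <- (GenomicRanges::start(gr)[i1] + GenomicRanges::end(gr)[i1]) / 2
    c2 <- (GenomicRanges::start(gr)[i2] + GenomicRanges::end(gr)[i2]) / 2
    near <- vapply(c1, function(x) any(abs(x - c2) <= 20), logical(1))
    gr$high[i1[near]] <- TRUE
  }
  gr
}

#' Simulate a DMS accessibility track
#'
#' A/C positions within 100 nt upstream of every distal PAS receive Poisson
#' coverage and Beta-distributed mutation rates whose mean is
#' \code{dms_structured_rate} inside motifs labeled structured,
#' \code{dms_open_rate} elsewhere. Non-A/C positions are absent (rate 0 by
#' convention).
#'
#' @param config A \code{\link{sim_config}}.
#' @param sim Output of \code{\link{simulate_genome}}.
#' @return A DMS track \code{data.frame(chrom, pos, strand, base, coverage,
#'   rate)} with 1-based positions and transcript-sense bases.
#' @export
simulate_dms <- function(config, sim) {
  set.seed(config$seed + 3L)
  truth <- sim$truth
  k <- config$pas_per_exon
  dp <- truth$pas[truth$pas$pas_index == k, ]
  rows <- list()
  for (i in seq_len(nrow(dp))) {
    anchor <- dp$genomic_pos[i]
    strand <- dp$strand[i]
    gpos <- genomic_position(-100:0, anchor, strand)  # upstream window
    win <- fetch_sequence(sim$genome, dp$chrom[i], min(gpos), max(gpos),
                          strand)
    base <- strsplit(win, "")[[1]]  # transcript order = gpos order
    keep <- base %in% c("A", "C")
    if (!any(keep)) next
    gpos <- gpos[keep]; base <- base[keep]
    ## motif footprints for rate assignment
    g <- dp$hexamer_gap[i]
    hex_t <- (dp$transcript_pos[i] - g - 6L):(dp$transcript_pos[i] - g - 1L)
    ugua_t <- (min(hex_t) - dp$linker[i] - 4L):(min(hex_t) - dp$linker[i] - 1L)
    motif_g <- genomic_position(c(hex_t, ugua_t) - dp$transcript_pos[i],
                                anchor, strand)
    in_motif <- gpos %in% motif_g
    m <- ifelse(in_motif & dp$structured[i], config$dms_structured_rate,
                config$dms_open_rate)
    rate <- numeric(length(gpos))
    for (u in unique(m)) {
      sel <- m == u
      rate[sel] <- rbeta_mean(sum(sel), u)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = dp$chrom[i], pos = gpos, strand = strand, base = base,
      coverage = rpois(length(gpos), config$dms_coverage_mean),
      rate = rate
    )
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Simulate the expression table and a DaPars-style dPDUI table
#'
#' Expressed transcripts get control TPM medians above 1;
#' \code{fraction_unexpressed} of the non-changing genes are simulated
#' below threshold. The dPDUI column is the true control-minus-knockdown
#' distal usage plus Gaussian noise; adjusted p-values are small for
#' regulated genes and roughly uniform otherwise.
#'
#' @param config A \code{\link{sim_config}}.
#' @param sim Output of \code{\link{simulate_genome}}.
#' @return A list: \code{expression} (as \code{\link{read_expression_table}})
#'   and \code{dpdui} (\code{data.frame(gene_id, pPAS, dPAS, dPDUI,
#'   adjusted_p)}).
#' @export
simulate_expression_and_dpdui <- function(config, sim) {
  set.seed(config$seed + 4L)
  truth <- sim$truth
  exons <- sim$exons
  n <- length(exons)
  k <- config$pas_per_exon

  ## 3'UTR = cds_end .. exon 3' end (transcript sense)
  plus <- as.character(GenomicRanges::strand(exons)) == "+"
  utr <- GenomicRanges::GRanges(
    "chrS",
    IRanges::IRanges(ifelse(plus, exons$cds_end, GenomicRanges::start(exons)),
                     ifelse(plus, GenomicRanges::end(exons), exons$cds_end)),
    strand = GenomicRanges::strand(exons)
  )
  utr$transcript_id <- exons$gene_id

  nonch <- which(truth$genes$label == "non_changing")
  n_low <- round(config$fraction_unexpressed * n)
  low <- if (n_low > 0) sample(nonch, min(n_low, length(nonch))) else integer(0)
  mu <- rep(log(10), n); mu[low] <- log(0.2)
  tpm <- exp(matrix(rnorm(n * config$n_replicates, mu, 0.5), n,
                    config$n_replicates))
  colnames(tpm) <- paste0("tpm_ctrl", seq_len(config$n_replicates))
  rownames(tpm) <- exons$gene_id

  dist_ctrl <- truth$usage_control[, k]
  dist_kd <- truth$usage_kd[, k]
  dpdui <- (dist_ctrl - dist_kd) + rnorm(n, 0, config$dpdui_noise_sd)
  regulated <- truth$genes$label != "non_changing"
  p <- ifelse(regulated, runif(n, 0, 0.01), runif(n, 0.1, 1))
  ppas <- truth$pas$genomic_pos[truth$pas$pas_index == 1L]
  dpas <- truth$pas$genomic_pos[truth$pas$pas_index == k]

  list(
    expression = list(utr = utr, tpm = tpm),
    dpdui = data.frame(gene_id = exons$gene_id, pPAS = ppas, dPAS = dpas,
                       dPDUI = dpdui, adjusted_p = p)
  )
}

#' Simulate the full synthetic APA experiment
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list with \code{config}, \code{genome}, \code{exons},
#'   \code{pas_reference}, \code{truth}, \code{reads} (coverage tracks),
#'   \code{peaks}, \code{dms}, \code{expression}, \code{dpdui}.
#' @export
simulate_apa_experiment <- function(config = sim_config()) {
  sim <- simulate_genome(config)
  sim$reads <- simulate_three_prime_reads(config, sim)
  sim$peaks <- simulate_clip_peaks(config, sim)
  sim$dms <- simulate_dms(config, sim)
  ed <- simulate_expression_and_dpdui(config, sim)
  sim$expression <- ed$expression
  sim$dpdui <- ed$dpdui
  sim$config <- config
  sim
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Synthetic APA ground truth:", nrow(x$genes), "genes (",
      sum(x$genes$label == "lengthened_by_RBP"), "lengthened,",
      sum(x$genes$label == "shortened_by_RBP"), "shortened,",
      sum(x$genes$label == "non_changing"), "non-changing ),",
      nrow(x$decoys), "internal-priming decoys\n")
  invisible(x)
}
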