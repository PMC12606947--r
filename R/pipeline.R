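## One-call orchestration: simulate -> call PAS -> call APA changes ->
## binding atlas -> RNA maps -> motif maps -> DMS, with files and a
## machine-readable JSON report.

default_analysis_params <- function() {
  list(
    min_per_position = 10, min_total = 20,
    reference_slack = 0, hexamer_flank = 30,
    delta_thresh = 0.10, n_support = 2, opposite_tolerance = 0,
    nonchange_min_reads = 10, nonchange_max_delta = 0.05,
    change_thresh = 0.20, null_thresh = 0.05, alpha = 0.05,
    extension = 500,
    n_boot = 100, band_percentiles = c(25, 75), map_window = 300,
    motif_window_4mer = 10, motif_window_6mer = 20,
    motif_smooth = 5, gc_smooth = 10,
    dms_upstream_window = 100, dms_min_cov = 100,
    spacing_search_radius = 150, spacing_binding_radius = 100,
    min_median_tpm = 1, highly_expressed_pas_reads = 100
  )
}

#' Load and validate a pipeline configuration
#'
#' A configuration is a YAML file (or list) with two optional blocks:
#' \code{simulation} (fields of \code{\link{sim_config}}) and
#' \code{analysis} (thresholds and windows; defaults are the standard
#' values: 10 reads per position, 20 per cluster, usage delta 0.10 in 2/3
#' replicates, dPDUI 0.20/0.05 at alpha 0.05, 500 nt extension, 100
#' bootstraps at the 25th/75th percentiles, motif windows 10/20 nt with
#' smoothing 5/10 nt, DMS coverage 100 within 100 nt upstream, spacing
#' search 150 nt with binding within 100 nt). Unknown keys or non-numeric
#' values for numeric parameters fail validation before any computation.
#'
#' @param config NULL (all defaults), a path to a YAML file, or a list.
#' @param seed Optional seed overriding the configured one.
#' @return List with \code{simulation} (a \code{sim_config}) and
#'   \code{analysis} (parameter list).
#' @export
load_pipeline_config <- function(config = NULL, seed = NULL) {
  raw <- if (is.null(config)) list() else if (is.character(config)) {
    yaml::read_yaml(config)
  } else config
  bad <- setdiff(names(raw), c("simulation", "analysis"))
  if (length(bad)) stop("unknown config blocks: ", paste(bad, collapse = ", "))

  sim_defaults <- formals(sim_config)
  bad <- setdiff(names(raw$simulation), names(sim_defaults))
  if (length(bad)) {
    stop("unknown simulation parameters: ", paste(bad, collapse = ", "))
  }
  ana <- default_analysis_params()
  bad <- setdiff(names(raw$analysis), names(ana))
  if (length(bad)) {
    stop("unknown analysis parameters: ", paste(bad, collapse = ", "))
  }
  for (k in names(raw$analysis)) {
    if (!is.numeric(raw$analysis[[k]])) {
      stop("analysis parameter '", k, "' must be numeric, got ",
           class(raw$analysis[[k]])[1L])
    }
    ana[[k]] <- raw$analysis[[k]]
  }
  sim_args <- raw$simulation
  if (!is.null(seed)) sim_args$seed <- seed
  sim_cfg <- do.call(sim_config, sim_args)
  list(simulation = sim_cfg, analysis = ana)
}

## standard replicate pairing for one cellular fraction
fraction_pairing <- function(fraction, n_replicates) {
  lapply(seq_len(n_replicates), function(r) {
    c(kd = paste("kd", fraction, paste0("rep", r), sep = "_"),
      control = paste("control", fraction, paste0("rep", r), sep = "_"))
  })
}

## match clean clusters to planted truth PAS (same gene, within tol nt)
truth_confusion <- function(result, truth, changes, tol = 10) {
  usage <- result$usage
  m <- merge(data.frame(terminal_exon_id = usage$terminal_exon_id,
                        pas = usage$pas,
                        status = changes$status),
             truth$pas[, c("gene_id", "genomic_pos")],
             by.x = "terminal_exon_id", by.y = "gene_id")
  m <- m[abs(m$pas - m$genomic_pos) <= tol, , drop = FALSE]
  m <- m[!duplicated(paste(m$terminal_exon_id, m$pas)), , drop = FALSE]
  lab <- setNames(truth$genes$label, truth$genes$gene_id)
  m$regulated <- lab[m$terminal_exon_id] != "non_changing"
  m$called <- m$status != "not_called"
  tab <- table(truth_regulated = m$regulated, called = m$called)
  sens <- if (any(m$regulated)) mean(m$called[m$regulated]) else NA_real_
  fpr <- if (any(!m$regulated)) mean(m$called[!m$regulated]) else NA_real_
  list(table = tab, sensitivity = sens, false_positive_rate = fpr,
       n_matched = nrow(m))
}

#' Run the full APA analysis pipeline on synthetic data
#'
#' Simulates every input under the configured seed, writes them to
#' \code{outdir/inputs}, and runs each analysis stage, writing per-stage
#' tables and a machine-readable \code{report.json} of all summary
#' statistics, including a truth-versus-called confusion table. Rerunning
#' with the same configuration and seed reproduces every output exactly.
#'
#' @param config NULL, a YAML path, or a list (see
#'   \code{\link{load_pipeline_config}}).
#' @param outdir Output directory (created if needed); NULL skips all
#'   file writing.
#' @param seed Optional seed override.
#' @return The report as a list (invisibly classed
#'   \code{apa_pipeline_report}).
#' @export
run_apa_pipeline <- function(config = NULL, outdir = NULL, seed = NULL) {
  cfg <- load_pipeline_config(config, seed)
  ana <- cfg$analysis
  scfg <- cfg$simulation

  ## ---- simulate ----
  sim <- simulate_apa_experiment(scfg)
  if (!is.null(outdir)) {
    dir.create(file.path(outdir, "inputs"), recursive = TRUE,
               showWarnings = FALSE)
    Biostrings::writeXStringSet(sim$genome,
                                file.path(outdir, "inputs", "genome.fa"))
    write_exon_table(sim$exons, file.path(outdir, "inputs", "exons.tsv"))
    write_bed6(sim$pas_reference,
               file.path(outdir, "inputs", "pas_reference.bed"))
    for (s in names(sim$reads)) {
      write_coverage(sim$reads[[s]],
                     file.path(outdir, "inputs", paste0(s, ".plus.bedGraph")),
                     file.path(outdir, "inputs", paste0(s, ".minus.bedGraph")))
    }
    pk <- sim$peaks
    pk$name <- paste(pk$rbp_id, pk$replicate, seq_along(pk), sep = "|")
    write_bed6(pk, file.path(outdir, "inputs", "peaks.bed"))
    write_dms_track(sim$dms, file.path(outdir, "inputs", "dms.tsv"))
    write.table(sim$dpdui, file.path(outdir, "inputs", "dpdui.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## ---- PAS cluster calling ----
  pas_res <- call_pas_clusters(
    sim$reads, sim$genome, sim$exons, sim$pas_reference,
    min_per_position = ana$min_per_position, min_total = ana$min_total,
    reference_slack = ana$reference_slack,
    hexamer_flank = ana$hexamer_flank)

  ## ---- APA change calling per fraction ----
  fracs <- intersect(c("whole", "nuclear", "cytoplasmic"), scfg$fractions)
  changes <- list(); nonchanging <- list()
  for (f in fracs) {
    pairing <- fraction_pairing(f, scfg$n_replicates)
    changes[[f]] <- call_pas_changes(pas_res$usage, pairing,
                                     delta_thresh = ana$delta_thresh,
                                     n_support = ana$n_support,
                                     opposite_tolerance =
                                       ana$opposite_tolerance)
    nonchanging[[f]] <- call_nonchanging(pas_res$usage, pairing,
                                         min_reads = ana$nonchange_min_reads,
                                         max_delta = ana$nonchange_max_delta)
  }
  compartment <- NULL
  if (all(c("nuclear", "cytoplasmic") %in% fracs)) {
    compartment <- compare_compartments(
      changes$nuclear, changes$cytoplasmic,
      nonchanging$nuclear, nonchanging$cytoplasmic,
      pas_res$usage, pas_res$usage)
  }
  confusion_frac <- fracs[1L]
  confusion <- truth_confusion(pas_res, sim$truth,
                               changes[[confusion_frac]])

  ## ---- dPDUI event sets ----
  events <- classify_dpdui(sim$dpdui, change_thresh = ana$change_thresh,
                           null_thresh = ana$null_thresh,
                           alpha = ana$alpha)
  events$chrom <- "chrS"
  events$strand <- setNames(sim$truth$genes$strand,
                            sim$truth$genes$gene_id)[events$gene_id]

  ## ---- binding atlas ----
  expressed <- select_expressed(sim$expression, ana$min_median_tpm)
  rbps <- unique(sim$peaks$rbp_id)
  peak_sets <- lapply(setNames(rbps, rbps),
                      function(r) sim$peaks[sim$peaks$rbp_id == r])
  bound_frac <- vapply(peak_sets, utr_bound_fraction, numeric(1),
                       utrs = expressed)
  hi_pas_idx <- pas_res$clean$total >= ana$highly_expressed_pas_reads
  hi_pas <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(pas_res$clean)[hi_pas_idx],
    IRanges::IRanges(pas_res$clean$pas[hi_pas_idx],
                     pas_res$clean$pas[hi_pas_idx]),
    strand = GenomicRanges::strand(pas_res$clean)[hi_pas_idx])
  prox_freq <- lapply(peak_sets, pas_proximal_frequency, pas = hi_pas,
                      window = 500)
  jaccard <- pairwise_peak_jaccard(peak_sets)

  ## ---- RNA maps around the distal PAS ----
  reg_events <- events[events$label == "lengthened_by_RBP", , drop = FALSE]
  ctl_events <- events[events$label == "non_changing", , drop = FALSE]
  reg_peaks <- peak_sets[["RBP_regulator"]]
  mat_reg <- event_window_matrix(reg_events, reg_peaks, "dPAS",
                                 ana$map_window)
  mat_ctl <- event_window_matrix(ctl_events, reg_peaks, "dPAS",
                                 ana$map_window)
  prof_reg <- fraction_with_bootstrap(mat_reg, n_boot = ana$n_boot,
                                      percentiles = ana$band_percentiles,
                                      seed = scfg$seed + 10L)
  prof_ctl <- fraction_with_bootstrap(mat_ctl, n_boot = ana$n_boot,
                                      percentiles = ana$band_percentiles,
                                      seed = scfg$seed + 11L)
  fish <- positional_fisher(mat_reg, mat_ctl)
  best <- which.min(fish$p)
  map_summary <- list(
    argmax_offset = fish$offset[best],
    min_p = fish$p[best],
    n_regulated = nrow(mat_reg), n_nonchanging = nrow(mat_ctl))

  ## ---- motif maps and spacing ----
  half <- ana$spacing_search_radius
  event_seqs <- function(ev) {
    vapply(seq_len(nrow(ev)), function(i) {
      anchor <- ev$dPAS[i]
      fetch_sequence(sim$genome, ev$chrom[i], anchor - half, anchor + half,
                     ev$strand[i])
    }, character(1))
  }
  seq_reg <- event_seqs(reg_events)
  seq_ctl <- event_seqs(ctl_events)
  offs <- -half:half
  wf_reg <- window_frequency(seq_reg, motif_spec("UGUA"), offsets = offs,
                             window = ana$motif_window_4mer,
                             smooth = ana$motif_smooth)
  wf_ctl <- window_frequency(seq_ctl, motif_spec("UGUA"), offsets = offs,
                             window = ana$motif_window_4mer,
                             smooth = ana$motif_smooth)
  hyper <- positional_hypergeom(wf_reg$n_with_match, wf_ctl$n_with_match,
                                length(seq_reg), length(seq_ctl))
  gc_reg <- gc_profile(seq_reg, offsets = offs, smooth = ana$gc_smooth)

  truth_pas <- sim$truth$pas
  pas_gr <- function(rows) {
    GenomicRanges::GRanges(rows$chrom,
                           IRanges::IRanges(rows$genomic_pos,
                                            rows$genomic_pos),
                           strand = rows$strand)
  }
  k <- scfg$pas_per_exon
  lab <- setNames(sim$truth$genes$label, sim$truth$genes$gene_id)
  dpas_reg <- pas_gr(truth_pas[truth_pas$pas_index == k &
                                 lab[truth_pas$gene_id] ==
                                 "lengthened_by_RBP", ])
  dpas_ctl <- pas_gr(truth_pas[truth_pas$pas_index == k &
                                 lab[truth_pas$gene_id] ==
                                 "non_changing", ])
  spacing_reg <- motif_distance_distribution(
    dpas_reg, reg_peaks, sim$genome,
    search_radius = ana$spacing_search_radius,
    binding_radius = ana$spacing_binding_radius)
  spacing_ctl <- motif_distance_distribution(
    dpas_ctl, NULL, sim$genome,
    search_radius = ana$spacing_search_radius,
    binding_radius = ana$spacing_binding_radius)
  spacing_summary <- list(
    median_regulated = if (length(spacing_reg$linkers))
      median(spacing_reg$linkers) else NA_real_,
    median_control = if (length(spacing_ctl$linkers))
      median(spacing_ctl$linkers) else NA_real_)

  ## ---- DMS accessibility ----
  dms_reg <- motif_dms_scores(dpas_reg, motif_spec("AWUAAA"), sim$dms,
                              sim$genome,
                              upstream_window = ana$dms_upstream_window,
                              min_cov = ana$dms_min_cov)
  dms_ctl <- motif_dms_scores(dpas_ctl, motif_spec("AWUAAA"), sim$dms,
                              sim$genome,
                              upstream_window = ana$dms_upstream_window,
                              min_cov = ana$dms_min_cov)
  dms_test <- if (nrow(dms_reg) && nrow(dms_ctl)) {
    compare_accessibility(dms_reg$score, dms_ctl$score)
  } else list(D = NA_real_, p = NA_real_)

  ## ---- report ----
  report <- list(
    seed = scfg$seed,
    funnel = as.list(pas_res$funnel),
    n_clean_clusters = length(pas_res$clean),
    changes = lapply(changes, function(ch)
      as.list(table(factor(ch$status,
                           c("increased", "decreased", "not_called"))))),
    n_nonchanging = lapply(nonchanging, length),
    compartment = if (!is.null(compartment))
      lapply(compartment, length) else NULL,
    confusion = list(sensitivity = confusion$sensitivity,
                     false_positive_rate = confusion$false_positive_rate,
                     n_matched = confusion$n_matched),
    event_sets = as.list(table(events$label)),
    utr_bound_fraction = as.list(bound_frac),
    peak_jaccard_regulator_background =
      jaccard["RBP_regulator", "RBP_background"],
    rna_map = map_summary,
    spacing = spacing_summary,
    dms = dms_test
  )
  class(report) <- "apa_pipeline_report"

  if (!is.null(outdir)) {
    cl <- pas_res$clean
    bed <- GenomicRanges::GRanges(GenomicRanges::seqnames(cl),
                                  IRanges::IRanges(GenomicRanges::start(cl),
                                                   GenomicRanges::end(cl)),
                                  strand = GenomicRanges::strand(cl))
    bed$name <- paste0(cl$terminal_exon_id, ":", seq_along(cl))
    bed$score <- cl$total
    write_bed6(bed, file.path(outdir, "clusters.bed"))
    write.table(pas_res$usage, file.path(outdir, "usage.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(stage = names(pas_res$funnel),
                           clusters = as.integer(pas_res$funnel)),
                file.path(outdir, "filter_funnel.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (f in fracs) {
      write.table(changes[[f]],
                  file.path(outdir, paste0("changes_", f, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(events, file.path(outdir, "event_sets.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(prof_reg, file.path(outdir, "rna_map_regulated.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(prof_ctl, file.path(outdir, "rna_map_nonchanging.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(fish, file.path(outdir, "rna_map_fisher.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cbind(wf_reg[, c("offset", "frequency")],
                      frequency_nonchanging = wf_ctl$frequency,
                      p = hyper$p),
                file.path(outdir, "motif_map_ugua.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(gc_reg, file.path(outdir, "gc_profile_regulated.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(as.character(spacing_reg$linkers),
               file.path(outdir, "spacing_regulated.txt"))
    writeLines(as.character(spacing_ctl$linkers),
               file.path(outdir, "spacing_nonchanging.txt"))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(report)
}

#' @export
print.apa_pipeline_report <- function(x, ...) {
  cat("APA pipeline report (seed", x$seed, ")\n")
  cat("  cluster funnel:",
      paste(names(x$funnel), unlist(x$funnel), sep = "=",
            collapse = ", "), "\n")
  cat("  change-call sensitivity:", round(x$confusion$sensitivity, 3),
      " false-positive rate:", round(x$confusion$false_positive_rate, 3),
      "\n")
  cat("  RNA map: argmax offset", x$rna_map$argmax_offset, "nt, p =",
      signif(x$rna_map$min_p, 3), "\n")
  cat("  spacing medians (regulated/control):",
      x$spacing$median_regulated, "/", x$spacing$median_control, "nt\n")
  cat("  DMS KS: D =", round(x$dms$D, 3), ", p =", signif(x$dms$p, 3),
      "\n")
  invisible(x)
}
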