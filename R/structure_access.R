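## DMS accessibility of cis-elements upstream of PAS. Low DMS mutation
## rates at adenosines imply base-paired (structured) nucleotides.

#' Maximum DMS mutation rate per motif occurrence upstream of PAS
#'
#' For every occurrence of the motif within \code{upstream_window} nt
#' upstream (transcript orientation) of each PAS, records the maximum
#' mutation rate over the occurrence's adenosines that have coverage of
#' at least \code{min_cov}. Occurrences with no sufficiently covered A
#' are excluded ("sufficient data"); with \code{per_pas_max} the
#' occurrences of each PAS are collapsed to their maximum.
#'
#' @param pas Width-1 \code{GRanges} of PAS positions.
#' @param spec A \code{\link{motif_spec}} (or pattern string).
#' @param dms DMS track data.frame (\code{chrom, pos, strand, base,
#'   coverage, rate}; transcript-sense bases, 1-based positions).
#' @param genome Named \code{DNAStringSet}.
#' @param upstream_window Window upstream of the PAS scanned for motifs
#'   (default 100 nt).
#' @param min_cov Minimum coverage per position (default 100 reads).
#' @param per_pas_max Collapse to one score per PAS?
#' @return data.frame with \code{pas_index}, \code{motif_start} (genomic),
#'   and \code{score} (max A mutation rate), one row per retained motif
#'   occurrence (or per PAS when collapsed).
#' @export
motif_dms_scores <- function(pas, spec, dms, genome,
                             upstream_window = 100, min_cov = 100,
                             per_pas_max = FALSE) {
  if (is.character(spec)) spec <- motif_spec(spec)
  dms <- dms[dms$coverage >= min_cov, , drop = FALSE]
  key <- paste(dms$chrom, dms$strand, dms$pos, sep = "\r")
  rate <- setNames(dms$rate, key)
  base <- setNames(dms$base, key)
  rows <- list()
  for (i in seq_along(pas)) {
    chrom <- as.character(GenomicRanges::seqnames(pas))[i]
    strand <- as.character(GenomicRanges::strand(pas))[i]
    anchor <- GenomicRanges::start(pas)[i]
    glen <- if (is.character(genome)) nchar(genome[[chrom]]) else
      length(genome[[chrom]])
    ## clamp the upstream window at the chromosome bounds
    w_eff <- if (strand == "+") min(upstream_window, anchor - 1L) else
      min(upstream_window, glen - anchor)
    gpos <- genomic_position(-w_eff:0, anchor, strand)
    seq <- tryCatch(fetch_sequence(genome, chrom, min(gpos), max(gpos),
                                   strand),
                    error = function(e) NULL)
    if (is.null(seq)) next
    starts <- scan_motif(seq, spec)  # 1-based in transcript order
    w <- nchar(spec$pattern)
    for (s in starts) {
      ## transcript positions of the occurrence, mapped to genome
      occ_t <- (s - 1L):(s + w - 2L) - w_eff  # offsets from anchor
      occ_g <- genomic_position(occ_t, anchor, strand)
      occ_chars <- strsplit(substr(seq, s, s + w - 1L), "")[[1]]
      a_g <- occ_g[occ_chars == "A"]
      if (length(a_g) == 0L) next
      k <- paste(chrom, strand, a_g, sep = "\r")
      r <- rate[k]
      ok <- !is.na(r) & !is.na(base[k]) & base[k] == "A"
      r <- r[ok]
      if (length(r) == 0L) next  # no covered A: insufficient data
      rows[[length(rows) + 1L]] <- data.frame(
        pas_index = i, motif_start = min(occ_g), score = max(r))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pas_index = integer(), motif_start = integer(),
               score = numeric())
  if (per_pas_max && nrow(out)) {
    agg <- tapply(out$score, out$pas_index, max)
    out <- data.frame(pas_index = as.integer(names(agg)),
                      motif_start = NA_integer_,
                      score = as.numeric(agg))
  }
  rownames(out) <- NULL
  out
}

#' Compare accessibility distributions between PAS sets
#'
#' Two-sample two-tailed Kolmogorov-Smirnov test on motif accessibility
#' scores; the exact p-value is used when the smaller group has at most
#' 10 observations.
#'
#' @param scores_regulated,scores_control Numeric score vectors.
#' @return List with \code{D} and \code{p}.
#' @export
compare_accessibility <- function(scores_regulated, scores_control) {
  exact <- min(length(scores_regulated), length(scores_control)) <= 10
  kt <- suppressWarnings(ks.test(scores_regulated, scores_control,
                                 exact = if (exact) TRUE else NULL))
  list(D = unname(kt$statistic), p = kt$p.value)
}
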