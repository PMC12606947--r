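## 3'UTR binding breadth/specificity of RBPs and PAS-proximal binding
## frequency.

#' Select expressed transcripts
#'
#' @param expression List with \code{utr} (GRanges, metadata
#'   \code{transcript_id}) and \code{tpm} (matrix, one column per control
#'   sample), as from \code{\link{read_expression_table}}.
#' @param min_median_tpm Median control TPM threshold (default 1).
#' @return The \code{utr} GRanges restricted to transcripts whose median
#'   control TPM meets the threshold.
#' @export
select_expressed <- function(expression, min_median_tpm = 1.0) {
  if (length(expression$utr) == 0L) return(expression$utr)
  med <- apply(expression$tpm, 1L, median)
  keep <- med[expression$utr$transcript_id] >= min_median_tpm
  expression$utr[keep]
}

#' Fraction of expressed 3'UTRs bound by an RBP
#'
#' A 3'UTR counts as bound when any peak from either replicate overlaps it.
#'
#' @param peaks Peak \code{GRanges} (all replicates, any confidence) for
#'   one RBP.
#' @param utrs Expressed 3'UTR \code{GRanges}.
#' @return Fraction in [0, 1].
#' @export
utr_bound_fraction <- function(peaks, utrs) {
  if (length(utrs) == 0L) return(0)
  bound <- GenomicRanges::countOverlaps(utrs, peaks,
                                        ignore.strand = FALSE) > 0L
  mean(bound)
}

#' Peak composition over transcript features
#'
#' Each peak is assigned to exactly one region by the precedence
#' 3'UTR > CDS > noncoding exon > downstream extension > intron; peaks
#' overlapping none are reported as \code{other}.
#'
#' @param peaks Peak \code{GRanges} (typically the high-confidence subset).
#' @param regions Named list of \code{GRanges}: any of \code{utr3},
#'   \code{cds}, \code{noncoding}, \code{downstream}, \code{intron}.
#' @return Named numeric vector of fractions summing to 1 (empty input
#'   gives an empty vector, not NaNs).
#' @export
peak_region_composition <- function(peaks, regions) {
  if (length(peaks) == 0L) return(setNames(numeric(0), character(0)))
  precedence <- c("utr3", "cds", "noncoding", "downstream", "intron")
  assigned <- rep("other", length(peaks))
  left <- rep(TRUE, length(peaks))
  for (r in precedence) {
    if (is.null(regions[[r]])) next
    hit <- GenomicRanges::countOverlaps(peaks, regions[[r]],
                                        ignore.strand = FALSE) > 0L
    assigned[left & hit] <- r
    left <- left & !hit
  }
  tab <- table(assigned)
  frac <- as.numeric(tab) / length(peaks)
  setNames(frac, names(tab))
}

#' Per-nucleotide frequency of peak overlap around PAS
#'
#' For each transcript-orientation offset in \code{[-window, window]},
#' the fraction of PAS covered by at least one peak at that offset.
#'
#' @param peaks Peak \code{GRanges} for one RBP.
#' @param pas Width-1 \code{GRanges} of (highly expressed) PAS.
#' @param window Half-window in nt (default 500).
#' @return data.frame with \code{offset} and \code{frequency}.
#' @export
pas_proximal_frequency <- function(peaks, pas, window = 500) {
  mat <- anchor_window_matrix(pas, peaks, window)
  data.frame(offset = -window:window, frequency = colMeans(mat))
}

#' Pairwise Jaccard of peak-set footprints
#'
#' Jaccard is computed on merged base-pair footprints (intersection bp /
#' union bp), which is insensitive to how peaks are fragmented.
#'
#' @param peak_sets Named list of peak \code{GRanges}, one per RBP.
#' @return Symmetric matrix of Jaccard indices (diagonal 1 for non-empty
#'   sets).
#' @export
pairwise_peak_jaccard <- function(peak_sets) {
  n <- length(peak_sets)
  red <- lapply(peak_sets, GenomicRanges::reduce)
  out <- matrix(0, n, n, dimnames = list(names(peak_sets),
                                         names(peak_sets)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      inter <- sum(GenomicRanges::width(
        GenomicRanges::intersect(red[[i]], red[[j]])))
      uni <- sum(GenomicRanges::width(
        GenomicRanges::union(red[[i]], red[[j]])))
      out[i, j] <- out[j, i] <- if (uni > 0) inter / uni else 0
    }
  }
  out
}
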