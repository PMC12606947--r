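## Positional RNA maps: per-event peak occupancy around PAS anchors with
## bootstrap bands and per-position Fisher enrichment.

## binary (anchor x offset) occupancy matrix; offsets are transcript
## orientation, columns run -window..window
anchor_window_matrix <- function(anchors, peaks, window) {
  offs <- -window:window
  mat <- matrix(0L, length(anchors), length(offs))
  colnames(mat) <- offs
  if (length(anchors) == 0L || length(peaks) == 0L) return(mat)
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(anchors),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(anchors) - window),
                     GenomicRanges::start(anchors) + window),
    strand = GenomicRanges::strand(anchors))
  hits <- GenomicRanges::findOverlaps(win, peaks, ignore.strand = FALSE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  for (h in seq_along(q)) {
    i <- q[h]
    anchor <- GenomicRanges::start(anchors)[i]
    strand <- as.character(GenomicRanges::strand(anchors))[i]
    lo <- max(GenomicRanges::start(peaks)[s[h]], anchor - window)
    hi <- min(GenomicRanges::end(peaks)[s[h]], anchor + window)
    o <- transcript_offset(lo:hi, anchor, strand)
    mat[i, as.character(o)] <- 1L
  }
  mat
}

#' Binary event-by-offset peak occupancy matrix
#'
#' @param events An \code{event_sets} data.frame (see
#'   \code{\link{classify_dpdui}}) or any data.frame with \code{gene_id},
#'   anchor coordinate columns, \code{chrom}, and \code{strand}.
#' @param peaks Peak \code{GRanges} for one RBP.
#' @param anchor Which anchor column to use: \code{"pPAS"} or
#'   \code{"dPAS"}.
#' @param window Half-window in nt (default 300).
#' @return Binary matrix (events x offsets); entry 1 iff at least one peak
#'   covers that transcript-orientation offset from the event's anchor.
#' @export
event_window_matrix <- function(events, peaks, anchor = c("dPAS", "pPAS"),
                                window = 300) {
  anchor <- match.arg(anchor)
  chrom <- if (!is.null(events$chrom)) events$chrom else "chrS"
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(events[[anchor]],
                                                events[[anchor]]),
                               strand = events$strand)
  anchor_window_matrix(gr, peaks, window)
}

#' Per-offset binding fraction with bootstrap percentile band
#'
#' Events (matrix rows) are resampled with replacement \code{n_boot}
#' times; the band is the stated percentiles of the per-offset bootstrap
#' means.
#'
#' @param mat Binary occupancy matrix from
#'   \code{\link{event_window_matrix}}.
#' @param n_boot Bootstrap resamples (default 100).
#' @param percentiles Band percentiles (default 25th and 75th).
#' @param seed Seed for the resampling.
#' @return A \code{positional_profile} data.frame: \code{offset},
#'   \code{fraction}, \code{band_low}, \code{band_high}; attribute
#'   \code{n_events}.
#' @export
fraction_with_bootstrap <- function(mat, n_boot = 100,
                                    percentiles = c(25, 75), seed = 1) {
  n <- nrow(mat)
  frac <- colMeans(mat)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, ncol(mat))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[b, ] <- colMeans(mat[idx, , drop = FALSE])
  }
  qs <- apply(boot, 2L, quantile, probs = percentiles / 100, names = FALSE)
  out <- data.frame(offset = as.integer(colnames(mat)),
                    fraction = frac,
                    band_low = qs[1L, ],
                    band_high = qs[2L, ])
  attr(out, "n_events") <- n
  class(out) <- c("positional_profile", "data.frame")
  out
}

#' Per-offset Fisher enrichment between two event sets
#'
#' At each offset a 2x2 table of (bound, unbound) x (regulated, control)
#' is tested with a two-sided Fisher exact test (probability-mass
#' convention). Offsets where either set has zero events give \code{NA}.
#'
#' @param mat_regulated,mat_control Binary occupancy matrices over the
#'   same offsets.
#' @return data.frame with \code{offset}, \code{p}, and \code{sign} (+1
#'   where the regulated set is more bound, -1 where less, 0 where equal).
#' @export
positional_fisher <- function(mat_regulated, mat_control) {
  stopifnot(ncol(mat_regulated) == ncol(mat_control))
  n1 <- nrow(mat_regulated)
  n2 <- nrow(mat_control)
  b1 <- colSums(mat_regulated)
  b2 <- colSums(mat_control)
  p <- rep(NA_real_, length(b1))
  if (n1 > 0L && n2 > 0L) {
    for (j in seq_along(b1)) {
      tab <- matrix(c(b1[j], n1 - b1[j], b2[j], n2 - b2[j]), 2L)
      p[j] <- fisher.test(tab)$p.value
    }
  }
  d <- if (n1 > 0L && n2 > 0L) b1 / n1 - b2 / n2 else
    rep(NA_real_, length(b1))
  data.frame(offset = as.integer(colnames(mat_regulated)),
             p = p, sign = sign(d))
}

#' Signed -log10 p heatmap rows across RBPs
#'
#' @param fisher_list Named list of \code{\link{positional_fisher}}
#'   outputs, one per RBP, over the same offsets.
#' @return Matrix (RBP x offset) of signed -log10 p (positive =
#'   enrichment in the regulated set, negative = depletion), rows ordered
#'   by decreasing max |value|.
#' @export
enrichment_heatmap_rows <- function(fisher_list) {
  rows <- lapply(fisher_list, function(df) {
    v <- -log10(df$p) * df$sign
    v[df$sign == 0] <- 0
    v
  })
  m <- do.call(rbind, rows)
  colnames(m) <- fisher_list[[1L]]$offset
  ord <- order(apply(abs(m), 1L, max, na.rm = TRUE), decreasing = TRUE)
  m[ord, , drop = FALSE]
}

#' @export
print.positional_profile <- function(x, ...) {
  cat("Positional profile over offsets [", min(x$offset), ",",
      max(x$offset), "] nt;", attr(x, "n_events"), "events; peak fraction",
      round(max(x$fraction), 3), "at offset",
      x$offset[which.max(x$fraction)], "\n")
  invisible(x)
}

#' @export
plot.positional_profile <- function(x, ...) {
  plot(x$offset, x$fraction, type = "l", xlab = "offset (nt)",
       ylab = "fraction bound", ...)
  graphics::polygon(c(x$offset, rev(x$offset)),
                    c(x$band_low, rev(x$band_high)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(x$offset, x$fraction)
  invisible(x)
}
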