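## Motif scanning, sliding-window positional motif frequency, GC profiles,
## and UGUA-to-hexamer spacing distributions.

#' Build a motif specification
#'
#' @param pattern IUPAC nucleotide string, RNA or DNA alphabet (U is
#'   normalized to T), e.g. \code{"AWUAAA"} for the PAS hexamers or
#'   \code{"UGUA"} for the CFIm element.
#' @param orientation \code{"sense"} scans for the pattern itself;
#'   \code{"reverse_complement"} scans the sense sequence for the
#'   reverse-complemented pattern.
#' @return A \code{motif_spec} list with the normalized DNA pattern, the
#'   effective search pattern, and the default window size (10 nt for
#'   4-mers, 20 nt for 6-mers).
#' @export
motif_spec <- function(pattern,
                       orientation = c("sense", "reverse_complement")) {
  orientation <- match.arg(orientation)
  pattern <- normalize_motif(pattern)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", pattern)) {
    stop("pattern contains non-IUPAC characters: ", pattern)
  }
  search <- if (orientation == "reverse_complement") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
  } else pattern
  structure(list(pattern = pattern, orientation = orientation,
                 search = search,
                 window = if (nchar(pattern) <= 4L) 10L else 20L),
            class = "motif_spec")
}

#' Scan a sequence for all (overlapping) motif matches
#'
#' @param sequence Character DNA/RNA string (U normalized to T).
#' @param spec A \code{\link{motif_spec}} (or a pattern string).
#' @return Integer vector of 1-based match start positions within
#'   \code{sequence}.
#' @export
scan_motif <- function(sequence, spec) {
  if (is.character(spec)) spec <- motif_spec(spec)
  subject <- Biostrings::DNAString(normalize_motif(sequence))
  if (length(subject) < nchar(spec$search)) return(integer(0))
  m <- Biostrings::matchPattern(spec$search, subject, fixed = FALSE)
  IRanges::start(m)
}

#' Sliding-window motif frequency around an anchor
#'
#' For each offset, the fraction of sequences with at least one motif
#' match starting within the window centered at that offset (a window of
#' width w at offset x spans \code{[x - floor(w/2), x + ceiling(w/2) - 1]};
#' even windows bias 1 nt left). The raw profile is then smoothed with a
#' centered running mean.
#'
#' @param sequences Character vector of equal-length transcript-sense
#'   sequences aligned on a common anchor.
#' @param spec A \code{\link{motif_spec}}.
#' @param offsets Integer offsets of the sequence positions relative to
#'   the anchor (default: centered, \code{-(L-1)/2 ...}).
#' @param window Sliding-window width in nt (default: the spec's, 10 for
#'   4-mers / 20 for 6-mers).
#' @param smooth Running-mean length in nt (default 5).
#' @return data.frame with \code{offset}, \code{frequency} (smoothed),
#'   \code{raw}, and \code{n_with_match} (per-offset counts, for
#'   significance testing).
#' @export
window_frequency <- function(sequences, spec, offsets = NULL,
                             window = NULL, smooth = 5) {
  if (is.character(spec)) spec <- motif_spec(spec)
  if (is.null(window)) window <- spec$window
  L <- nchar(sequences[1L])
  stopifnot(all(nchar(sequences) == L))
  if (is.null(offsets)) offsets <- seq_len(L) - 1L - floor((L - 1L) / 2)
  n <- length(sequences)
  counts <- integer(L)
  lo <- pmax(seq_len(L) - floor(window / 2), 1L)
  hi <- pmin(seq_len(L) + ceiling(window / 2) - 1L, L)
  for (s in sequences) {
    starts <- scan_motif(s, spec)
    if (length(starts) == 0L) next
    ind <- logical(L); ind[starts] <- TRUE
    cs <- cumsum(ind)
    counts <- counts + as.integer((cs[hi] - c(0L, cs)[lo]) > 0L)
  }
  raw <- counts / n
  data.frame(offset = offsets, frequency = running_mean(raw, smooth),
             raw = raw, n_with_match = counts)
}

#' Per-offset two-tailed hypergeometric significance
#'
#' Compares per-offset with-match counts between a positive and a
#' negative sequence set using the two-tailed hypergeometric (Fisher
#' exact) test.
#'
#' @param counts_positive,counts_negative Integer vectors of per-offset
#'   with-match counts (\code{n_with_match} from
#'   \code{\link{window_frequency}}).
#' @param n_positive,n_negative Set sizes.
#' @return data.frame with \code{offset} index, \code{p}, and \code{sign}
#'   (+1 where the positive set is enriched). Empty sets give NA.
#' @export
positional_hypergeom <- function(counts_positive, counts_negative,
                                 n_positive, n_negative) {
  stopifnot(length(counts_positive) == length(counts_negative))
  p <- rep(NA_real_, length(counts_positive))
  if (n_positive > 0L && n_negative > 0L) {
    for (j in seq_along(p)) {
      tab <- matrix(c(counts_positive[j], n_positive - counts_positive[j],
                      counts_negative[j], n_negative - counts_negative[j]),
                    2L)
      p[j] <- fisher.test(tab)$p.value
    }
  }
  data.frame(offset = seq_along(p),
             p = p,
             sign = sign(counts_positive / n_positive -
                           counts_negative / n_negative))
}

#' Smoothed G/C content profile
#'
#' Per-offset fraction of sequences with G or C at that position
#' (ambiguous bases excluded from numerator and denominator), smoothed
#' with a centered running mean. A/U content is its complement on the
#' ACGT alphabet.
#'
#' @param sequences Equal-length aligned transcript-sense sequences.
#' @param offsets Offsets relative to the anchor (default centered).
#' @param smooth Running-mean length (default 10).
#' @return data.frame with \code{offset}, \code{gc} (smoothed), and
#'   \code{raw}.
#' @export
gc_profile <- function(sequences, offsets = NULL, smooth = 10) {
  L <- nchar(sequences[1L])
  stopifnot(all(nchar(sequences) == L))
  if (is.null(offsets)) offsets <- seq_len(L) - 1L - floor((L - 1L) / 2)
  chars <- do.call(rbind, strsplit(normalize_motif(sequences), ""))
  gc <- colSums(chars == "G" | chars == "C")
  acgt <- colSums(matrix(chars %in% c("A", "C", "G", "T"), nrow(chars)))
  raw <- ifelse(acgt > 0, gc / acgt, NA_real_)
  data.frame(offset = offsets, gc = running_mean(raw, smooth), raw = raw)
}

#' UGUA-to-hexamer linker length distribution at bound PAS
#'
#' For each PAS with at least one focal-RBP peak within
#' \code{binding_radius}, the hexamer nearest the cleavage site within
#' \code{search_radius} is paired with its nearest upstream UGUA; the
#' linker is the count of intervening nucleotides (hexamer start minus
#' UGUA end). PAS lacking either motif (or binding) contribute nothing.
#'
#' @param pas Width-1 \code{GRanges} of PAS positions.
#' @param peaks Focal-RBP peak \code{GRanges}.
#' @param genome Named \code{DNAStringSet}.
#' @param search_radius Sequence window around the PAS scanned for motifs
#'   (default 150 nt).
#' @param binding_radius Maximum PAS-to-peak distance for a PAS to
#'   qualify (default 100 nt).
#' @param hexamer,ugua Motif patterns (defaults AWUAAA and UGUA).
#' @return List: \code{linkers} (integer vector) and \code{ecdf} (its
#'   empirical CDF; NULL when empty).
#' @export
motif_distance_distribution <- function(pas, peaks, genome,
                                        search_radius = 150,
                                        binding_radius = 100,
                                        hexamer = "AWUAAA",
                                        ugua = "UGUA") {
  hex_spec <- motif_spec(hexamer)
  ugua_spec <- motif_spec(ugua)
  ## PAS with proximal binding; peaks = NULL skips the binding filter
  if (length(pas) == 0L) return(list(linkers = integer(0), ecdf = NULL))
  if (is.null(peaks)) {
    bound <- rep(TRUE, length(pas))
  } else {
    probe <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(pas),
      IRanges::IRanges(pmax(1L, GenomicRanges::start(pas) - binding_radius),
                       GenomicRanges::start(pas) + binding_radius),
      strand = GenomicRanges::strand(pas))
    bound <- GenomicRanges::countOverlaps(probe, peaks,
                                          ignore.strand = FALSE) > 0L
  }
  linkers <- integer(0)
  for (i in which(bound)) {
    chrom <- as.character(GenomicRanges::seqnames(pas))[i]
    strand <- as.character(GenomicRanges::strand(pas))[i]
    anchor <- GenomicRanges::start(pas)[i]
    glen <- if (is.character(genome)) nchar(genome[[chrom]]) else
      length(genome[[chrom]])
    lo <- max(1L, anchor - search_radius)
    hi <- min(anchor + search_radius, glen)
    seq <- tryCatch(fetch_sequence(genome, chrom, lo, hi, strand),
                    error = function(e) NULL)
    if (is.null(seq)) next
    ## 1-based positions within seq; transcript orientation already
    hex_starts <- scan_motif(seq, hex_spec)
    ugua_starts <- scan_motif(seq, ugua_spec)
    if (length(hex_starts) == 0L || length(ugua_starts) == 0L) next
    center <- if (strand == "+") anchor - lo + 1L else hi - anchor + 1L
    hx <- hex_starts[which.min(abs(hex_starts - center))]
    ugua_end <- ugua_starts + nchar(ugua_spec$pattern) - 1L
    up <- ugua_end[ugua_end < hx]
    if (length(up) == 0L) next
    linkers <- c(linkers, hx - max(up) - 1L)
  }
  list(linkers = linkers,
       ecdf = if (length(linkers)) ecdf(linkers) else NULL)
}
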