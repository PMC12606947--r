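## Small shared numerics.

#' Centered running mean with shrunken edge windows
#'
#' A window of length \code{k} at index \code{i} spans
#' \code{[i - floor(k/2), i + ceiling(k/2) - 1]} (even windows bias 1 left),
#' clipped at the vector edges so every position gets a mean over the
#' positions actually available.
#'
#' @param x Numeric vector (NAs propagate as missing within a window).
#' @param k Window length in positions; \code{k = 1} returns \code{x}.
#' @return Numeric vector, same length as \code{x}.
#' @export
running_mean <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  lo <- pmax(seq_len(n) - floor(k / 2), 1L)
  hi <- pmin(seq_len(n) + ceiling(k / 2) - 1L, n)
  cs <- cumsum(ifelse(is.na(x), 0, x))
  cnt <- cumsum(!is.na(x))
  num <- cs[hi] - c(0, cs)[lo]
  den <- cnt[hi] - c(0, cnt)[lo]
  ifelse(den > 0, num / den, NA_real_)
}

## transcript-orientation offset of genomic position(s) from an anchor;
## all arguments recycle
transcript_offset <- function(pos, anchor, strand) {
  n <- max(length(pos), length(anchor), length(strand))
  plus <- rep_len(strand == "+", n)
  pos <- rep_len(pos, n); anchor <- rep_len(anchor, n)
  ifelse(plus, pos - anchor, anchor - pos)
}

## genomic position of transcript-orientation offset(s) from an anchor
genomic_position <- function(offset, anchor, strand) {
  n <- max(length(offset), length(anchor), length(strand))
  plus <- rep_len(strand == "+", n)
  offset <- rep_len(offset, n); anchor <- rep_len(anchor, n)
  ifelse(plus, anchor + offset, anchor - offset)
}

## normalize an RNA/DNA motif to uppercase DNA (U -> T)
normalize_motif <- function(pattern) {
  gsub("U", "T", toupper(pattern))
}

## leading run length of a given base
leading_run <- function(seq, base = "A") {
  chars <- strsplit(seq, "")[[1]]
  mism <- which(chars != base)
  if (length(mism) == 0L) length(chars) else mism[1L] - 1L
}
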