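## Downstream extension of gene ends for peak calling near cleavage sites.

#' Extend gene 3' ends downstream
#'
#' Adds \code{extension} nt on the transcript 3' side of every gene (plus
#' strand: end grows; minus strand: start shrinks, floored at 1). When the
#' added extension overlaps a downstream same-strand gene, the record is
#' flagged and its id gains the suffix \code{"_overlapping<GENE_ID>"} so
#' potentially mis-assigned signal can be filtered out.
#'
#' @param genes \code{GRanges} with a \code{gene_id} metadata column.
#' @param extension Extension length in nt (default 500).
#' @return \code{GRanges} of extended intervals with metadata
#'   \code{gene_id} (suffixed where flagged), \code{original_start},
#'   \code{original_end}, \code{overlap_flag} (downstream gene id or NA),
#'   and attribute \code{extended = TRUE}. Extending an already-extended
#'   set is refused.
#' @export
extend_gene_ends <- function(genes, extension = 500) {
  if (isTRUE(S4Vectors::metadata(genes)$extended)) {
    stop("genes are already extended; refusing to extend twice")
  }
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  new_start <- ifelse(plus, GenomicRanges::start(genes),
                      pmax(1L, GenomicRanges::start(genes) - extension))
  new_end <- ifelse(plus, GenomicRanges::end(genes) + extension,
                    GenomicRanges::end(genes))
  ext <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                IRanges::IRanges(new_start, new_end),
                                strand = GenomicRanges::strand(genes))
  ext$gene_id <- genes$gene_id
  ext$original_start <- GenomicRanges::start(genes)
  ext$original_end <- GenomicRanges::end(genes)
  ext$overlap_flag <- NA_character_

  ## the added region only
  added <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(ifelse(plus, GenomicRanges::end(genes) + 1L, new_start),
                     ifelse(plus, new_end,
                            pmax(1L, GenomicRanges::start(genes) - 1L))),
    strand = GenomicRanges::strand(genes))
  ok <- GenomicRanges::width(added) > 0 &
    GenomicRanges::start(added) <= GenomicRanges::end(added)
  hits <- GenomicRanges::findOverlaps(added, genes, ignore.strand = FALSE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  keep <- q != s & ok[q]
  for (i in which(keep)) {
    if (is.na(ext$overlap_flag[q[i]])) {
      ext$overlap_flag[q[i]] <- genes$gene_id[s[i]]
      ext$gene_id[q[i]] <- paste0(genes$gene_id[q[i]], "_overlapping",
                                  genes$gene_id[s[i]])
    }
  }
  S4Vectors::metadata(ext)$extended <- TRUE
  S4Vectors::metadata(ext)$extension <- extension
  ext
}

#' Fraction of peaks inside flagged overlap regions
#'
#' @param peaks Peak \code{GRanges}.
#' @param extended Output of \code{\link{extend_gene_ends}}.
#' @return List with \code{count} and \code{fraction} of peaks whose
#'   interval intersects any flagged extension region.
#' @export
flag_overlap_peaks <- function(peaks, extended) {
  flagged <- extended[!is.na(extended$overlap_flag)]
  if (length(flagged) == 0L || length(peaks) == 0L) {
    return(list(count = 0L, fraction = 0))
  }
  plus <- as.character(GenomicRanges::strand(flagged)) == "+"
  region <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(flagged),
    IRanges::IRanges(ifelse(plus, flagged$original_end + 1L,
                            GenomicRanges::start(flagged)),
                     ifelse(plus, GenomicRanges::end(flagged),
                            flagged$original_start - 1L)),
    strand = GenomicRanges::strand(flagged))
  n <- sum(GenomicRanges::countOverlaps(peaks, region,
                                        ignore.strand = TRUE) > 0L)
  list(count = n, fraction = n / length(peaks))
}
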