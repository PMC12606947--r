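## Readers/writers for the plain-text formats the pipeline touches, plus
## sequence access. Files are BED-convention (0-based half-open); in-memory
## intervals are GRanges (1-based closed).

#' Read a BED6 file into a GRanges
#'
#' @param path Path to a tab-delimited BED6 file (chrom, start, end, name,
#'   score, strand; 0-based half-open).
#' @return A \code{GRanges} with metadata columns \code{name} and
#'   \code{score}, in file order.
#' @details Malformed lines (wrong field count, non-numeric coordinates,
#'   \code{start >= end}, unknown strand) raise an error naming the
#'   offending line number.
#' @export
read_bed6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_granges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("malformed BED6 line ", which(nf < 6L)[1L], " in ", path,
         ": expected >= 6 tab-separated fields")
  }
  mat <- t(vapply(fields, function(f) f[1:6], character(6)))
  start0 <- suppressWarnings(as.numeric(mat[, 2L]))
  end0 <- suppressWarnings(as.numeric(mat[, 3L]))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) {
    stop("malformed BED6 line ", bad[1L], " in ", path,
         ": non-numeric coordinates")
  }
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad)) {
    stop("malformed BED6 line ", bad[1L], " in ", path,
         ": requires 0 <= start < end")
  }
  strand <- mat[, 6L]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    stop("malformed BED6 line ", bad[1L], " in ", path,
         ": unknown strand '", strand[bad[1L]], "'")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = mat[, 1L],
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand
  )
  gr$name <- mat[, 4L]
  gr$score <- suppressWarnings(as.numeric(mat[, 5L]))
  gr
}

#' Write a GRanges as BED6
#'
#' @param gr A \code{GRanges}; metadata columns \code{name} and \code{score}
#'   are used when present.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bed6 <- function(gr, path) {
  name <- if (!is.null(gr$name)) gr$name else rep(".", length(gr))
  score <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = name, score = score,
    strand = as.character(GenomicRanges::strand(gr))
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a reference PAS site list (BED-derived, single positions)
#'
#' @param path BED file whose intervals are 1-nt cleavage positions
#'   (0-based half-open, so \code{end = start + 1}).
#' @return A \code{GRanges} of width-1 sites.
#' @export
read_pas_sites <- function(path) {
  gr <- read_bed6(path)
  if (length(gr) && any(GenomicRanges::width(gr) != 1L)) {
    stop("reference PAS sites must be single positions (width 1)")
  }
  gr
}

#' Read a terminal-exon annotation table
#'
#' Tab-delimited with header columns \code{gene_id}, \code{chrom},
#' \code{start}, \code{end}, \code{strand} and optional \code{cds_end}
#' (all coordinates BED-convention 0-based half-open; \code{cds_end} a
#' 0-based position inside the exon marking the 3'UTR start).
#'
#' @param path Path to the table.
#' @return A \code{GRanges} with metadata columns \code{gene_id} and
#'   \code{cds_end} (1-based position or \code{NA}).
#' @export
read_exon_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    stop("exon table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$start >= df$end)) {
    stop("malformed exon table line ",
         which(df$start >= df$end)[1L] + 1L, ": start >= end")
  }
  if (any(!df$strand %in% c("+", "-"))) {
    stop("malformed exon table line ",
         which(!df$strand %in% c("+", "-"))[1L] + 1L, ": unknown strand")
  }
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = df$strand)
  gr$gene_id <- df$gene_id
  gr$cds_end <- if ("cds_end" %in% names(df)) {
    ifelse(is.na(df$cds_end), NA_integer_, as.integer(df$cds_end) + 1L)
  } else NA_integer_
  bad <- which(!is.na(gr$cds_end) &
                 (gr$cds_end < GenomicRanges::start(gr) |
                    gr$cds_end > GenomicRanges::end(gr)))
  if (length(bad)) {
    stop("malformed exon table line ", bad[1L] + 1L,
         ": cds_end outside exon")
  }
  gr
}

#' Write a terminal-exon annotation table
#' @param exons GRanges with \code{gene_id} and optional \code{cds_end}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_exon_table <- function(exons, path) {
  df <- data.frame(
    gene_id = exons$gene_id,
    chrom = as.character(GenomicRanges::seqnames(exons)),
    start = GenomicRanges::start(exons) - 1L,
    end = GenomicRanges::end(exons),
    strand = as.character(GenomicRanges::strand(exons)),
    cds_end = if (!is.null(exons$cds_end)) exons$cds_end - 1L else NA
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a strand-split bedGraph pair into a coverage track
#'
#' 3' end coverage is stored per position. bedGraph records (0-based
#' half-open) are expanded to per-position counts; overlapping records sum.
#'
#' @param plus_path bedGraph of the plus strand.
#' @param minus_path bedGraph of the minus strand.
#' @param sample_id Identifier attached to the track.
#' @return A coverage track: \code{data.frame(chrom, strand, pos, count)}
#'   with 1-based positions, zero-count positions absent, and attribute
#'   \code{sample_id}.
#' @export
read_coverage <- function(plus_path, minus_path, sample_id = "sample") {
  parse_one <- function(path, strand) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
    if (length(lines) == 0L) {
      return(data.frame(chrom = character(), strand = character(),
                        pos = integer(), count = numeric()))
    }
    fields <- strsplit(lines, "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 4L)) {
      stop("malformed bedGraph line ", which(nf < 4L)[1L], " in ", path)
    }
    mat <- t(vapply(fields, function(f) f[1:4], character(4)))
    start0 <- as.numeric(mat[, 2L]); end0 <- as.numeric(mat[, 3L])
    val <- as.numeric(mat[, 4L])
    if (any(is.na(start0) | is.na(end0) | is.na(val))) {
      stop("malformed bedGraph line ",
           which(is.na(start0) | is.na(end0) | is.na(val))[1L], " in ", path)
    }
    if (any(val < 0)) {
      stop("negative coverage value at bedGraph line ",
           which(val < 0)[1L], " in ", path)
    }
    w <- end0 - start0
    pos <- sequence(w, from = start0 + 1L)  # expand to 1-based positions
    data.frame(chrom = rep(mat[, 1L], w), strand = strand,
               pos = as.integer(pos), count = rep(val, w))
  }
  df <- rbind(parse_one(plus_path, "+"), parse_one(minus_path, "-"))
  df <- collapse_coverage(df)
  attr(df, "sample_id") <- sample_id
  df
}

## sum duplicate (chrom,strand,pos) rows and sort
collapse_coverage <- function(df) {
  if (nrow(df) == 0L) return(df)
  key <- paste(df$chrom, df$strand, df$pos, sep = "\r")
  agg <- rowsum(df$count, key, reorder = FALSE)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    strand = vapply(parts, `[`, "", 2L),
    pos = as.integer(vapply(parts, `[`, "", 3L)),
    count = as.numeric(agg[, 1L])
  )
  out <- out[out$count > 0, , drop = FALSE]
  out <- out[order(out$chrom, out$strand, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a coverage track as a strand-split bedGraph pair
#'
#' Adjacent positions with equal counts are merged into single bedGraph
#' records, so write/read round-trips are exact.
#'
#' @param track A coverage track as returned by \code{\link{read_coverage}}.
#' @param plus_path,minus_path Output paths.
#' @return The two paths, invisibly.
#' @export
write_coverage <- function(track, plus_path, minus_path) {
  write_one <- function(df, path) {
    if (nrow(df) == 0L) { writeLines(character(), path); return() }
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    new_run <- c(TRUE, df$chrom[-1L] != df$chrom[-nrow(df)] |
                   df$pos[-1L] != df$pos[-nrow(df)] + 1L |
                   df$count[-1L] != df$count[-nrow(df)])
    run <- cumsum(new_run)
    out <- data.frame(
      chrom = df$chrom[new_run],
      start = df$pos[new_run] - 1L,
      end = tapply(df$pos, run, max),
      count = df$count[new_run]
    )
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  write_one(track[track$strand == "+", , drop = FALSE], plus_path)
  write_one(track[track$strand == "-", , drop = FALSE], minus_path)
  invisible(c(plus_path, minus_path))
}

#' Sum coverage tracks across samples
#' @param tracks List of coverage tracks.
#' @return A combined coverage track (no \code{sample_id}).
#' @export
combine_coverage <- function(tracks) {
  collapse_coverage(do.call(rbind, tracks))
}

#' Fetch the transcript-sense sequence of an interval
#'
#' @param genome A named \code{DNAStringSet} (or named character vector of
#'   sequences). U is treated as T on input.
#' @param chrom,start,end,strand Interval (1-based closed). Minus-strand
#'   requests return the reverse complement.
#' @return Uppercase DNA character string.
#' @export
fetch_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(gsub("U", "T", toupper(genome)))
  }
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  n <- length(genome[[chrom]])
  if (start < 1L || end > n || start > end) {
    stop("interval [", start, ",", end, "] out of bounds for ", chrom,
         " (length ", n, ")")
  }
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

#' Read a transcript expression table
#'
#' Tab-delimited with header: \code{transcript_id}, \code{chrom},
#' \code{start}, \code{end}, \code{strand} (the 3'UTR interval,
#' BED-convention), then one \code{tpm_*} column per control sample.
#'
#' @param path Path to the table.
#' @return A list with \code{utr} (GRanges, metadata \code{transcript_id})
#'   and \code{tpm} (numeric matrix, rows = transcripts).
#' @export
read_expression_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  tpm_cols <- grep("^tpm", names(df), value = TRUE)
  if (length(tpm_cols) == 0L) stop("expression table has no tpm_* columns")
  tpm <- as.matrix(df[, tpm_cols, drop = FALSE])
  if (any(tpm < 0)) stop("negative TPM values")
  utr <- GenomicRanges::GRanges(df$chrom,
                                IRanges::IRanges(df$start + 1L, df$end),
                                strand = df$strand)
  utr$transcript_id <- df$transcript_id
  rownames(tpm) <- df$transcript_id
  list(utr = utr, tpm = tpm)
}

#' Read a DMS accessibility track
#'
#' Tab-delimited with header: \code{chrom}, \code{pos} (0-based),
#' \code{strand}, \code{base} (transcript-sense), \code{coverage},
#' \code{rate}.
#'
#' @param path Path to the table.
#' @return \code{data.frame(chrom, pos, strand, base, coverage, rate)} with
#'   1-based positions.
#' @export
read_dms_track <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (any(df$rate < 0 | df$rate > 1)) {
    stop("DMS mutation rates must lie in [0,1]")
  }
  if (any(df$coverage < 0)) stop("negative DMS coverage")
  df$pos <- as.integer(df$pos) + 1L
  df
}

#' Write a DMS accessibility track
#' @param dms A track as returned by \code{\link{read_dms_track}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_dms_track <- function(dms, path) {
  out <- dms
  out$pos <- out$pos - 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Strand-aware overlap query
#'
#' @param subject GRanges to search.
#' @param probe A single-interval GRanges (or one expressible as such).
#' @param same_strand Restrict hits to the probe's strand?
#' @return The subset of \code{subject} sharing at least one base with
#'   \code{probe}.
#' @export
overlap_query <- function(subject, probe, same_strand = FALSE) {
  hits <- GenomicRanges::findOverlaps(
    probe, subject,
    ignore.strand = !same_strand
  )
  subject[unique(S4Vectors::subjectHits(hits))]
}

empty_granges <- function() {
  gr <- GenomicRanges::GRanges()
  gr$name <- character()
  gr$score <- numeric()
  gr
}
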