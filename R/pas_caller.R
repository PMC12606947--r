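## 3' end cluster calling, PAS assignment, internal-priming / hexamer /
## reference filters, terminal-exon assignment, and relative usage.
##
## Coverage tracks hold per-position 3' end read counts (the read 3' end
## marks the cleavage site). Cluster definition uses the coverage summed
## over all samples so cluster boundaries are shared across samples.

#' Call 3' end clusters from combined coverage
#'
#' Clusters are maximal runs of adjacent positions whose combined
#' (all-sample) count exceeds \code{min_per_position}; clusters with fewer
#' than \code{min_total} reads across all samples are dropped, or flagged
#' \code{fail_low_total} when \code{keep_filtered} is set.
#'
#' @param combined Combined coverage track (\code{\link{combine_coverage}}).
#' @param min_per_position Positions must exceed this count (default 10) to
#'   enter a cluster.
#' @param min_total Minimum summed reads per retained cluster (default 20).
#' @param keep_filtered Keep sub-threshold clusters with a flag instead of
#'   dropping them?
#' @return A \code{GRanges} of clusters with metadata columns \code{total}
#'   (combined reads) and \code{flags} (character; "" = clean).
#' @export
call_clusters <- function(combined, min_per_position = 10, min_total = 20,
                          keep_filtered = FALSE) {
  out <- list()
  df <- combined[combined$count > min_per_position, , drop = FALSE]
  if (nrow(df)) {
    df <- df[order(df$chrom, df$strand, df$pos), , drop = FALSE]
    new_run <- c(TRUE, df$chrom[-1L] != df$chrom[-nrow(df)] |
                   df$strand[-1L] != df$strand[-nrow(df)] |
                   df$pos[-1L] != df$pos[-nrow(df)] + 1L)
    run <- cumsum(new_run)
    start <- df$pos[new_run]
    end <- as.integer(tapply(df$pos, run, max))
    total <- as.numeric(tapply(df$count, run, sum))
    gr <- GenomicRanges::GRanges(df$chrom[new_run],
                                 IRanges::IRanges(start, end),
                                 strand = df$strand[new_run])
    gr$total <- total
    gr$flags <- ifelse(total < min_total, "fail_low_total", "")
    if (!keep_filtered) gr <- gr[gr$flags == ""]
    return(gr)
  }
  gr <- GenomicRanges::GRanges()
  gr$total <- numeric()
  gr$flags <- character()
  gr
}

#' Assign the PAS position of each cluster
#'
#' The PAS is the position of highest combined coverage within the cluster;
#' ties go to the 3'-most position in transcript orientation (largest
#' coordinate on the plus strand, smallest on the minus strand).
#'
#' @param clusters Cluster \code{GRanges} from \code{\link{call_clusters}}.
#' @param combined The combined coverage track used to call them.
#' @return \code{clusters} with an added integer metadata column \code{pas}.
#' @export
assign_pas <- function(clusters, combined) {
  if (length(clusters) == 0L) {
    clusters$pas <- integer()
    return(clusters)
  }
  key <- paste(combined$chrom, combined$strand, combined$pos, sep = "\r")
  cnt <- setNames(combined$count, key)
  pas <- integer(length(clusters))
  for (i in seq_along(clusters)) {
    pos <- GenomicRanges::start(clusters)[i]:GenomicRanges::end(clusters)[i]
    k <- paste(as.character(GenomicRanges::seqnames(clusters))[i],
               as.character(GenomicRanges::strand(clusters))[i], pos,
               sep = "\r")
    v <- cnt[k]
    v[is.na(v)] <- 0
    best <- pos[v == max(v)]
    pas[i] <- if (as.character(GenomicRanges::strand(clusters))[i] == "+")
      max(best) else min(best)
  }
  clusters$pas <- pas
  clusters
}

add_flag <- function(flags, new, add) {
  ifelse(add, ifelse(nzchar(flags), paste(flags, new, sep = ","), new),
         flags)
}

has_flag <- function(flags, what) {
  vapply(strsplit(flags, ",", fixed = TRUE),
         function(f) what %in% f, logical(1))
}

#' Flag likely internal-priming clusters
#'
#' Two genomic-sequence heuristics against oligo-dT mispriming on A-rich
#' genomic stretches: \code{fail_consecutive_A} when more than 6
#' consecutive genome-templated adenosines (transcript sense) directly
#' follow the assigned PAS, and \code{fail_A_rich_window} when more than 7
#' of the 10 nt directly downstream of the cluster's 3' boundary are
#' adenosines.
#'
#' @param clusters Clusters with a \code{pas} column.
#' @param genome Named \code{DNAStringSet}.
#' @return \code{clusters} with updated \code{flags}.
#' @export
filter_internal_priming <- function(clusters, genome) {
  if (length(clusters) == 0L) return(clusters)
  consec <- logical(length(clusters))
  window <- logical(length(clusters))
  for (i in seq_along(clusters)) {
    chrom <- as.character(GenomicRanges::seqnames(clusters))[i]
    strand <- as.character(GenomicRanges::strand(clusters))[i]
    pas <- clusters$pas[i]
    ## downstream of the PAS, transcript orientation
    ds <- if (strand == "+") {
      fetch_sequence(genome, chrom, pas + 1L, pas + 10L, "+")
    } else {
      fetch_sequence(genome, chrom, pas - 10L, pas - 1L, "-")
    }
    consec[i] <- leading_run(ds, "A") > 6L
    ## 10 nt downstream of the cluster 3' boundary
    w <- if (strand == "+") {
      b <- GenomicRanges::end(clusters)[i]
      fetch_sequence(genome, chrom, b + 1L, b + 10L, "+")
    } else {
      b <- GenomicRanges::start(clusters)[i]
      fetch_sequence(genome, chrom, b - 10L, b - 1L, "-")
    }
    window[i] <- sum(strsplit(w, "")[[1]] == "A") > 7L
  }
  flags <- add_flag(clusters$flags, "fail_consecutive_A", consec)
  clusters$flags <- add_flag(flags, "fail_A_rich_window", window)
  clusters
}

#' Flag clusters lacking a PAS hexamer
#'
#' The sense-strand cluster sequence (optionally extended
#' \code{flank_upstream} nt on the transcript 5' side) is searched for
#' AATAAA or ATTAAA; absence flags \code{fail_no_hexamer}.
#'
#' @param clusters Clusters \code{GRanges}.
#' @param genome Named \code{DNAStringSet}.
#' @param flank_upstream Extra nt upstream of the cluster to search
#'   (default 0 = the cluster interval only).
#' @return \code{clusters} with updated \code{flags}.
#' @export
filter_hexamer <- function(clusters, genome, flank_upstream = 0) {
  if (length(clusters) == 0L) return(clusters)
  miss <- logical(length(clusters))
  for (i in seq_along(clusters)) {
    chrom <- as.character(GenomicRanges::seqnames(clusters))[i]
    strand <- as.character(GenomicRanges::strand(clusters))[i]
    s <- GenomicRanges::start(clusters)[i]
    e <- GenomicRanges::end(clusters)[i]
    if (strand == "+") s <- max(1L, s - flank_upstream) else
      e <- e + flank_upstream
    seq <- fetch_sequence(genome, chrom, s, e, strand)
    miss[i] <- !grepl("AATAAA", seq, fixed = TRUE) &&
      !grepl("ATTAAA", seq, fixed = TRUE)
  }
  clusters$flags <- add_flag(clusters$flags, "fail_no_hexamer", miss)
  clusters
}

#' Flag clusters absent from a reference PAS database
#'
#' A cluster passes iff a same-strand reference site lies within
#' \code{[start - slack, end + slack]}; otherwise it gains
#' \code{fail_not_in_reference}.
#'
#' @param clusters Clusters \code{GRanges}.
#' @param reference Width-1 \code{GRanges} of reference cleavage sites.
#' @param slack Extra nt of tolerance on each side (default 0: the site
#'   must fall within the cluster).
#' @return \code{clusters} with updated \code{flags}.
#' @export
filter_reference <- function(clusters, reference, slack = 0) {
  if (length(clusters) == 0L) return(clusters)
  probe <- clusters
  if (slack > 0) {
    probe <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(clusters),
      IRanges::IRanges(pmax(1L, GenomicRanges::start(clusters) - slack),
                       GenomicRanges::end(clusters) + slack),
      strand = GenomicRanges::strand(clusters))
  }
  hits <- GenomicRanges::countOverlaps(probe, reference,
                                       ignore.strand = FALSE)
  clusters$flags <- add_flag(clusters$flags, "fail_not_in_reference",
                             hits == 0L)
  clusters
}

#' Assign clusters to terminal exons
#'
#' A cluster is assigned iff its PAS position falls within a same-strand
#' terminal exon. If the PAS lies in the overlap of several same-strand
#' exons, the exon whose annotated 3' end is nearest downstream of the PAS
#' wins. Unassigned clusters get \code{NA} and are excluded from usage
#' analysis.
#'
#' @param clusters Clusters with a \code{pas} column.
#' @param exons Terminal-exon \code{GRanges} with \code{gene_id}.
#' @return \code{clusters} with added \code{terminal_exon_id}.
#' @export
assign_terminal_exon <- function(clusters, exons) {
  if (length(clusters) == 0L) {
    clusters$terminal_exon_id <- character()
    return(clusters)
  }
  pas_gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(clusters),
                                   IRanges::IRanges(clusters$pas,
                                                    clusters$pas),
                                   strand = GenomicRanges::strand(clusters))
  hits <- GenomicRanges::findOverlaps(pas_gr, exons, ignore.strand = FALSE)
  assigned <- rep(NA_character_, length(clusters))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  for (i in unique(q)) {
    cand <- s[q == i]
    if (length(cand) > 1L) {
      strand <- as.character(GenomicRanges::strand(clusters))[i]
      end3 <- if (strand == "+") GenomicRanges::end(exons)[cand] else
        GenomicRanges::start(exons)[cand]
      dist <- transcript_offset(end3, clusters$pas[i], strand)
      cand <- cand[which.min(dist)]  # nearest annotated 3' end downstream
    }
    assigned[i] <- exons$gene_id[cand]
  }
  clusters$terminal_exon_id <- assigned
  clusters
}

#' Count reads per cluster per sample
#'
#' @param clusters Cluster \code{GRanges}.
#' @param tracks Named list of per-sample coverage tracks.
#' @return Numeric matrix, rows = clusters, columns = samples.
#' @export
cluster_sample_counts <- function(clusters, tracks) {
  counts <- matrix(0, length(clusters), length(tracks),
                   dimnames = list(NULL, names(tracks)))
  if (length(clusters) == 0L) return(counts)
  cl_gr <- clusters
  for (s in seq_along(tracks)) {
    tr <- tracks[[s]]
    if (nrow(tr) == 0L) next
    pos_gr <- GenomicRanges::GRanges(tr$chrom,
                                     IRanges::IRanges(tr$pos, tr$pos),
                                     strand = tr$strand)
    hits <- GenomicRanges::findOverlaps(pos_gr, cl_gr,
                                        ignore.strand = FALSE)
    if (length(hits)) {
      agg <- rowsum(tr$count[S4Vectors::queryHits(hits)],
                    S4Vectors::subjectHits(hits))
      counts[as.integer(rownames(agg)), s] <-
        counts[as.integer(rownames(agg)), s] + agg[, 1L]
    }
  }
  counts
}

#' Relative PAS usage within terminal exons
#'
#' Usage of a cluster in a sample is its read count divided by the summed
#' counts of all clusters assigned to the same terminal exon in that
#' sample. Exon-sample totals of zero give missing usage (\code{NA}), not
#' zero.
#'
#' @param clusters Flag-free clusters with \code{terminal_exon_id}.
#' @param counts Matrix from \code{\link{cluster_sample_counts}}.
#' @return A \code{usage_table}: data.frame with \code{terminal_exon_id},
#'   \code{pas}, cluster index, and one usage column per sample; attribute
#'   \code{counts} keeps the raw count matrix.
#' @export
compute_relative_usage <- function(clusters, counts) {
  keep <- !is.na(clusters$terminal_exon_id)
  clusters <- clusters[keep]
  counts <- counts[keep, , drop = FALSE]
  usage <- counts
  if (length(clusters)) {
    for (exon in unique(clusters$terminal_exon_id)) {
      idx <- which(clusters$terminal_exon_id == exon)
      tot <- colSums(counts[idx, , drop = FALSE])
      u <- sweep(counts[idx, , drop = FALSE], 2L, tot, "/")
      u[, tot == 0] <- NA_real_
      usage[idx, ] <- u
    }
  }
  out <- data.frame(terminal_exon_id = clusters$terminal_exon_id,
                    pas = clusters$pas,
                    strand = as.character(GenomicRanges::strand(clusters)),
                    cluster = seq_along(clusters))
  out <- cbind(out, as.data.frame(usage))
  attr(out, "counts") <- counts
  attr(out, "samples") <- colnames(counts)
  class(out) <- c("usage_table", "data.frame")
  out
}

#' Run the full cluster-calling and filtering funnel
#'
#' Applies, in order: cluster calling (per-position and total thresholds),
#' PAS assignment, internal-priming filters, hexamer filter, reference
#' filter, and terminal-exon assignment, accumulating flags so any subset
#' can be reported. The returned object keeps all clusters; \code{clean}
#' selects the flag-free, exon-assigned subset.
#'
#' @param tracks Named list of per-sample coverage tracks.
#' @param genome Named \code{DNAStringSet}.
#' @param exons Terminal-exon \code{GRanges}.
#' @param reference Reference PAS site \code{GRanges}.
#' @param min_per_position,min_total,reference_slack,hexamer_flank Filter
#'   parameters (defaults: 10 reads per position, 20 total, slack 0,
#'   strict-cluster hexamer search).
#' @return A list of class \code{pas_call_result}: \code{clusters} (all,
#'   flagged), \code{counts}, \code{usage} (clean subset), \code{funnel}
#'   (named counts surviving each stage).
#' @export
call_pas_clusters <- function(tracks, genome, exons, reference,
                              min_per_position = 10, min_total = 20,
                              reference_slack = 0, hexamer_flank = 0) {
  combined <- combine_coverage(tracks)
  clusters <- call_clusters(combined, min_per_position, min_total,
                            keep_filtered = TRUE)
  clusters <- assign_pas(clusters, combined)
  clusters <- filter_internal_priming(clusters, genome)
  clusters <- filter_hexamer(clusters, genome, hexamer_flank)
  clusters <- filter_reference(clusters, reference, reference_slack)
  clusters <- assign_terminal_exon(clusters, exons)

  funnel <- c(
    called = length(clusters),
    pass_total = sum(!has_flag(clusters$flags, "fail_low_total")),
    pass_internal_priming = sum(
      !has_flag(clusters$flags, "fail_low_total") &
        !has_flag(clusters$flags, "fail_consecutive_A") &
        !has_flag(clusters$flags, "fail_A_rich_window")),
    pass_hexamer = NA, pass_reference = NA, assigned = NA
  )
  cum <- !has_flag(clusters$flags, "fail_low_total") &
    !has_flag(clusters$flags, "fail_consecutive_A") &
    !has_flag(clusters$flags, "fail_A_rich_window")
  cum <- cum & !has_flag(clusters$flags, "fail_no_hexamer")
  funnel["pass_hexamer"] <- sum(cum)
  cum <- cum & !has_flag(clusters$flags, "fail_not_in_reference")
  funnel["pass_reference"] <- sum(cum)
  funnel["assigned"] <- sum(cum & !is.na(clusters$terminal_exon_id))

  clean <- clusters[clusters$flags == "" & !is.na(clusters$terminal_exon_id)]
  counts <- cluster_sample_counts(clean, tracks)
  usage <- compute_relative_usage(clean, counts)

  out <- list(clusters = clusters, clean = clean, counts = counts,
              usage = usage, funnel = funnel)
  class(out) <- "pas_call_result"
  out
}

#' @export
print.pas_call_result <- function(x, ...) {
  cat("PAS cluster calls\n")
  cat("  funnel:",
      paste(names(x$funnel), x$funnel, sep = "=", collapse = ", "), "\n")
  cat("  clean clusters:", length(x$clean), "in",
      length(unique(x$clean$terminal_exon_id)), "terminal exons\n")
  invisible(x)
}
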