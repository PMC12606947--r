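## APA change calling from replicate usage tables, dPDUI classification,
## compartment comparison, and overlap statistics.

#' Classify a DaPars-style dPDUI table into event sets
#'
#' dPDUI follows the control-minus-knockdown convention for distal usage,
#' so positive values mean the knockdown shifts expression toward the
#' proximal PAS (the RBP lengthens the 3'UTR). Changing events need
#' |dPDUI| >= \code{change_thresh} with adjusted p < \code{alpha};
#' non-changing events need |dPDUI| < \code{null_thresh} with adjusted
#' p > \code{alpha}; everything else is unclassified.
#'
#' @param table data.frame with columns \code{gene_id}, \code{pPAS},
#'   \code{dPAS}, \code{dPDUI}, \code{adjusted_p}.
#' @param change_thresh Absolute dPDUI needed for a change (default 0.20).
#' @param null_thresh Absolute dPDUI bound for non-changing (default 0.05).
#' @param alpha Adjusted p-value threshold (default 0.05).
#' @return The table with an added \code{label} column, one of
#'   \code{lengthened_by_RBP}, \code{shortened_by_RBP},
#'   \code{non_changing}, \code{unclassified}; class \code{event_sets}.
#'   Rows with missing p are dropped with a warning.
#' @export
classify_dpdui <- function(table, change_thresh = 0.20, null_thresh = 0.05,
                           alpha = 0.05) {
  miss <- is.na(table$adjusted_p) | is.na(table$dPDUI)
  if (any(miss)) {
    warning(sum(miss), " rows with missing dPDUI or adjusted p skipped")
    table <- table[!miss, , drop = FALSE]
  }
  d <- table$dPDUI
  p <- table$adjusted_p
  label <- rep("unclassified", nrow(table))
  label[d >= change_thresh & p < alpha] <- "lengthened_by_RBP"
  label[d <= -change_thresh & p < alpha] <- "shortened_by_RBP"
  label[abs(d) < null_thresh & p > alpha] <- "non_changing"
  table$label <- label
  class(table) <- c("event_sets", "data.frame")
  table
}

## per-cluster KD-minus-control usage deltas, one column per replicate pair
usage_deltas <- function(usage, pairing) {
  samples <- attr(usage, "samples")
  miss <- setdiff(unlist(pairing), samples)
  if (length(miss)) {
    stop("unpaired or unknown samples in pairing: ",
         paste(miss, collapse = ", "))
  }
  deltas <- vapply(pairing, function(p) {
    usage[[p["kd"]]] - usage[[p["control"]]]
  }, numeric(nrow(usage)))
  if (nrow(usage) == 1L) deltas <- matrix(deltas, nrow = 1L)
  deltas
}

#' Call per-PAS usage changes from replicate pairs
#'
#' A cluster is called increased (decreased) when at least
#' \code{n_support} replicate knockdown-minus-control usage deltas are
#' >= \code{delta_thresh} (<= -\code{delta_thresh}) and no replicate moves
#' in the opposite direction by more than \code{opposite_tolerance}.
#' Missing deltas (zero-coverage exon-samples) neither support nor
#' disqualify.
#'
#' @param usage A \code{usage_table} from
#'   \code{\link{compute_relative_usage}}.
#' @param pairing List of named character vectors
#'   \code{c(kd = , control = )}, one per replicate pair.
#' @param delta_thresh Minimum usage change (default 0.10).
#' @param n_support Replicates required in the same direction (default 2).
#' @param opposite_tolerance Largest tolerated opposite-direction delta
#'   (default 0: any opposite-sign delta disqualifies).
#' @return data.frame with \code{terminal_exon_id}, \code{pas}, per-pair
#'   deltas, and \code{status} in \{increased, decreased, not_called\}.
#' @export
call_pas_changes <- function(usage, pairing, delta_thresh = 0.10,
                             n_support = 2, opposite_tolerance = 0.0) {
  deltas <- usage_deltas(usage, pairing)
  status <- apply(deltas, 1L, function(d) {
    d <- d[!is.na(d)]
    if (length(d) < n_support) return("not_called")
    up <- sum(d >= delta_thresh)
    dn <- sum(d <= -delta_thresh)
    any_neg <- any(d < -opposite_tolerance)
    any_pos <- any(d > opposite_tolerance)
    if (up >= n_support && !any_neg) "increased"
    else if (dn >= n_support && !any_pos) "decreased"
    else "not_called"
  })
  out <- data.frame(terminal_exon_id = usage$terminal_exon_id,
                    pas = usage$pas,
                    strand = if (!is.null(usage$strand)) usage$strand
                    else "+")
  colnames(deltas) <- paste0("delta_rep", seq_len(ncol(deltas)))
  out <- cbind(out, as.data.frame(deltas))
  out$status <- status
  out
}

#' Confidently non-changing terminal exons
#'
#' An exon qualifies when every sample's exon read total is at least
#' \code{min_reads} and no PAS usage changes by more than \code{max_delta}
#' in any replicate pair.
#'
#' @param usage A \code{usage_table}.
#' @param pairing Replicate pairing as in \code{\link{call_pas_changes}}.
#' @param min_reads Minimum exon total per sample (default 10).
#' @param max_delta Largest tolerated usage change (default 0.05).
#' @return Character vector of terminal-exon ids.
#' @export
call_nonchanging <- function(usage, pairing, min_reads = 10,
                             max_delta = 0.05) {
  counts <- attr(usage, "counts")
  deltas <- usage_deltas(usage, pairing)
  ok <- logical(0)
  exons <- unique(usage$terminal_exon_id)
  keep <- vapply(exons, function(exon) {
    idx <- which(usage$terminal_exon_id == exon)
    tot <- colSums(counts[idx, , drop = FALSE])
    if (any(tot < min_reads)) return(FALSE)
    d <- deltas[idx, , drop = FALSE]
    all(is.na(d) | abs(d) <= max_delta)
  }, logical(1))
  exons[keep]
}

## per-exon direction of the distal PAS (3'-most) change, for compartment
## and overlap comparisons: "lengthened" when distal usage rises in KD
exon_change_direction <- function(changes, usage) {
  called <- changes[changes$status != "not_called", , drop = FALSE]
  if (nrow(called) == 0L) {
    return(data.frame(terminal_exon_id = character(),
                      direction = character()))
  }
  out <- lapply(split(called, called$terminal_exon_id), function(df) {
    ## distal = 3'-most called PAS of the exon (strand-aware)
    i <- if (df$strand[1L] == "+") which.max(df$pas) else which.min(df$pas)
    data.frame(terminal_exon_id = df$terminal_exon_id[1L],
               direction = ifelse(df$status[i] == "increased",
                                  "lengthened", "shortened"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare APA calls between cellular compartments
#'
#' @param calls_a,calls_b Change-call tables from
#'   \code{\link{call_pas_changes}} for the two compartments (e.g. nuclear
#'   and cytoplasmic).
#' @param nonchanging_a,nonchanging_b Confident non-changing exon ids from
#'   \code{\link{call_nonchanging}}.
#' @param usage_a,usage_b The usage tables the calls came from (used to
#'   orient the distal PAS).
#' @return List of exon-id vectors: \code{shared} (significant and
#'   same-direction in both), \code{a_specific}, \code{b_specific}
#'   (significant in one, confidently non-changing in the other).
#' @export
compare_compartments <- function(calls_a, calls_b,
                                 nonchanging_a, nonchanging_b,
                                 usage_a, usage_b) {
  dir_a <- exon_change_direction(calls_a, usage_a)
  dir_b <- exon_change_direction(calls_b, usage_b)
  m <- merge(dir_a, dir_b, by = "terminal_exon_id",
             suffixes = c("_a", "_b"))
  shared <- m$terminal_exon_id[m$direction_a == m$direction_b]
  a_specific <- setdiff(intersect(dir_a$terminal_exon_id, nonchanging_b),
                        dir_b$terminal_exon_id)
  b_specific <- setdiff(intersect(dir_b$terminal_exon_id, nonchanging_a),
                        dir_a$terminal_exon_id)
  list(shared = shared, a_specific = a_specific, b_specific = b_specific)
}

#' Overlap statistics between two target gene sets
#'
#' @param set_a,set_b Character vectors of gene ids, subsets of
#'   \code{universe}.
#' @param universe Jointly quantified genes.
#' @param directions_a,directions_b Optional named direction vectors
#'   (names = gene ids) used for the same-direction fraction.
#' @return List: \code{fisher_p} (two-tailed Fisher exact on the 2x2
#'   membership table), \code{jaccard}, \code{same_direction_fraction}
#'   (NA when directions are absent or the intersection is empty), and
#'   the 2x2 \code{table}.
#' @export
overlap_stats <- function(set_a, set_b, universe,
                          directions_a = NULL, directions_b = NULL) {
  stopifnot(all(set_a %in% universe), all(set_b %in% universe))
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)))
  fisher_p <- fisher.test(tab)$p.value
  inter <- intersect(set_a, set_b)
  uni <- union(set_a, set_b)
  jaccard <- if (length(uni)) length(inter) / length(uni) else NA_real_
  same_dir <- NA_real_
  if (!is.null(directions_a) && !is.null(directions_b) && length(inter)) {
    same_dir <- mean(directions_a[inter] == directions_b[inter])
  }
  list(fisher_p = fisher_p, jaccard = jaccard,
       same_direction_fraction = same_dir, table = tab)
}
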