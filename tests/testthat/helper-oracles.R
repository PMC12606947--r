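# Independent brute-force oracles used to check the package's
# implementations, plus small fixture builders. The oracles deliberately
# share no code with the functions they check.

# coverage track from a named count vector (names = positions, one chrom)
cov_track <- function(counts, chrom = "chr1", strand = "+",
                      sample_id = "s1") {
  df <- data.frame(chrom = chrom, strand = strand,
                   pos = as.integer(names(counts)),
                   count = as.numeric(counts))
  df <- df[df$count > 0, , drop = FALSE]
  attr(df, "sample_id") <- sample_id
  df
}

gr <- function(chrom, start, end, strand = "+", ...) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                              strand = strand)
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(g)[[nm]] <- extra[[nm]]
  g
}

# brute-force cluster scan: walk positions one by one
oracle_clusters <- function(counts_by_pos, min_per_position = 10,
                            min_total = 20) {
  pos <- as.integer(names(counts_by_pos))
  cnt <- as.numeric(counts_by_pos)
  keep <- cnt > min_per_position
  clusters <- list()
  cur <- NULL
  for (i in order(pos)) {
    if (!keep[i]) { if (!is.null(cur)) clusters <- c(clusters, list(cur)); cur <- NULL; next }
    if (is.null(cur)) {
      cur <- list(start = pos[i], end = pos[i], total = cnt[i])
    } else if (pos[i] == cur$end + 1L) {
      cur$end <- pos[i]; cur$total <- cur$total + cnt[i]
    } else {
      clusters <- c(clusters, list(cur))
      cur <- list(start = pos[i], end = pos[i], total = cnt[i])
    }
  }
  if (!is.null(cur)) clusters <- c(clusters, list(cur))
  clusters <- Filter(function(cl) cl$total >= min_total, clusters)
  do.call(rbind, lapply(clusters, as.data.frame))
}

# brute-force argmax-with-3'-most-tie PAS
oracle_pas <- function(counts_by_pos, start, end, strand) {
  pos <- as.integer(names(counts_by_pos))
  sel <- pos >= start & pos <= end
  pos <- pos[sel]; cnt <- as.numeric(counts_by_pos)[sel]
  best <- pos[cnt == max(cnt)]
  if (strand == "+") max(best) else min(best)
}

# exhaustive two-tailed hypergeometric p for a 2x2 with fixed margins,
# probability-mass convention
oracle_fisher2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) dhyper(x, m, n, k), numeric(1))
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exhaustive permutation two-sample KS p (all assignments of the pooled
# sample into groups of the observed sizes)
oracle_ks_perm <- function(x, y) {
  ks_stat <- function(x, y) {
    v <- sort(unique(c(x, y)))
    max(abs(ecdf(x)(v) - ecdf(y)(v)))
  }
  obs <- ks_stat(x, y)
  pool <- c(x, y)
  n <- length(x)
  combs <- utils::combn(length(pool), n)
  stats <- apply(combs, 2L, function(idx)
    ks_stat(pool[idx], pool[-idx]))
  mean(stats >= obs - 1e-12)
}

# brute-force IUPAC matcher
iupac_map <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
               S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
               D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
oracle_scan <- function(seq, pattern) {
  seq <- gsub("U", "T", toupper(seq))
  pattern <- gsub("U", "T", toupper(pattern))
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(seq, "")[[1]]
  L <- length(sc); w <- length(pc)
  if (L < w) return(integer(0))
  hits <- integer(0)
  for (s in seq_len(L - w + 1L)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!grepl(sc[s + j - 1L], iupac_map[[pc[j]]], fixed = TRUE)) {
        ok <- FALSE; break
      }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTUacgtu", "TGCAATGCAA", s), "")[[1]]),
        collapse = "")
}

# tiny two-gene genome with one PAS each, for filter unit tests
tiny_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}
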