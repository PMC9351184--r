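# Independent brute-force oracles the implementation is checked against.
# These deliberately share no code with the package internals.

# two-sided Fisher p by explicit enumeration over the conditional support
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  obs <- dens[support == a]
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# signed-rank two-sided p by full 2^n enumeration of sign patterns
oracle_wilcoxon_p <- function(deltas) {
  d <- deltas[deltas != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# BH step-up from the direct formula: adj_(i) = min_{j>=i} m p_(j)/j, capped
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, rev(cummin(rev(m * ps / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force interval membership for 1-based sites vs 0-based half-open
oracle_in_intervals <- function(chrom, pos, intervals) {
  any(intervals$chrom == chrom &
        intervals$start <= pos - 1 & pos - 1 < intervals$end)
}

# per-base peak overlap: materialize both RBPs' covered base sets
oracle_overlap_bp <- function(pk1, pk2) {
  bases <- function(pk) {
    unique(unlist(lapply(seq_len(nrow(pk)), function(i)
      paste(pk$chrom[i], seq(pk$start[i], pk$end[i] - 1)))))
  }
  length(intersect(bases(pk1), bases(pk2)))
}

# naive per-read double loop over catalog sites and read records
oracle_count_alleles <- function(reads, catalog, trim = 6, min_mapq = 21,
                                 min_baseq = 30) {
  out <- data.frame(catalog[, c("chrom", "pos", "strand")],
                    edited = 0L, total = 0L)
  for (i in seq_len(nrow(catalog))) {
    for (j in seq_len(nrow(reads))) {
      if (reads$chrom[j] != catalog$chrom[i]) next
      flag <- reads$flag[j]
      if (bitwAnd(flag, 0x4) != 0) next
      if (bitwAnd(flag, 0x400) != 0) next
      if (bitwAnd(flag, 0x100) != 0 || bitwAnd(flag, 0x800) != 0) next
      if (reads$mapq[j] < min_mapq) next
      # expand the CIGAR base by base
      ops <- regmatches(reads$cigar[j],
                        gregexpr("[0-9]+[MIDNSHP=X]", reads$cigar[j]))[[1]]
      qpos <- 0; rpos <- reads$pos[j] - 1
      hit_q <- NA
      for (op in ops) {
        len <- as.integer(sub("[A-Z=]", "", op))
        type <- sub("[0-9]+", "", op)
        if (type %in% c("M", "=", "X")) {
          for (s in seq_len(len)) {
            qpos <- qpos + 1; rpos <- rpos + 1
            if (rpos == catalog$pos[i]) hit_q <- qpos
          }
        } else if (type %in% c("I", "S")) qpos <- qpos + len
        else if (type %in% c("D", "N")) rpos <- rpos + len
      }
      if (is.na(hit_q)) next
      qlen <- nchar(reads$seq[j])
      seq_pos <- if (bitwAnd(flag, 0x10) != 0) qlen - hit_q + 1 else hit_q
      if (seq_pos <= trim) next
      if (utf8ToInt(substr(reads$qual[j], hit_q, hit_q)) - 33 < min_baseq)
        next
      base <- toupper(substr(reads$seq[j], hit_q, hit_q))
      if (!base %in% c("A", "C", "G", "T")) next
      out$total[i] <- out$total[i] + 1L
      want <- if (catalog$strand[i] == "+") "G" else "C"
      if (base == want) out$edited[i] <- out$edited[i] + 1L
    }
  }
  out
}

# exhaustive enumeration of all nested structures (min loop 3, WC + GU,
# honoring hard 'unpaired' flags); returns the maximum pair count
oracle_max_pairs <- function(seq, blocked = NULL) {
  ch <- toupper(strsplit(seq, "")[[1]])
  ch[ch == "T"] <- "U"
  n <- length(ch)
  if (is.null(blocked)) blocked <- rep(FALSE, n)
  can <- function(i, j) {
    !blocked[i] && !blocked[j] && j - i >= 4 &&
      paste0(ch[i], ch[j]) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  best <- function(i, j) {
    if (i >= j || j - i < 4) return(0)
    b <- best(i + 1, j)
    for (k in (i + 4):j) {
      if (!can(i, k)) next
      b <- max(b, 1 + best(i + 1, k - 1) + best(k + 1, j))
    }
    b
  }
  best(1, n)
}

# a small rMATS-style SE table written to a temp file
write_rmats_se <- function(pvals, pos = 5000, chrom = "chr1") {
  f <- tempfile(fileext = ".txt")
  n <- length(pvals)
  df <- data.frame(ID = seq_len(n), GeneID = rep("g", n),
                   geneSymbol = rep("G", n),
                   chr = rep(chrom, length.out = max(n, 0)),
                   strand = rep("+", n),
                   exonStart_0base = rep(pos - 50, n),
                   exonEnd = rep(pos + 50, n),
                   upstreamES = rep(pos - 2000, n),
                   upstreamEE = rep(pos - 1900, n),
                   downstreamES = rep(pos + 1900, n),
                   downstreamEE = rep(pos + 2000, n),
                   PValue = pvals, FDR = pvals)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}
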