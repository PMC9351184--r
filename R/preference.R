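## The statistical core: per-site Fisher exact comparison of editing levels
## between eCLIP and background RNA-seq, the per-RBP global paired
## signed-rank test, BH adjustment, and site classification into
## favored / disfavored / ns.

#' Two-sided Fisher exact p-value for 2x2 tables (vectorized)
#'
#' Computes the two-sided Fisher exact p-value for tables
#' `[[a, b], [c, d]]` by full enumeration of the conditional
#' (hypergeometric) distribution: the p-value is the sum of all point
#' probabilities not exceeding the observed one (within a relative
#' tolerance of 1e-7, guarding against floating-point ties — the same
#' convention as [stats::fisher.test()]).
#'
#' @param a,b,c,d Vectors of the four cell counts, recycled to a common
#'   length.
#' @return Vector of two-sided p-values.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stopf("negative cell count")
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]          # row-1 total
    nn <- c[i] + d[i]         # row-2 total
    k <- a[i] + c[i]          # column-1 total
    if (m + nn == 0) return(1)
    support <- max(0, k - nn):min(k, m)
    dens <- dhyper(support, m, nn, k)
    obs <- dens[support == a[i]]
    min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of the per-site differences. Zero differences
#' are dropped before ranking (the classic signed-rank treatment); tied
#' absolute differences receive midranks. For `n <= exact_limit` non-zero
#' differences the null distribution of the rank sum is enumerated exactly
#' over all sign assignments (via dynamic programming over doubled ranks,
#' equivalent to the full 2^n enumeration); beyond that a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param deltas Numeric vector of paired differences.
#' @param exact_limit Largest n for the exact branch (default 25).
#' @return List with `statistic` (rank sum of positive differences), `p`
#'   (two-sided), `n` (non-zero differences used), `exact`, `degenerate`
#'   (TRUE when every difference was zero, in which case `p = 1`).
#' @export
wilcoxon_signed_exact <- function(deltas, exact_limit = 25L) {
  stopifnot(is.numeric(deltas))
  d <- deltas[deltas != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p = 1, n = 0L, exact = TRUE,
                degenerate = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    # doubled ranks are integers even with midranks
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    # distribution of the doubled positive-rank sum over all 2^n signings
    f <- numeric(tot + 1L); f[1] <- 1
    for (x in r2) {
      g <- f
      g[(x + 1L):(tot + 1L)] <- g[(x + 1L):(tot + 1L)] + f[1:(tot + 1L - x)]
      f <- g
    }
    f <- f / 2^n
    w2 <- as.integer(round(2 * w))
    lower <- sum(f[1:(w2 + 1L)])
    upper <- sum(f[(w2 + 1L):(tot + 1L)])
    p <- min(1, 2 * min(lower, upper))
    list(statistic = w, p = p, n = n, exact = TRUE, degenerate = FALSE)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    list(statistic = w, p = p, n = n, exact = FALSE, degenerate = FALSE)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value family, restoring
#' input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pair eCLIP and background editing profiles
#'
#' Intersects the retained sites of a peak-restricted eCLIP profile with
#' those of the matched background RNA-seq profile (the fraction matching
#' the RBP's subcellular location, whole-cell when unknown), removes
#' blacklisted sites, and computes per-site editing levels and their
#' difference.
#'
#' @param eclip Filtered eCLIP `editing_profile` (restrict with
#'   [restrict_to_peaks()] first, or pass `peaks` here).
#' @param background Filtered background RNA-seq `editing_profile`.
#' @param peaks Optional `peak_set`; when given, `eclip` is restricted to it.
#' @param blacklist Optional data.frame with `chrom`, `pos` of sites to
#'   exclude (e.g. from [fraction_concordance()]).
#' @return Data.frame of class `paired_sites`, ordered by (chrom, pos),
#'   with per-site counts, levels and `delta` = eCLIP level - background
#'   level.
#' @export
pair_profiles <- function(eclip, background, peaks = NULL, blacklist = NULL) {
  if (!is.null(peaks)) eclip <- restrict_to_peaks(eclip, peaks)
  ke <- site_key(eclip$chrom, eclip$pos, eclip$strand)
  kb <- site_key(background$chrom, background$pos, background$strand)
  shared <- intersect(ke, kb)
  ie <- match(shared, ke); ib <- match(shared, kb)
  out <- data.frame(chrom = eclip$chrom[ie], pos = eclip$pos[ie],
                    strand = eclip$strand[ie],
                    edited_eclip = eclip$edited[ie],
                    total_eclip = eclip$total[ie],
                    edited_bg = background$edited[ib],
                    total_bg = background$total[ib],
                    stringsAsFactors = FALSE)
  if (!is.null(blacklist) && nrow(out) && NROW(blacklist)) {
    drop <- paste(out$chrom, out$pos) %in%
      paste(blacklist$chrom, blacklist$pos)
    out <- out[!drop, , drop = FALSE]
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) {
    out$level_eclip <- editing_level(out$edited_eclip, out$total_eclip)
    out$level_bg <- editing_level(out$edited_bg, out$total_bg)
    out$delta <- out$level_eclip - out$level_bg
  } else {
    out$level_eclip <- out$level_bg <- out$delta <- numeric(0)
  }
  class(out) <- c("paired_sites", "data.frame")
  out
}

#' Global editing preference of one RBP
#'
#' Tests whether the editing levels of an RBP's bound sites differ overall
#' between the eCLIP data and the background RNA-seq, with a two-sided
#' paired Wilcoxon signed-rank test on the per-site level differences.
#'
#' @param pairs A `paired_sites` data.frame.
#' @param rbp,cell_line Labels carried into the result.
#' @param p_threshold Significance threshold on the Wilcoxon p (default
#'   1e-5).
#' @param exact_limit Passed to [wilcoxon_signed_exact()].
#' @return List of class `global_preference`: `rbp`, `cell_line`,
#'   `n_sites`, `statistic`, `wilcoxon_p`, `median_delta` (median over all
#'   pairs, zeros included), `significant`, `degenerate`.
#' @export
global_preference_test <- function(pairs, rbp = NA_character_,
                                   cell_line = NA_character_,
                                   p_threshold = 1e-5, exact_limit = 25L) {
  if (!nrow(pairs)) stopf("global preference test needs at least one pair")
  wt <- wilcoxon_signed_exact(pairs$delta, exact_limit = exact_limit)
  structure(list(rbp = rbp, cell_line = cell_line, n_sites = nrow(pairs),
                 statistic = wt$statistic, wilcoxon_p = wt$p,
                 median_delta = median(pairs$delta),
                 significant = wt$p < p_threshold,
                 p_threshold = p_threshold,
                 exact = wt$exact, degenerate = wt$degenerate),
            class = "global_preference")
}

#' @export
print.global_preference <- function(x, ...) {
  cat(sprintf("global preference: %s (%s), n = %d sites\n",
              x$rbp, x$cell_line, x$n_sites))
  cat(sprintf("  paired Wilcoxon signed-rank p = %.4g (%s)%s\n",
              x$wilcoxon_p, if (x$exact) "exact" else "normal approx.",
              if (x$degenerate) " [degenerate: all differences zero]" else ""))
  cat(sprintf("  median delta = %.4f; %ssignificant at p < %g\n",
              x$median_delta, if (x$significant) "" else "not ",
              x$p_threshold))
  invisible(x)
}

#' Per-site differential-editing test
#'
#' Two-sided Fisher exact test of one site's edited/unedited read counts in
#' eCLIP versus background, accounting for the stochastic sampling noise of
#' the reads at low coverage.
#'
#' @param edited_eclip,total_eclip,edited_bg,total_bg Count vectors.
#' @return Data.frame with `p` and `delta` (eCLIP level - background level).
#' @export
site_preference_test <- function(edited_eclip, total_eclip,
                                 edited_bg, total_bg) {
  p <- fisher_exact_2x2(edited_eclip, total_eclip - edited_eclip,
                        edited_bg, total_bg - edited_bg)
  data.frame(p = p,
             delta = editing_level(edited_eclip, total_eclip) -
               editing_level(edited_bg, total_bg))
}

#' Classify sites as favored, disfavored or ns
#'
#' Runs [site_preference_test()] on every pair, adjusts the p-values within
#' the (RBP, cell line) family by Benjamini-Hochberg, and calls a site
#' *favored* when the eCLIP editing level exceeds the background level by
#' more than `min_delta` with adjusted p below `alpha`, *disfavored* for
#' the opposite direction, and *ns* otherwise. Both threshold comparisons
#' are strict.
#'
#' @param pairs A `paired_sites` data.frame from one (RBP, cell line).
#' @param rbp,cell_line Labels carried into the calls.
#' @param alpha Significance level on the (adjusted) p (default 0.05).
#' @param min_delta Minimum absolute level difference (default 0.1).
#' @param adjust Adjust p-values within the family (default TRUE); FALSE
#'   applies `alpha` to the raw Fisher p instead.
#' @return Data.frame of class `site_preference_calls` with the pair
#'   columns plus `rbp`, `cell_line`, `p`, `p_adj`, `call`.
#' @export
classify_sites <- function(pairs, rbp = NA_character_,
                           cell_line = NA_character_, alpha = 0.05,
                           min_delta = 0.1, adjust = TRUE) {
  out <- as.data.frame(pairs)
  out$rbp <- rbp
  out$cell_line <- cell_line
  if (nrow(out)) {
    st <- site_preference_test(out$edited_eclip, out$total_eclip,
                               out$edited_bg, out$total_bg)
    out$p <- st$p
    out$p_adj <- if (adjust) adjust_bh(st$p) else st$p
    p_eff <- out$p_adj
    out$call <- ifelse(p_eff < alpha & out$delta > min_delta, "favored",
                ifelse(p_eff < alpha & out$delta < -min_delta, "disfavored",
                       "ns"))
  } else {
    out$p <- out$p_adj <- numeric(0)
    out$call <- character(0)
  }
  class(out) <- c("site_preference_calls", "data.frame")
  out
}
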