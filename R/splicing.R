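## Positional enrichment of RBP-associated editing sites near exon/intron
## boundaries, and association with differential alternative-splicing
## events.

#' Bin editing sites by distance from an exon/intron boundary
#'
#' Sites falling inside the anchored feature (introns for the intron
#' anchors, exons for the exon anchors) of any transcript are binned by
#' their distance from the feature's transcriptional 5' or 3' end into
#' fixed-width blocks (default 200 nt): bin k holds distances
#' `(k-1)*bin_size <= d < k*bin_size`, with d = 0 at the boundary base.
#' Distances are strand-aware (the 5' end of a minus-strand intron is its
#' genomic right end). A site seen in several transcripts is counted once,
#' at its minimum distance. Sites farther than `n_bins * bin_size` (or in
#' the wrong feature type) are tallied as uncounted; sites in no transcript
#' are tallied as skipped.
#'
#' @param sites Data.frame with `chrom`, `pos` (1-based), `strand`.
#' @param gene_model A `gene_model` from [read_gene_model()].
#' @param anchor One of `"intron_5p"`, `"intron_3p"`, `"exon_5p"`,
#'   `"exon_3p"`.
#' @param bin_size Block width in nucleotides (default 200).
#' @param n_bins Number of blocks kept from the anchor.
#' @return List of class `boundary_bins`: `anchor`, `bin_size`, `n_bins`,
#'   `counts` (length `n_bins`), `n_sites`, `n_uncounted`, `n_skipped`.
#' @export
bin_sites_by_boundary <- function(sites, gene_model,
                                  anchor = c("intron_5p", "intron_3p",
                                             "exon_5p", "exon_3p"),
                                  bin_size = 200L, n_bins = 10L) {
  anchor <- match.arg(anchor)
  want_intron <- grepl("^intron", anchor)
  from_5p <- grepl("5p$", anchor)
  txs <- gene_model$transcripts
  counts <- integer(n_bins)
  n_skipped <- 0L; n_uncounted <- 0L
  for (i in seq_len(nrow(sites))) {
    pos0 <- sites$pos[i] - 1L            # 0-based site coordinate
    best <- NA_integer_
    intragenic <- FALSE
    for (tx in txs) {
      if (tx$chrom != sites$chrom[i]) next
      ex <- tx$exons
      if (pos0 < ex[1, 1] || pos0 >= ex[nrow(ex), 2]) next
      intragenic <- TRUE
      feats <- if (want_intron) {
        if (nrow(ex) < 2) next
        cbind(start = ex[-nrow(ex), 2], end = ex[-1, 1])
      } else ex
      hit <- which(pos0 >= feats[, 1] & pos0 < feats[, 2])
      if (!length(hit)) next
      f <- feats[hit[1], ]
      # transcriptional 5' end is the genomic left end on '+', right on '-'
      d <- if ((tx$strand == "+") == from_5p) pos0 - f[1]
           else f[2] - 1L - pos0
      if (is.na(best) || d < best) best <- d
    }
    if (!intragenic) { n_skipped <- n_skipped + 1L; next }
    if (is.na(best)) { n_uncounted <- n_uncounted + 1L; next }
    k <- best %/% bin_size + 1L
    if (k > n_bins) n_uncounted <- n_uncounted + 1L
    else counts[k] <- counts[k] + 1L
  }
  structure(list(anchor = anchor, bin_size = as.integer(bin_size),
                 n_bins = as.integer(n_bins), counts = counts,
                 n_sites = nrow(sites), n_uncounted = n_uncounted,
                 n_skipped = n_skipped),
            class = "boundary_bins")
}

#' @export
print.boundary_bins <- function(x, ...) {
  cat(sprintf("boundary bins (%s, %d x %d nt): %d site(s), %d binned, %d uncounted, %d skipped\n",
              x$anchor, x$n_bins, x$bin_size, x$n_sites, sum(x$counts),
              x$n_uncounted, x$n_skipped))
  print(stats::setNames(x$counts, paste0("bin", seq_len(x$n_bins))))
  invisible(x)
}

#' Per-bin enrichment of foreground sites over background
#'
#' For each bin, a two-sided Fisher exact test of
#' `[[fore_k, fore_total - fore_k], [back_k, back_total - back_k]]` (totals
#' over the binned sites), with Benjamini-Hochberg adjustment across bins.
#'
#' @param fore,back `boundary_bins` with the same anchor, bin size and bin
#'   count.
#' @return Data.frame with `bin`, `fore`, `back`, `odds_ratio`, `p`,
#'   `p_adj`.
#' @export
boundary_enrichment <- function(fore, back) {
  if (!identical(fore$anchor, back$anchor) ||
      !identical(fore$bin_size, back$bin_size) ||
      !identical(fore$n_bins, back$n_bins))
    stopf("foreground and background bin tables are not compatible")
  ft <- sum(fore$counts); bt <- sum(back$counts)
  if (bt == 0) stopf("background bin table is empty")
  f <- fore$counts; b <- back$counts
  p <- fisher_exact_2x2(f, ft - f, b, bt - b)
  or <- (f * (bt - b)) / ((ft - f) * b)
  data.frame(bin = seq_len(fore$n_bins), fore = f, back = b,
             odds_ratio = or, p = p, p_adj = adjust_bh(p))
}

#' Flag editing sites inside differential AS event coordinates
#'
#' A site is AS-related when it lies within any coordinate block of a
#' differential alternative-splicing event (events pre-filtered at
#' p < 0.05 by [read_rmats_events()]).
#'
#' @param sites Data.frame with `chrom`, `pos`, `strand`.
#' @param events An `as_events` data.frame (or anything with `chrom`,
#'   `start`, `end` 0-based half-open).
#' @return Logical vector along `sites` rows.
#' @export
flag_as_related <- function(sites, events) {
  site_in_intervals(sites, events)
}

#' Association of RBP-associated sites with AS events
#'
#' Compares the AS-related fraction of an RBP's associated (favored or
#' disfavored) editing sites against the other sites in the same RBP's
#' peaks that were tested but called ns, with a two-sided Fisher exact
#' test. The odds ratio is raw unless the 2x2 table has a zero cell, in
#' which case the Haldane-Anscombe 0.5 correction is applied and flagged.
#'
#' @param assoc_sites Data.frame of the RBP-associated sites (`chrom`,
#'   `pos`, `strand`).
#' @param other_sites Data.frame of the ns sites in the same peaks.
#' @param events An `as_events` table of differential events.
#' @return List of class `as_association`: counts, `odds_ratio`, `p`,
#'   `or_corrected` flag.
#' @export
as_enrichment <- function(assoc_sites, other_sites, events) {
  if (!nrow(assoc_sites)) stopf("no RBP-associated sites supplied")
  if (!nrow(other_sites)) stopf("no comparison (ns) sites supplied")
  n_assoc_as <- sum(flag_as_related(assoc_sites, events))
  n_other_as <- sum(flag_as_related(other_sites, events))
  n_assoc <- nrow(assoc_sites); n_other <- nrow(other_sites)
  tab <- c(n_assoc_as, n_assoc - n_assoc_as, n_other_as,
           n_other - n_other_as)
  p <- fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4])
  corrected <- any(tab == 0)
  t2 <- if (corrected) tab + 0.5 else tab
  or <- (t2[1] * t2[4]) / (t2[2] * t2[3])
  structure(list(n_assoc_as = n_assoc_as, n_assoc_total = n_assoc,
                 n_other_as = n_other_as, n_other_total = n_other,
                 odds_ratio = or, p = p, or_corrected = corrected),
            class = "as_association")
}

#' @export
print.as_association <- function(x, ...) {
  cat(sprintf("AS association: %d/%d associated vs %d/%d other sites AS-related\n",
              x$n_assoc_as, x$n_assoc_total, x$n_other_as, x$n_other_total))
  cat(sprintf("  OR = %.3f%s, Fisher p = %.4g\n", x$odds_ratio,
              if (x$or_corrected) " (Haldane-Anscombe corrected)" else "",
              x$p))
  invisible(x)
}
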