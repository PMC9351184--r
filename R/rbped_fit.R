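## The user-facing fit: one call pairs an RBP's eCLIP profile with its
## background, runs the global signed-rank test and the per-site Fisher
## calls, and returns a classed object with the usual accessor methods.

#' Fit the editing preference of one RBP
#'
#' Pairs an eCLIP editing profile with its matched background RNA-seq
#' profile (restricting to binding peaks and removing blacklisted sites),
#' then tests the RBP's preference for edited versus unedited RNA at two
#' levels: globally, with a two-sided paired Wilcoxon signed-rank test on
#' the per-site editing-level differences, and per site, with a two-sided
#' Fisher exact test on the edited/unedited read counts followed by
#' Benjamini-Hochberg adjustment and classification into favored,
#' disfavored or ns.
#'
#' @param eclip Filtered eCLIP `editing_profile`.
#' @param background Filtered background RNA-seq `editing_profile`; choose
#'   the cell fraction matching the RBP's subcellular location, whole-cell
#'   when unknown.
#' @param peaks Optional `peak_set` to restrict the eCLIP profile to.
#' @param blacklist Optional data.frame (`chrom`, `pos`) of sites excluded
#'   from pairing (e.g. fraction-discordant sites).
#' @param rbp,cell_line Labels.
#' @param alpha,min_delta,adjust Per-site call thresholds, see
#'   [classify_sites()].
#' @param global_p Global-significance threshold, see
#'   [global_preference_test()].
#' @return Object of class `rbped` with components `pairs`
#'   (`paired_sites`), `global` (`global_preference`), `calls`
#'   (`site_preference_calls`) and the thresholds used. `NULL` `global`
#'   when no sites could be paired.
#' @seealso [summary.rbped()], [coef.rbped()], [plot.rbped()]
#' @examples
#' sim <- simulate_counts(sim_config(n_sites = 200, n_rbps = 1,
#'                                   n_effects = 20, seed = 7))
#' fit <- rbped(sim$eclip[[1]], sim$background$whole, rbp = "RBP1")
#' fit
#' @export
rbped <- function(eclip, background, peaks = NULL, blacklist = NULL,
                  rbp = attr(eclip, "sample_id"), cell_line = NA_character_,
                  alpha = 0.05, min_delta = 0.1, adjust = TRUE,
                  global_p = 1e-5) {
  pairs <- pair_profiles(eclip, background, peaks = peaks,
                         blacklist = blacklist)
  glob <- if (nrow(pairs))
    global_preference_test(pairs, rbp = rbp, cell_line = cell_line,
                           p_threshold = global_p) else NULL
  calls <- classify_sites(pairs, rbp = rbp, cell_line = cell_line,
                          alpha = alpha, min_delta = min_delta,
                          adjust = adjust)
  structure(list(rbp = rbp, cell_line = cell_line, pairs = pairs,
                 global = glob, calls = calls,
                 thresholds = list(alpha = alpha, min_delta = min_delta,
                                   adjust = adjust, global_p = global_p)),
            class = "rbped")
}

#' @export
print.rbped <- function(x, ...) {
  cat(sprintf("RBP editing-preference fit: %s (%s)\n", x$rbp, x$cell_line))
  cat(sprintf("  %d paired site(s)\n", nrow(x$pairs)))
  if (!is.null(x$global)) {
    cat(sprintf("  global: Wilcoxon p = %.4g, median delta = %.4f%s\n",
                x$global$wilcoxon_p, x$global$median_delta,
                if (x$global$significant)
                  sprintf(" (significant at p < %g)", x$global$p_threshold)
                else ""))
  }
  tb <- table(factor(x$calls$call, c("favored", "disfavored", "ns")))
  cat(sprintf("  site calls: %d favored, %d disfavored, %d ns\n",
              tb[["favored"]], tb[["disfavored"]], tb[["ns"]]))
  invisible(x)
}

#' Summarize an RBP preference fit
#' @param object An `rbped` fit.
#' @param ... Unused.
#' @return List of class `summary.rbped` with the global test, call counts
#'   and the most significant site calls.
#' @method summary rbped
#' @export
summary.rbped <- function(object, ...) {
  calls <- object$calls
  sig <- calls[calls$call != "ns", , drop = FALSE]
  sig <- sig[order(sig$p_adj), , drop = FALSE]
  structure(list(rbp = object$rbp, cell_line = object$cell_line,
                 n_sites = nrow(object$pairs), global = object$global,
                 n_favored = sum(calls$call == "favored"),
                 n_disfavored = sum(calls$call == "disfavored"),
                 top_calls = head(sig, 10),
                 thresholds = object$thresholds),
            class = "summary.rbped")
}

#' @export
print.summary.rbped <- function(x, ...) {
  cat(sprintf("RBP editing preference: %s (%s)\n", x$rbp, x$cell_line))
  if (!is.null(x$global)) print(x$global)
  cat(sprintf("  favored sites: %d; disfavored: %d (|delta| > %g, %s p < %g)\n",
              x$n_favored, x$n_disfavored, x$thresholds$min_delta,
              if (x$thresholds$adjust) "adjusted" else "raw",
              x$thresholds$alpha))
  if (nrow(x$top_calls)) {
    cat("  top calls:\n")
    print(x$top_calls[, c("chrom", "pos", "strand", "level_eclip",
                          "level_bg", "delta", "p_adj", "call")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Per-site editing-level differences of a fit
#' @param object An `rbped` fit.
#' @param ... Unused.
#' @return Named numeric vector of per-site deltas (eCLIP level minus
#'   background level), named `chrom:pos:strand`.
#' @method coef rbped
#' @export
coef.rbped <- function(object, ...) {
  p <- object$pairs
  structure(p$delta, names = site_key(p$chrom, p$pos, p$strand))
}

#' @method as.data.frame rbped
#' @export
as.data.frame.rbped <- function(x, ...) {
  df <- as.data.frame(x$calls)
  df$level_rnaseq <- df$level_bg
  df[, c("chrom", "pos", "strand", "rbp", "cell_line", "level_eclip",
         "level_rnaseq", "delta", "p", "p_adj", "call")]
}

#' Plot the editing-level difference distribution of a fit
#'
#' Histogram of the per-site eCLIP-minus-background editing-level
#' differences, annotated with the global signed-rank p-value and median.
#'
#' @param x An `rbped` fit.
#' @param ... Passed to [graphics::hist()].
#' @method plot rbped
#' @export
plot.rbped <- function(x, ...) {
  d <- x$pairs$delta
  graphics::hist(d, breaks = 30, col = "grey80", border = "white",
                 main = sprintf("%s (%s): n = %d", x$rbp, x$cell_line,
                                length(d)),
                 xlab = "editing level difference (eCLIP - background)", ...)
  graphics::abline(v = 0, lty = 2)
  if (!is.null(x$global)) {
    graphics::mtext(sprintf("Wilcoxon p = %.3g, median = %.3f",
                            x$global$wilcoxon_p, x$global$median_delta),
                    side = 3, line = 0, cex = 0.8)
  }
  invisible(x)
}

#' Tabulate global results across fits
#' @param fits List of `rbped` fits.
#' @return Data.frame, one row per fit, mirroring the per-RBP summary table.
#' @export
global_summary_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    g <- f$global
    data.frame(rbp = f$rbp, cell_line = f$cell_line,
               n_sites = if (is.null(g)) 0L else g$n_sites,
               wilcoxon_p = if (is.null(g)) NA_real_ else g$wilcoxon_p,
               median_delta = if (is.null(g)) NA_real_ else g$median_delta,
               significant = if (is.null(g)) FALSE else g$significant,
               n_favored = sum(f$calls$call == "favored"),
               n_disfavored = sum(f$calls$call == "disfavored"),
               stringsAsFactors = FALSE)
  }))
}
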