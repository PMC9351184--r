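## Editing-level quantification: filtered per-site allele counts, replicate
## merging, site retention, and cross-fraction concordance.

#' Read-level filter configuration
#'
#' Defaults encode the standard known-site editing-calling filters: the
#' first six bases of each read are ignored (ligation/priming artifacts),
#' only reads with mapping quality above 20 are used, bases with quality
#' below 30 are dropped, and PCR-duplicate and multi-mapping (secondary /
#' supplementary) reads are removed.
#'
#' @param trim_5prime Bases masked at the start of each read, counted in the
#'   original sequencing orientation (default 6).
#' @param min_mapq Minimum mapping quality kept; the default 21 keeps reads
#'   with MAPQ strictly greater than 20.
#' @param min_baseq Minimum base quality kept (default 30; a base with
#'   quality 30 is kept).
#' @param drop_duplicates Drop reads flagged as PCR duplicates.
#' @param drop_multimappers Drop secondary and supplementary alignments.
#' @return A list of class `read_filter_config`.
#' @export
read_filter_config <- function(trim_5prime = 6L, min_mapq = 21L,
                               min_baseq = 30L, drop_duplicates = TRUE,
                               drop_multimappers = TRUE) {
  stopifnot(trim_5prime >= 0, min_mapq >= 0, min_baseq >= 0)
  structure(list(trim_5prime = as.integer(trim_5prime),
                 min_mapq = as.integer(min_mapq),
                 min_baseq = as.integer(min_baseq),
                 drop_duplicates = isTRUE(drop_duplicates),
                 drop_multimappers = isTRUE(drop_multimappers)),
            class = "read_filter_config")
}

#' Construct an editing profile
#'
#' An editing profile is one sample's per-site edited/total counts for one
#' assay and cell fraction.
#'
#' @param counts Data.frame with columns `chrom`, `pos`, `strand`, `edited`,
#'   `total` (one row per site; `0 <= edited <= total`).
#' @param sample_id Sample label.
#' @param assay `"rnaseq"` or `"eclip"`.
#' @param fraction `"whole"`, `"nucleus"` or `"cytosol"`.
#' @param filtered Whether `counts` already passed [retain_sites()].
#' @return Data.frame of class `editing_profile` with attributes
#'   `sample_id`, `assay`, `fraction`, `filtered`.
#' @export
editing_profile <- function(counts, sample_id = "sample",
                            assay = c("rnaseq", "eclip"),
                            fraction = c("whole", "nucleus", "cytosol"),
                            filtered = FALSE) {
  assay <- match.arg(assay)
  fraction <- match.arg(fraction)
  need <- c("chrom", "pos", "strand", "edited", "total")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stopf("counts missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(counts$edited < 0 | counts$edited > counts$total))
    stopf("invalid counts: need 0 <= edited <= total")
  check_strand(counts$strand)
  df <- as.data.frame(counts)[, need]
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, sample_id = sample_id, assay = assay, fraction = fraction,
            filtered = isTRUE(filtered),
            class = c("editing_profile", "data.frame"))
}

#' Read an editing profile from a counts TSV
#' @param path TSV with columns `chrom`, `pos`, `strand`, `edited`, `total`.
#' @inheritParams editing_profile
#' @export
read_counts <- function(path, sample_id = basename(path), assay = "rnaseq",
                        fraction = "whole", filtered = FALSE) {
  editing_profile(read_tsv(path), sample_id = sample_id, assay = assay,
                  fraction = fraction, filtered = filtered)
}

#' Write an editing profile as a counts TSV
#' @param profile An `editing_profile`.
#' @param path Output path.
#' @export
write_counts <- function(profile, path) {
  write_tsv(as.data.frame(profile)[, c("chrom", "pos", "strand",
                                       "edited", "total")], path)
}

#' Retain adequately covered sites
#'
#' Keeps sites whose total passing depth exceeds 10 reads (`total >=
#' min_depth`, default 11) and that have at least one read supporting the
#' edited base.
#'
#' @param profile An `editing_profile` (or plain counts data.frame).
#' @param min_depth Minimum total depth retained (default 11, i.e. depth
#'   strictly above 10).
#' @param min_edited Minimum edited-read count retained (default 1).
#' @return The filtered profile, flagged `filtered`.
#' @export
retain_sites <- function(profile, min_depth = 11L, min_edited = 1L) {
  keep <- profile$total >= min_depth & profile$edited >= min_edited
  out <- profile[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filtered") <- TRUE
  out
}

#' Merge replicate profiles
#'
#' Per-site edited and total counts are summed across replicates (after
#' per-replicate read filtering, before site retention), and the merged
#' profile is then re-filtered with [retain_sites()].
#'
#' @param profiles List of `editing_profile`s sharing assay and fraction.
#' @param min_depth,min_edited Passed to [retain_sites()].
#' @return Merged, filtered `editing_profile`.
#' @export
merge_replicates <- function(profiles, min_depth = 11L, min_edited = 1L) {
  stopifnot(length(profiles) >= 1)
  assays <- vapply(profiles, attr, "", "assay")
  fracs <- vapply(profiles, attr, "", "fraction")
  if (length(unique(assays)) > 1L) stopf("cannot merge mixed assays: %s",
                                         paste(unique(assays), collapse = ", "))
  if (length(unique(fracs)) > 1L) stopf("cannot merge mixed fractions: %s",
                                        paste(unique(fracs), collapse = ", "))
  all <- do.call(rbind, lapply(profiles, function(p)
    as.data.frame(p)[, c("chrom", "pos", "strand", "edited", "total")]))
  key <- site_key(all$chrom, all$pos, all$strand)
  agg <- rowsum(all[, c("edited", "total")], key)
  first <- all[!duplicated(key), c("chrom", "pos", "strand")]
  merged <- cbind(first, agg[site_key(first$chrom, first$pos, first$strand),
                             , drop = FALSE])
  merged <- editing_profile(
    merged,
    sample_id = paste(vapply(profiles, attr, "", "sample_id"),
                      collapse = "+"),
    assay = assays[1], fraction = fracs[1])
  retain_sites(merged, min_depth = min_depth, min_edited = min_edited)
}

#' Per-site editing level
#'
#' The editing level is the fraction of reads supporting the A-to-I
#' conversion over the total passing depth at the site.
#'
#' @param edited,total Count vectors (recycled per base R rules).
#' @return Numeric vector in `[0, 1]`.
#' @export
editing_level <- function(edited, total) {
  if (any(total == 0)) stopf("editing level undefined at zero depth")
  if (any(edited < 0 | edited > total)) stopf("need 0 <= edited <= total")
  edited / total
}

#' Restrict an eCLIP profile to binding peaks
#'
#' Only editing sites located within an RBP's binding peaks are informative
#' about that RBP; all other sites are dropped.
#'
#' @param profile An `editing_profile` with assay `"eclip"`.
#' @param peaks A `peak_set`.
#' @param strand_aware Require matching strand for the overlap
#'   (default FALSE).
#' @return The restricted profile.
#' @export
restrict_to_peaks <- function(profile, peaks, strand_aware = FALSE) {
  if (!identical(attr(profile, "assay"), "eclip"))
    stopf("restrict_to_peaks expects an eCLIP profile")
  keep <- site_in_intervals(profile, peaks, strand_aware = strand_aware)
  out <- profile[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-fraction concordance of editing levels
#'
#' For sites detected in two cell fractions, computes the Pearson
#' correlation of editing levels and flags sites whose levels differ
#' significantly between fractions (two-sided Fisher exact test per site on
#' the edited/unedited counts, Benjamini-Hochberg adjusted). Flagged sites
#' form a blacklist that downstream preference analyses exclude.
#'
#' @param a,b Two `editing_profile`s of the same assay and different
#'   fractions.
#' @param fdr Adjusted-p cutoff for blacklisting (default 0.05).
#' @return List of class `fraction_concordance`: `pearson_r` (NA when fewer
#'   than 3 shared sites), `n_shared`, `table` (per-site levels, p, p_adj),
#'   `blacklist` (subset with `p_adj < fdr`).
#' @export
fraction_concordance <- function(a, b, fdr = 0.05) {
  if (!identical(attr(a, "assay"), attr(b, "assay")))
    stopf("profiles must share assay")
  if (identical(attr(a, "fraction"), attr(b, "fraction")))
    stopf("profiles must come from different fractions")
  ka <- site_key(a$chrom, a$pos, a$strand)
  kb <- site_key(b$chrom, b$pos, b$strand)
  shared <- intersect(ka, kb)
  ia <- match(shared, ka); ib <- match(shared, kb)
  tab <- data.frame(chrom = a$chrom[ia], pos = a$pos[ia],
                    strand = a$strand[ia],
                    edited_a = a$edited[ia], total_a = a$total[ia],
                    edited_b = b$edited[ib], total_b = b$total[ib],
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  if (nrow(tab)) {
    tab$level_a <- editing_level(tab$edited_a, tab$total_a)
    tab$level_b <- editing_level(tab$edited_b, tab$total_b)
    tab$p <- fisher_exact_2x2(tab$edited_a, tab$total_a - tab$edited_a,
                              tab$edited_b, tab$total_b - tab$edited_b)
    tab$p_adj <- adjust_bh(tab$p)
  } else {
    tab$level_a <- tab$level_b <- tab$p <- tab$p_adj <- numeric(0)
  }
  r <- if (nrow(tab) >= 3) cor(tab$level_a, tab$level_b) else NA_real_
  structure(list(pearson_r = r, n_shared = nrow(tab), table = tab,
                 blacklist = tab[tab$p_adj < fdr, , drop = FALSE],
                 fdr = fdr,
                 fractions = c(attr(a, "fraction"), attr(b, "fraction"))),
            class = "fraction_concordance")
}

#' @export
print.fraction_concordance <- function(x, ...) {
  cat(sprintf("fraction concordance (%s vs %s): %d shared sites\n",
              x$fractions[1], x$fractions[2], x$n_shared))
  cat(sprintf("  Pearson r = %s; %d site(s) blacklisted at FDR < %g\n",
              if (is.na(x$pearson_r)) "undefined (< 3 shared sites)"
              else format(x$pearson_r, digits = 4),
              nrow(x$blacklist), x$fdr))
  invisible(x)
}
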