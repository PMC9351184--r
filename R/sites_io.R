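## Readers and writers for the external formats the pipeline touches, plus
## the one coordinate conversion in the package.
##
## Conventions: editing sites are 1-based (REDIportal style); all interval
## files (BED peaks, rMATS event blocks, gene-model exons) are 0-based
## half-open (BED style).  The conversion between the two happens only in
## site_in_intervals().

#' Read a known editing-site catalog
#'
#' Reads a tab-separated catalog of A-to-I editing sites (columns `chrom`,
#' `pos` with 1-based positions, `strand`, and optionally `site_id`), drops
#' any site whose position appears in an exclusion list (e.g. positions
#' pre-extracted from dbSNP, so apparent editing caused by genomic SNPs is
#' removed), deduplicates, and returns the catalog sorted by (chrom, pos).
#'
#' @param path Path to the catalog TSV.
#' @param exclusion Optional path to a position-list TSV with columns
#'   `chrom`, `pos`; matching (chrom, pos) entries are removed regardless
#'   of strand.
#' @return A data.frame of class `editing_sites` with columns `chrom`,
#'   `pos`, `strand`, `site_id` (NA when absent). The reference base of
#'   every site is adenosine on the transcribed strand.
#' @examples
#' f <- tempfile()
#' writeLines("chrom\tpos\tstrand\nchr1\t100\t+\nchr1\t200\t+", f)
#' read_site_catalog(f)
#' @export
read_site_catalog <- function(path, exclusion = NULL) {
  df <- read_tsv(path)
  need <- c("chrom", "pos", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s): %s", path,
                          paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(pos) | pos < 1 | !df$strand %in% c("+", "-"))
  if (length(bad)) {
    # +1 for the header row so the reported number matches the file
    stopf("%s: malformed row at line %d", path, bad[1] + 1L)
  }
  sites <- data.frame(chrom = as.character(df$chrom), pos = pos,
                      strand = as.character(df$strand),
                      site_id = if ("site_id" %in% names(df))
                        as.character(df$site_id) else NA_character_,
                      stringsAsFactors = FALSE)
  key <- site_key(sites$chrom, sites$pos, sites$strand)
  if (anyDuplicated(key)) {
    warnf("%s: %d duplicate site row(s) merged", path, sum(duplicated(key)))
    sites <- sites[!duplicated(key), , drop = FALSE]
  }
  if (!is.null(exclusion)) {
    ex <- read_tsv(exclusion)
    if (!all(c("chrom", "pos") %in% names(ex)))
      stopf("%s: exclusion list needs columns chrom, pos", exclusion)
    drop <- paste(sites$chrom, sites$pos) %in% paste(ex$chrom, ex$pos)
    sites <- sites[!drop, , drop = FALSE]
  }
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  class(sites) <- c("editing_sites", "data.frame")
  sites
}

#' Write an editing-site catalog
#' @param sites An `editing_sites` data.frame.
#' @param path Output TSV path.
#' @export
write_site_catalog <- function(sites, path) {
  write_tsv(sites[, c("chrom", "pos", "strand", "site_id")], path)
}

#' Read RBP binding peaks (BED6 / narrowPeak)
#'
#' Parses the first six BED columns (chrom, 0-based start, end, name, score,
#' strand); extra narrowPeak columns are ignored. Intervals are kept verbatim
#' as 0-based half-open.
#'
#' @param path BED6 or narrowPeak file (no header).
#' @param rbp,cell_line Optional labels attached to the peak set.
#' @return A data.frame of class `peak_set` with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand` and attributes `rbp`, `cell_line`.
#' @export
read_peaks <- function(path, rbp = NA_character_, cell_line = NA_character_) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    pk <- data.frame(chrom = character(), start = integer(), end = integer(),
                     name = character(), score = numeric(), strand = character(),
                     stringsAsFactors = FALSE)
    return(as_peak_set(pk, rbp, cell_line))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) stopf("%s: fewer than 6 columns at line %d",
                         path, which(nf < 6)[1])
  take <- function(i) vapply(fields, `[[`, "", i)
  start <- suppressWarnings(as.integer(take(2)))
  end <- suppressWarnings(as.integer(take(3)))
  if (anyNA(start) || anyNA(end))
    stopf("%s: non-integer coordinate at line %d", path,
          which(is.na(start) | is.na(end))[1])
  bad <- which(end <= start)
  if (length(bad)) stopf("%s: end <= start at line %d", path, bad[1])
  pk <- data.frame(chrom = take(1), start = start, end = end,
                   name = take(4), score = suppressWarnings(as.numeric(take(5))),
                   strand = take(6), stringsAsFactors = FALSE)
  as_peak_set(pk, rbp, cell_line)
}

as_peak_set <- function(df, rbp = NA_character_, cell_line = NA_character_) {
  attr(df, "rbp") <- rbp
  attr(df, "cell_line") <- cell_line
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Write peaks as BED6
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(peaks)[, c("chrom", "start", "end", "name", "score",
                                 "strand")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

## rMATS "Events specific columns" per event type (JC dialect).  Each pair
## (start, end) is a 0-based half-open block; a site inside any block of a
## differential event counts as AS-related.
.rmats_blocks <- list(
  SE   = list(c("exonStart_0base", "exonEnd")),
  MXE  = list(c("1stExonStart_0base", "1stExonEnd"),
              c("2ndExonStart_0base", "2ndExonEnd")),
  A3SS = list(c("longExonStart_0base", "longExonEnd"),
              c("shortES", "shortEE")),
  A5SS = list(c("longExonStart_0base", "longExonEnd"),
              c("shortES", "shortEE")),
  RI   = list(c("riExonStart_0base", "riExonEnd"))
)

#' Read differential alternative-splicing events from an rMATS table
#'
#' Reads one rMATS `*.MATS.JC.txt`-style table, keeps events with
#' `PValue < p_cutoff`, and assembles each event's coordinate blocks from
#' the event-specific columns of its type (SE: the skipped exon; MXE: both
#' alternative exons; A3SS/A5SS: long and short exon; RI: the retained-intron
#' region).
#'
#' @param path rMATS table with a header row.
#' @param event_type One of `"SE"`, `"MXE"`, `"A3SS"`, `"A5SS"`, `"RI"`.
#' @param p_cutoff Events with p-values below this are retained (default
#'   0.05, the differential-AS cutoff).
#' @return A data.frame of class `as_events`, one row per coordinate block:
#'   columns `event_id`, `event_type`, `chrom`, `strand`, `p_value`,
#'   `start`, `end` (0-based half-open).
#' @export
read_rmats_events <- function(path, event_type, p_cutoff = 0.05) {
  if (!event_type %in% names(.rmats_blocks))
    stopf("unknown rMATS event type '%s'", event_type)
  df <- read_tsv(path)
  blocks <- .rmats_blocks[[event_type]]
  need <- c("ID", "chr", "strand", "PValue", unlist(blocks))
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing rMATS column '%s'", path, miss[1])
  df <- df[!is.na(df$PValue) & df$PValue < p_cutoff, , drop = FALSE]
  out <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(event_id = as.character(df$ID),
               event_type = rep(event_type, nrow(df)),
               chrom = as.character(df$chr), strand = as.character(df$strand),
               p_value = df$PValue,
               start = as.integer(df[[b[1]]]), end = as.integer(df[[b[2]]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out) || !nrow(out)) {
    out <- data.frame(event_id = character(), event_type = character(),
                      chrom = character(), strand = character(),
                      p_value = numeric(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  } else {
    bad <- which(out$end <= out$start)
    if (length(bad)) stopf("%s: event %s has block end <= start",
                           path, out$event_id[bad[1]])
    out <- out[order(out$event_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("as_events", "data.frame")
  out
}

#' Test whether editing sites fall inside genomic intervals
#'
#' The single point where 1-based site positions meet 0-based half-open
#' intervals: a site at 1-based position p lies in `[start, end)` iff
#' `start <= p - 1 < end`.
#'
#' @param sites Data.frame with `chrom`, `pos` (1-based) and, if
#'   `strand_aware`, `strand`.
#' @param intervals Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand`.
#' @param strand_aware If TRUE, an interval only matches a site on the same
#'   strand (default FALSE, the usual convention for eCLIP peak BED files).
#' @return Logical vector along `sites` rows.
#' @export
site_in_intervals <- function(sites, intervals, strand_aware = FALSE) {
  if (!nrow(sites)) return(logical(0))
  if (is.null(intervals) || !nrow(intervals)) return(rep(FALSE, nrow(sites)))
  sg <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(start = sites$pos, width = 1L),
    strand = if (strand_aware) sites$strand else "*")
  ig <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end),
    strand = if (strand_aware && "strand" %in% names(intervals))
      intervals$strand else "*")
  # disjoint chromosome sets are a legitimate no-overlap case, not worth
  # GenomeInfoDb's "no sequence levels in common" warning
  suppressWarnings(
    GenomicRanges::countOverlaps(sg, ig, ignore.strand = !strand_aware)) > 0L
}

#' Read a gene model from BED12 or a GTF exon subset
#'
#' @param path BED12 file (blocks = exons, thickStart/thickEnd = CDS) or a
#'   GTF with exon features (no CDS information in that case).
#' @param format `"auto"` (by extension), `"bed12"` or `"gtf"`.
#' @return A list of class `gene_model`; element `transcripts` is a named
#'   list, one entry per transcript with fields `transcript_id`, `chrom`,
#'   `strand`, `exons` (2-column matrix of 0-based half-open intervals in
#'   genomic order) and `cds` (0-based half-open c(start, end) or NULL).
#' @export
read_gene_model <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff)$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  }
  if (format == "bed12") {
    gr <- rtracklayer::import(path, format = "BED")
    txs <- lapply(seq_along(gr), function(i) {
      x <- gr[i]
      bl <- x$blocks[[1]]                    # exon ranges, 1-based closed
      exons <- cbind(start = BiocGenerics::start(bl) +
                       BiocGenerics::start(x) - 2L,
                     end = BiocGenerics::end(bl) + BiocGenerics::start(x) - 1L)
      th <- x$thick
      cds <- NULL
      if (length(th) && BiocGenerics::width(th)[1] > 0L) {
        cds <- c(BiocGenerics::start(th)[1] - 1L, BiocGenerics::end(th)[1])
      }
      list(transcript_id = as.character(x$name),
           chrom = as.character(GenomicRanges::seqnames(x)),
           strand = as.character(BiocGenerics::strand(x)),
           exons = exons, cds = cds)
    })
  } else {
    gr <- rtracklayer::import(path, format = "GTF")
    gr <- gr[gr$type == "exon"]
    ids <- as.character(gr$transcript_id)
    txs <- lapply(split(seq_along(gr), ids), function(idx) {
      x <- gr[idx]
      o <- order(BiocGenerics::start(x))
      list(transcript_id = ids[idx[1]],
           chrom = as.character(GenomicRanges::seqnames(x))[1],
           strand = as.character(BiocGenerics::strand(x))[1],
           exons = cbind(start = BiocGenerics::start(x)[o] - 1L,
                         end = BiocGenerics::end(x)[o]),
           cds = NULL)
    })
  }
  names(txs) <- vapply(txs, `[[`, "", "transcript_id")
  structure(list(transcripts = txs), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene model:", length(x$transcripts), "transcript(s)\n")
  invisible(x)
}
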