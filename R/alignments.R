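## Per-site allele counting from alignments.
##
## The counting core operates on plain read records (one row per alignment:
## flag, chrom, pos, mapq, cigar, seq, qual); a thin adapter pulls those
## records out of a coordinate-sorted indexed BAM with Rsamtools.  Both
## routes share the same filters, so the BAM path and the record path are
## interchangeable in tests.

## SAM flag bits
.FLAG_UNMAPPED <- 0x4L
.FLAG_REVERSE <- 0x10L
.FLAG_SECONDARY <- 0x100L
.FLAG_DUP <- 0x400L
.FLAG_SUPPLEMENTARY <- 0x800L

has_flag <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

## Walk one CIGAR to locate the query (read) position aligned to a 1-based
## reference position. Returns NA when the site falls in a deletion/skip or
## outside the alignment. Query positions count along the stored SEQ,
## including soft-clipped bases.
query_pos_at_ref <- function(cigar, read_start, ref_target) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  qpos <- 1L
  rpos <- as.integer(read_start)
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      if (ref_target < rpos + len) {
        if (ref_target < rpos) return(NA_integer_)
        return(qpos + (ref_target - rpos))
      }
      qpos <- qpos + len
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      if (ref_target < rpos + len) return(NA_integer_)
      rpos <- rpos + len
    }
    # H and P consume neither sequence nor reference
  }
  NA_integer_
}

#' Count edited and total alleles at catalog sites
#'
#' For every site in the catalog, counts reads passing the filters whose
#' aligned base at the site is a called base (`total`) and the subset whose
#' base matches the edited allele — G at a site annotated on the `+` strand,
#' C (the genome-space complement) on the `-` strand (`edited`).
#'
#' Filters: unmapped reads are always skipped; PCR duplicates and
#' secondary/supplementary alignments are dropped per the configuration;
#' reads below the mapping-quality threshold are dropped; bases below the
#' base-quality threshold are dropped; and bases within the first
#' `trim_5prime` positions of the read *in its original sequencing
#' orientation* are masked (for reverse-strand alignments these are the last
#' stored bases). `N` bases never count.
#'
#' @param src Either a path to a coordinate-sorted, indexed BAM file, or a
#'   data.frame of read records with columns `flag`, `chrom`, `pos`
#'   (1-based leftmost), `mapq`, `cigar`, `seq`, `qual` (Phred+33 string).
#' @param catalog An `editing_sites` data.frame.
#' @param filter A [read_filter_config()].
#' @return An unfiltered counts data.frame (`chrom`, `pos`, `strand`,
#'   `edited`, `total`), one row per catalog site, suitable for
#'   [editing_profile()].
#' @export
count_site_alleles <- function(src, catalog, filter = read_filter_config()) {
  stopifnot(inherits(filter, "read_filter_config"))
  if (is.character(src)) {
    reads_by_site <- .bam_reads_by_site(src, catalog)
  } else {
    reads_by_site <- .records_by_site(src, catalog)
  }
  edited <- integer(nrow(catalog))
  total <- integer(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    rr <- reads_by_site[[i]]
    if (is.null(rr) || !nrow(rr)) next
    cnt <- .count_one_site(rr, catalog$pos[i], catalog$strand[i], filter)
    edited[i] <- cnt[1]; total[i] <- cnt[2]
  }
  data.frame(chrom = catalog$chrom, pos = catalog$pos,
             strand = catalog$strand, edited = edited, total = total,
             stringsAsFactors = FALSE)
}

## Count one site from the read records overlapping it.
.count_one_site <- function(rr, pos, strand, filter) {
  edited <- 0L; total <- 0L
  edited_base <- if (strand == "+") "G" else "C"
  for (j in seq_len(nrow(rr))) {
    flag <- as.integer(rr$flag[j])
    if (has_flag(flag, .FLAG_UNMAPPED)) next
    if (filter$drop_duplicates && has_flag(flag, .FLAG_DUP)) next
    if (filter$drop_multimappers &&
        (has_flag(flag, .FLAG_SECONDARY) ||
         has_flag(flag, .FLAG_SUPPLEMENTARY))) next
    if (is.na(rr$mapq[j]) || rr$mapq[j] < filter$min_mapq) next
    qpos <- query_pos_at_ref(rr$cigar[j], rr$pos[j], pos)
    if (is.na(qpos)) next
    qlen <- nchar(rr$seq[j])
    # position in original sequencing orientation: reverse-strand
    # alignments store the reverse complement, so sequencing position
    # counts from the other end
    seq_pos <- if (has_flag(flag, .FLAG_REVERSE)) qlen - qpos + 1L else qpos
    if (seq_pos <= filter$trim_5prime) next
    baseq <- utf8ToInt(substr(rr$qual[j], qpos, qpos)) - 33L
    if (length(baseq) != 1L || baseq < filter$min_baseq) next
    base <- toupper(substr(rr$seq[j], qpos, qpos))
    if (!base %in% c("A", "C", "G", "T")) next
    total <- total + 1L
    if (base == edited_base) edited <- edited + 1L
  }
  c(edited, total)
}

.records_by_site <- function(reads, catalog) {
  need <- c("flag", "chrom", "pos", "mapq", "cigar", "seq", "qual")
  miss <- setdiff(need, names(reads))
  if (length(miss)) stopf("read records missing column(s): %s",
                          paste(miss, collapse = ", "))
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  lapply(seq_len(nrow(catalog)), function(i) {
    hit <- reads$chrom == catalog$chrom[i] &
      reads$pos <= catalog$pos[i] &
      reads$pos + rw - 1L >= catalog$pos[i]
    reads[hit, , drop = FALSE]
  })
}

.bam_reads_by_site <- function(path, catalog) {
  if (!file.exists(path)) stopf("BAM file not found: %s", path)
  idx <- paste0(path, ".bai")
  if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", path)))
    stopf("BAM file %s is not indexed (coordinate-sorted, indexed input required)",
          path)
  bf <- Rsamtools::BamFile(path)
  seqs <- names(Rsamtools::scanBamHeader(bf)$targets)
  absent <- !catalog$chrom %in% seqs
  if (any(absent))
    warnf("%d catalog site(s) on chromosome(s) absent from %s; counted (0, 0)",
          sum(absent), basename(path))
  out <- vector("list", nrow(catalog))
  present <- which(!absent)
  if (length(present)) {
    which_gr <- GenomicRanges::GRanges(
      catalog$chrom[present],
      IRanges::IRanges(catalog$pos[present], width = 1L))
    param <- Rsamtools::ScanBamParam(
      what = c("flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
      which = which_gr)
    res <- Rsamtools::scanBam(bf, param = param)
    for (k in seq_along(present)) {
      r <- res[[k]]
      out[[present[k]]] <- data.frame(
        flag = r$flag, chrom = as.character(r$rname), pos = r$pos,
        mapq = r$mapq, cigar = r$cigar,
        seq = as.character(r$seq), qual = as.character(r$qual),
        stringsAsFactors = FALSE)
    }
  }
  out
}

#' Write read records as a SAM file
#'
#' Minimal single-end SAM emitter used for the mini-alignment fixtures that
#' exercise [count_site_alleles()]; convert with [Rsamtools::asBam()] to
#' test the BAM route.
#'
#' @param reads Read-record data.frame (see [count_site_alleles()]); an
#'   optional `qname` column is used when present.
#' @param path Output `.sam` path.
#' @param seqlengths Named integer vector of reference lengths for the
#'   header.
#' @export
write_sam <- function(reads, path, seqlengths) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  o <- order(match(reads$chrom, names(seqlengths)), reads$pos)
  reads <- reads[o, , drop = FALSE]
  qname <- if ("qname" %in% names(reads)) reads$qname
           else sprintf("read%04d", seq_len(nrow(reads)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  qname, as.integer(reads$flag), reads$chrom,
                  as.integer(reads$pos), as.integer(reads$mapq),
                  reads$cigar, reads$seq, reads$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}
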