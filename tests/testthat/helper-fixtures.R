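# In-code fixtures shared across test files.

make_catalog_file <- function(rows, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  f <- file.path(dir, "catalog.tsv")
  writeLines(c("chrom\tpos\tstrand", rows), f)
  f
}

make_exclusion_file <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos", rows), f)
  f
}

make_bed_file <- function(rows) {
  f <- tempfile(fileext = ".bed")
  writeLines(rows, f)
  f
}

make_profile <- function(edited, total, chrom = "chr1",
                         pos = seq_along(edited) * 100L,
                         strand = "+", assay = "rnaseq",
                         fraction = "whole", id = "s") {
  editing_profile(data.frame(chrom = chrom, pos = pos,
                             strand = strand, edited = edited,
                             total = total, stringsAsFactors = FALSE),
                  sample_id = id, assay = assay, fraction = fraction)
}

# toy two-exon gene model: exon [1000,2000), intron [2000,4000),
# exon [4000,5000) (0-based half-open), CDS ending at 4500 on '+'
make_toy_gene_model <- function(strand = "+") {
  tx <- list(transcript_id = "tx1", chrom = "chr1", strand = strand,
             exons = cbind(start = c(1000L, 4000L), end = c(2000L, 5000L)),
             cds = if (strand == "+") c(1000L, 4500L) else c(1500L, 5000L))
  structure(list(transcripts = list(tx1 = tx)), class = "gene_model")
}
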