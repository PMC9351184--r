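# toy model (helper): exon [1000,2000), intron [2000,4000), exon [4000,5000)

test_that("boundary binning measures strand-aware distances into features", {
  gm <- make_toy_gene_model("+")
  s <- function(pos) data.frame(chrom = "chr1", pos = pos, strand = "+")

  # 150 nt downstream of the intron 5' end (first intron base = 0-based 2000)
  bb <- bin_sites_by_boundary(s(2151), gm, "intron_5p", 200, 5)
  expect_equal(bb$counts, c(1L, 0L, 0L, 0L, 0L))
  # exactly 200 nt falls in bin 2 (half-open bins)
  bb <- bin_sites_by_boundary(s(2201), gm, "intron_5p", 200, 5)
  expect_equal(bb$counts[2], 1L)
  # the boundary base itself is distance 0, bin 1
  bb <- bin_sites_by_boundary(s(2001), gm, "intron_5p", 200, 5)
  expect_equal(bb$counts[1], 1L)
  # beyond n_bins * bin_size is uncounted
  bb <- bin_sites_by_boundary(s(3500), gm, "intron_5p", 200, 5)
  expect_equal(sum(bb$counts), 0L)
  expect_equal(bb$n_uncounted, 1L)
  # intron 3' anchor: distance counted from the other end
  bb <- bin_sites_by_boundary(s(3951), gm, "intron_3p", 200, 5)
  expect_equal(bb$counts[1], 1L)   # 49 nt from 3' end
  # exon anchors bin exonic sites
  bb <- bin_sites_by_boundary(s(1050), gm, "exon_5p", 200, 5)
  expect_equal(bb$counts[1], 1L)
  # intergenic sites are skipped
  bb <- bin_sites_by_boundary(s(9999), gm, "intron_5p", 200, 5)
  expect_equal(bb$n_skipped, 1L)
  # exonic site under an intron anchor is intragenic but uncounted
  bb <- bin_sites_by_boundary(s(1500), gm, "intron_5p", 200, 5)
  expect_equal(bb$n_uncounted, 1L)
})

test_that("minus-strand features anchor at their transcriptional ends", {
  gm <- make_toy_gene_model("-")
  s <- data.frame(chrom = "chr1", pos = 3951, strand = "-")
  # on '-', the intron's 5' end is its genomic right end (0-based 3999);
  # site 3951 (0-based 3950) is 49 nt into the intron
  bb <- bin_sites_by_boundary(s, gm, "intron_5p", 200, 5)
  expect_equal(bb$counts[1], 1L)
  bb <- bin_sites_by_boundary(s, gm, "intron_3p", 200, 5)
  # distance from the genomic-left (transcriptional 3') end: 1950 -> bin 10
  expect_equal(sum(bb$counts), 0L)
})

test_that("binning partitions every input site exactly once", {
  gm <- make_toy_gene_model("+")
  set.seed(13)
  sites <- data.frame(chrom = "chr1", pos = sample(500:6000, 300, TRUE),
                      strand = "+")
  for (anch in c("intron_5p", "intron_3p", "exon_5p", "exon_3p")) {
    bb <- bin_sites_by_boundary(sites, gm, anch, 200, 4)
    expect_equal(sum(bb$counts) + bb$n_uncounted + bb$n_skipped,
                 nrow(sites))
  }
})

test_that("multi-transcript sites are counted once at minimum distance", {
  tx2 <- list(transcript_id = "tx2", chrom = "chr1", strand = "+",
              exons = cbind(start = c(1000L, 2100L),
                            end = c(2050L, 5000L)), cds = NULL)
  gm <- make_toy_gene_model("+")
  gm$transcripts$tx2 <- tx2
  # site 0-based 2060: 60 into tx1's intron, 10 into tx2's intron
  bb <- bin_sites_by_boundary(data.frame(chrom = "chr1", pos = 2061,
                                         strand = "+"),
                              gm, "intron_5p", 50, 5)
  expect_equal(bb$counts, c(1L, 0L, 0L, 0L, 0L))   # min distance 10, bin 1
})

test_that("bin enrichment reproduces the Fisher/odds-ratio arithmetic", {
  mk_bins <- function(counts) structure(
    list(anchor = "intron_5p", bin_size = 200L, n_bins = length(counts),
         counts = as.integer(counts), n_sites = sum(counts),
         n_uncounted = 0L, n_skipped = 0L), class = "boundary_bins")
  # identical tables: all p = 1
  enr <- boundary_enrichment(mk_bins(c(10, 20, 30)), mk_bins(c(10, 20, 30)))
  expect_equal(enr$p, rep(1, 3))
  # worked example: fore 30/50 in bin 1 vs back 10/100
  enr <- boundary_enrichment(mk_bins(c(30, 20)), mk_bins(c(10, 90)))
  expect_equal(enr$odds_ratio[1], 13.5)
  expect_equal(enr$p[1], oracle_fisher_p(30, 20, 10, 90), tolerance = 1e-12)
  # empty fore bin: depletion direction, same test
  enr <- boundary_enrichment(mk_bins(c(0, 50)), mk_bins(c(40, 60)))
  expect_lt(enr$odds_ratio[1], 1)
  expect_equal(enr$p[1], oracle_fisher_p(0, 50, 40, 60), tolerance = 1e-12)
  expect_error(boundary_enrichment(mk_bins(c(1, 2)), mk_bins(c(0, 0))),
               "empty")
  expect_error(boundary_enrichment(mk_bins(c(1, 2)), mk_bins(c(1, 2, 3))),
               "compatible")
})

test_that("uniform foreground draws show no boundary enrichment", {
  gm <- make_toy_gene_model("+")
  set.seed(17)
  back_sites <- data.frame(chrom = "chr1",
                           pos = sample(2001:4000, 400, TRUE), strand = "+")
  fore_sites <- back_sites[sample(400, 120), ]
  fore <- bin_sites_by_boundary(fore_sites, gm, "intron_5p", 200, 10)
  back <- bin_sites_by_boundary(back_sites, gm, "intron_5p", 200, 10)
  enr <- boundary_enrichment(fore, back)
  expect_gte(mean(enr$p > 0.05), 0.95)
})

test_that("AS-relatedness flags sites inside event blocks", {
  ev <- data.frame(event_id = c("1", "1", "2"), event_type = "SE",
                   chrom = "chr1", strand = "+", p_value = 0.01,
                   start = c(100L, 500L, 120L), end = c(200L, 600L, 180L))
  s <- function(pos) data.frame(chrom = "chr1", pos = pos, strand = "+")
  expect_true(flag_as_related(s(150), ev))       # inside a block
  expect_false(flag_as_related(s(300), ev))      # between blocks
  # overlapping two events still a single TRUE
  expect_equal(flag_as_related(s(150), ev), TRUE)
  # brute-force agreement on random fixtures
  set.seed(19)
  sites <- s(sample(1:700, 150, TRUE))
  got <- flag_as_related(sites, ev)
  want <- vapply(seq_len(nrow(sites)), function(i)
    oracle_in_intervals(sites$chrom[i], sites$pos[i], ev), logical(1))
  expect_equal(got, want)
})

test_that("AS enrichment compares associated vs other binding sites", {
  ev <- data.frame(event_id = "1", event_type = "SE", chrom = "chr1",
                   strand = "+", p_value = 0.01, start = 0L, end = 1000L)
  s <- function(pos) data.frame(chrom = rep("chr1", length(pos)), pos = pos,
                                strand = rep("+", length(pos)))
  # 8/10 vs 2/10 AS-related: same table as the preference worked example
  assoc <- s(c(1:8 * 10, 5000, 6000))
  other <- s(c(15, 25, 5001:5008 * 1))
  other$pos <- c(15, 25, seq(5001, 5008))
  ae <- as_enrichment(assoc, other, ev)
  expect_equal(ae$n_assoc_as, 8L)
  expect_equal(ae$n_other_as, 2L)
  expect_equal(ae$p, 4252 / 184756, tolerance = 1e-12)
  expect_false(ae$or_corrected)
  # identical AS fractions: OR = 1, p = 1
  ae <- as_enrichment(s(c(100, 5000)), s(c(200, 6000)), ev)
  expect_equal(ae$odds_ratio, 1)
  expect_equal(ae$p, 1)
  # zero cell triggers the Haldane-Anscombe correction
  ae <- as_enrichment(s(rep(5000, 10)), s(c(1:5 * 10, 6001:6005)), ev)
  expect_true(ae$or_corrected)
  expect_true(is.finite(ae$odds_ratio))
  expect_error(as_enrichment(s(integer(0)), other, ev), "associated")
})
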