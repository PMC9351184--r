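test_that("site catalog reading applies exclusion, dedup and ordering", {
  f <- make_catalog_file(c("chr1\t100\t+", "chr1\t200\t+"))
  ex <- make_exclusion_file("chr1\t200")
  sites <- read_site_catalog(f, ex)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$pos, 100L)

  # empty exclusion leaves the catalog unchanged
  ex0 <- make_exclusion_file(character())
  expect_equal(nrow(read_site_catalog(f, ex0)), 2L)

  # duplicated rows merge with a warning
  fd <- make_catalog_file(c("chr1\t100\t+", "chr1\t100\t+"))
  expect_warning(sites <- read_site_catalog(fd), "duplicate")
  expect_equal(nrow(sites), 1L)

  # deterministic (chrom, pos) order regardless of input order
  fo <- make_catalog_file(c("chr2\t50\t-", "chr1\t900\t+", "chr1\t100\t+"))
  sites <- read_site_catalog(fo)
  expect_equal(sites$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(sites$pos, c(100L, 900L, 50L))
})

test_that("malformed catalog rows are rejected with their line number", {
  f <- make_catalog_file(c("chr1\t100\t+", "chr1\tnope\t+"))
  expect_error(read_site_catalog(f), "line 3")
  f2 <- make_catalog_file("chr1\t100\t*")
  expect_error(read_site_catalog(f2), "line 2")
  f3 <- make_catalog_file("chr1\t0\t+")
  expect_error(read_site_catalog(f3), "line 2")
})

test_that("peak reading parses BED6 and narrowPeak and validates intervals", {
  f <- make_bed_file("chr1\t100\t200\tpeak1\t50\t+")
  pk <- read_peaks(f)
  expect_equal(pk$start, 100L)
  expect_equal(pk$end, 200L)
  expect_equal(pk$strand, "+")

  # narrowPeak: 10 columns, only the first 6 used
  f10 <- make_bed_file(
    "chr1\t100\t200\tpeak1\t50\t+\t1.5\t2.5\t3.5\t25")
  pk10 <- read_peaks(f10)
  expect_equal(ncol(pk10), 6L)
  expect_equal(pk10$end, 200L)

  fbad <- make_bed_file(c("chr1\t100\t200\tp\t0\t+", "chr1\t200\t100\tp\t0\t+"))
  expect_error(read_peaks(fbad), "line 2")
})

test_that("rMATS reading filters by p-value and assembles type blocks", {
  f <- write_rmats_se(c(0.01, 0.04, 0.2))
  ev <- read_rmats_events(f, "SE", p_cutoff = 0.05)
  expect_equal(length(unique(ev$event_id)), 2L)   # p = 0.2 dropped
  expect_true(all(ev$p_value < 0.05))

  # empty table -> empty result
  f0 <- write_rmats_se(numeric(0))
  expect_equal(nrow(read_rmats_events(f0, "SE")), 0L)

  # RI: a single block from the retained-intron region columns
  fri <- tempfile()
  write.table(data.frame(ID = 1, GeneID = "g", geneSymbol = "G",
                         chr = "chr1", strand = "+",
                         riExonStart_0base = 100, riExonEnd = 900,
                         upstreamES = 100, upstreamEE = 300,
                         downstreamES = 700, downstreamEE = 900,
                         PValue = 0.01, FDR = 0.01),
              fri, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- read_rmats_events(fri, "RI")
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start, ev$end), c(100L, 900L))

  # MXE yields two blocks per event
  fmxe <- tempfile()
  write.table(data.frame(ID = 1, GeneID = "g", geneSymbol = "G",
                         chr = "chr1", strand = "+",
                         `1stExonStart_0base` = 100, `1stExonEnd` = 200,
                         `2ndExonStart_0base` = 400, `2ndExonEnd` = 500,
                         upstreamES = 0, upstreamEE = 50,
                         downstreamES = 600, downstreamEE = 700,
                         PValue = 0.01, FDR = 0.01, check.names = FALSE),
              fmxe, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- read_rmats_events(fmxe, "MXE")
  expect_equal(nrow(ev), 2L)
  expect_setequal(ev$start, c(100L, 400L))

  expect_error(read_rmats_events(f, "XX"), "unknown")
  expect_error(read_rmats_events(fri, "SE"), "exonStart_0base")
})

test_that("site/interval overlap follows the half-open convention", {
  iv <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  s <- function(pos) data.frame(chrom = "chr1", pos = pos, strand = "+")
  expect_true(site_in_intervals(s(150), iv))    # inside
  expect_false(site_in_intervals(s(100), iv))   # 0-based 99, before start
  expect_true(site_in_intervals(s(101), iv))    # 0-based 100, at start
  expect_true(site_in_intervals(s(200), iv))    # 0-based 199, last base
  expect_false(site_in_intervals(s(201), iv))   # 0-based 200, past end
  expect_false(site_in_intervals(data.frame(chrom = "chr2", pos = 150,
                                            strand = "+"), iv))
})

test_that("overlap agrees with a brute-force scan on random fixtures", {
  set.seed(11)
  iv <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                   start = sample(0:500, 30, TRUE))
  iv$end <- iv$start + sample(1:80, 30, TRUE)
  sites <- data.frame(chrom = sample(c("chr1", "chr2", "chr3"), 200, TRUE),
                      pos = sample(1:600, 200, TRUE), strand = "+")
  got <- site_in_intervals(sites, iv)
  want <- vapply(seq_len(nrow(sites)), function(i)
    oracle_in_intervals(sites$chrom[i], sites$pos[i], iv), logical(1))
  expect_equal(got, want)
})

test_that("strand-aware overlap only matches same-strand intervals", {
  iv <- data.frame(chrom = "chr1", start = 100L, end = 200L, strand = "-")
  s <- data.frame(chrom = "chr1", pos = 150L, strand = "+")
  expect_true(site_in_intervals(s, iv))                       # default
  expect_false(site_in_intervals(s, iv, strand_aware = TRUE))
  s$strand <- "-"
  expect_true(site_in_intervals(s, iv, strand_aware = TRUE))
})

test_that("table formats round-trip exactly", {
  sites <- data.frame(chrom = c("chr1", "chr2"), pos = c(5L, 7L),
                      strand = c("+", "-"), site_id = c("a", "b"),
                      stringsAsFactors = FALSE)
  class(sites) <- c("editing_sites", "data.frame")
  f <- tempfile()
  write_site_catalog(sites, f)
  back <- read_site_catalog(f)
  expect_equal(as.data.frame(back), as.data.frame(sites))

  prof <- make_profile(c(3L, 5L), c(20L, 30L))
  fc <- tempfile()
  write_counts(prof, fc)
  back <- read_counts(fc, sample_id = "s")
  expect_equal(as.data.frame(back), as.data.frame(prof))

  pk <- read_peaks(make_bed_file(c("chr1\t10\t50\tp1\t5\t+",
                                   "chr2\t0\t9\tp2\t1\t-")))
  fp <- tempfile()
  write_peaks(pk, fp)
  expect_equal(as.data.frame(read_peaks(fp)), as.data.frame(pk))

  net <- rbp_network(data.frame(rbp_a = "B", rbp_b = "A", weight = 3),
                     nodes = c("A", "B", "C"))
  fn <- tempfile()
  write_edge_list(net, fn)
  expect_equal(read_edge_list(fn, nodes = net$nodes)$edges, net$edges)
})

test_that("BED12 gene models import with exons and CDS intact", {
  gm0 <- make_toy_gene_model("+")
  f <- tempfile(fileext = ".bed")
  rbped:::.write_bed12(gm0, f)
  gm <- read_gene_model(f)
  tx <- gm$transcripts$tx1
  expect_equal(unname(tx$exons[, "start"]), c(1000L, 4000L))
  expect_equal(unname(tx$exons[, "end"]), c(2000L, 5000L))
  expect_equal(tx$cds, c(1000L, 4500L))
  expect_equal(tx$strand, "+")
})
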