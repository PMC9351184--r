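test_that("two-sided Fisher p matches known worked tables", {
  # 8/10 edited in eCLIP vs 2/10 in background: 4252/184756
  expect_equal(fisher_exact_2x2(8, 2, 2, 8), 4252 / 184756,
               tolerance = 1e-12)
  # identical rows are maximally unsurprising
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  # swapping the rows leaves p unchanged
  expect_equal(fisher_exact_2x2(8, 2, 2, 8), fisher_exact_2x2(2, 8, 8, 2))
  # degenerate empty table
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1)
})

test_that("Fisher p agrees with the enumeration oracle and fisher.test", {
  set.seed(42)
  for (rep in 1:200) {
    m <- sample(0:25, 1); n <- sample(0:25, 1)
    a <- if (m > 0) sample(0:m, 1) else 0
    c <- if (n > 0) sample(0:n, 1) else 0
    p <- fisher_exact_2x2(a, m - a, c, n - c)
    expect_equal(p, oracle_fisher_p(a, m - a, c, n - c), tolerance = 1e-12)
    if (m + n > 0) {
      pf <- stats::fisher.test(matrix(c(a, m - a, c, n - c), 2,
                                      byrow = TRUE))$p.value
      expect_equal(p, pf, tolerance = 1e-9)
    }
  }
})

test_that("site preference test reports delta with the Fisher p", {
  st <- site_preference_test(8, 10, 2, 10)
  expect_equal(st$p, 4252 / 184756, tolerance = 1e-12)
  expect_equal(st$delta, 0.6)
  # swapping the assays negates delta, keeps p
  sw <- site_preference_test(2, 10, 8, 10)
  expect_equal(sw$p, st$p)
  expect_equal(sw$delta, -st$delta)
})

test_that("exact signed-rank test matches full sign enumeration", {
  # worked case: 5 equal positive deltas
  wt <- wilcoxon_signed_exact(rep(0.2, 5))
  expect_true(wt$exact)
  expect_equal(wt$p, 0.0625, tolerance = 1e-15)

  # exact branch vs 2^n enumeration for n <= 12, with and without ties
  set.seed(7)
  for (n in c(1:12)) {
    d <- round(stats::rnorm(n), 2)
    expect_equal(wilcoxon_signed_exact(d)$p, oracle_wilcoxon_p(d),
                 tolerance = 1e-12)
    d_tied <- sample(c(-0.2, 0.2, 0.4, -0.4), n, replace = TRUE)
    expect_equal(wilcoxon_signed_exact(d_tied)$p,
                 oracle_wilcoxon_p(d_tied), tolerance = 1e-12)
  }

  # matches wilcox.test in tie-free exact cases
  set.seed(8)
  d <- stats::rnorm(15)
  expect_equal(wilcoxon_signed_exact(d)$p,
               stats::wilcox.test(d, exact = TRUE)$p.value,
               tolerance = 1e-12)

  # symmetric deltas carry no preference
  expect_equal(wilcoxon_signed_exact(c(-0.2, 0.2, -0.3, 0.3))$p, 1)

  # all-zero deltas degenerate to p = 1
  wt0 <- wilcoxon_signed_exact(c(0, 0, 0))
  expect_true(wt0$degenerate)
  expect_equal(wt0$p, 1)
})

test_that("large-sample signed-rank branch tracks the normal approximation", {
  set.seed(9)
  d <- stats::rnorm(60, mean = 0.15)
  got <- wilcoxon_signed_exact(d)
  expect_false(got$exact)
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
  expect_equal(got$p, ref, tolerance = 1e-9)
})

test_that("BH adjustment matches the step-up oracle and its invariances", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(1.0), 1.0)
  expect_equal(adjust_bh(0.013), 0.013)   # m = 1 leaves p unchanged

  set.seed(10)
  for (rep in 1:20) {
    p <- stats::runif(sample(1:40, 1))
    adj <- adjust_bh(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-14)
    # permutation invariance
    perm <- sample(seq_along(p))
    expect_equal(adjust_bh(p[perm]), adj[perm], tolerance = 1e-14)
    # monotone nondecreasing along sorted p
    expect_true(all(diff(adj[order(p)]) >= -1e-14))
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
})

test_that("profile pairing intersects retained sites and honors blacklist", {
  ec <- make_profile(c(8L, 9L, 5L, 7L, 6L), rep(10L, 5), assay = "eclip")
  bg <- make_profile(c(2L, 2L, 5L, 2L, 2L), rep(10L, 5))
  pairs <- pair_profiles(ec, bg)
  expect_equal(nrow(pairs), 5L)
  expect_equal(pairs$delta[1], 0.6)

  # blacklisted site removed
  bl <- data.frame(chrom = "chr1", pos = 200L)
  expect_equal(nrow(pair_profiles(ec, bg, blacklist = bl)), 4L)

  # site present in eCLIP only is excluded
  bg2 <- bg[-1, , drop = FALSE]
  expect_equal(nrow(pair_profiles(ec, bg2)), 4L)

  # peak restriction applies before pairing
  pk <- as_peak_set(data.frame(chrom = "chr1", start = 99L, end = 101L,
                               name = "p", score = 0, strand = "+"))
  expect_equal(nrow(pair_profiles(ec, bg, peaks = pk)), 1L)

  # empty intersection is an empty pairing, not an error
  far <- make_profile(5L, 10L, pos = 99999L)
  expect_equal(nrow(pair_profiles(ec, far)), 0L)
})

test_that("site classification applies strict delta and alpha thresholds", {
  mk <- function(ee, te, eb, tb) {
    ec <- make_profile(ee, te, assay = "eclip")
    bg <- make_profile(eb, tb)
    pair_profiles(ec, bg)
  }
  # strong favored call
  calls <- classify_sites(mk(80L, 100L, 20L, 100L), rbp = "X")
  expect_equal(calls$call, "favored")
  # delta exactly at +0.1 is ns (strict inequality)
  calls <- classify_sites(mk(200L, 1000L, 100L, 1000L))
  expect_equal(calls$delta, 0.1)
  expect_true(calls$p_adj < 0.05)
  expect_equal(calls$call, "ns")
  # large delta without significance is ns
  calls <- classify_sites(mk(4L, 10L, 8L, 10L))
  expect_equal(calls$call, "ns")
  # disfavored direction
  calls <- classify_sites(mk(20L, 100L, 80L, 100L))
  expect_equal(calls$call, "disfavored")
  # raw-p mode reproduces the unadjusted reading
  pairs <- mk(c(16L, 5L), c(20L, 20L), c(8L, 5L), c(20L, 20L))
  raw <- classify_sites(pairs, adjust = FALSE)
  expect_equal(raw$p, raw$p_adj)
})

test_that("global preference test summarizes pairs", {
  ec <- make_profile(rep(8L, 5), rep(10L, 5), assay = "eclip")
  bg <- make_profile(rep(2L, 5), rep(10L, 5))
  pairs <- pair_profiles(ec, bg)
  g <- global_preference_test(pairs, rbp = "X", cell_line = "K562")
  expect_equal(g$n_sites, 5L)
  expect_equal(g$wilcoxon_p, 0.0625)
  expect_equal(g$median_delta, 0.6)
  expect_false(g$significant)   # threshold is 1e-5
  # median is over all pairs, zeros included
  ec2 <- make_profile(c(8L, 5L, 5L), rep(10L, 3), assay = "eclip")
  bg2 <- make_profile(c(2L, 5L, 5L), rep(10L, 3))
  g2 <- global_preference_test(pair_profiles(ec2, bg2))
  expect_equal(g2$median_delta, 0)
  expect_error(global_preference_test(pair_profiles(ec, make_profile(5L, 10L,
                                                                     pos = 1L))),
               "at least one pair")
})
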