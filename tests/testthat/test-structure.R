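test_that("3'UTR assignment is strand-aware and transcript-coordinated", {
  # toy model: exons [1000,2000) and [4000,5000); '+' CDS ends at 4500,
  # so the '+' 3'UTR is [4500,5000)
  gm <- make_toy_gene_model("+")
  s <- function(pos, strand = "+") data.frame(chrom = "chr1", pos = pos,
                                              strand = strand)
  utr <- annotate_3utr_sites(s(4551), gm)
  expect_equal(nrow(utr), 1L)
  expect_equal(utr$utr_pos, 51L)   # 50 nt past the CDS end
  # CDS sites are excluded
  expect_equal(nrow(annotate_3utr_sites(s(1500), gm)), 0L)
  expect_equal(nrow(annotate_3utr_sites(s(4400), gm)), 0L)
  # intronic position past the CDS end is not exonic UTR
  expect_equal(nrow(annotate_3utr_sites(s(3000), gm)), 0L)

  # '-' transcript: CDS starts at 1500, so the genomic-left [1000,1500)
  # is 3'UTR; transcript coordinates count from the genomic right
  gmm <- make_toy_gene_model("-")
  utr <- annotate_3utr_sites(s(1001, "-"), gmm)
  expect_equal(nrow(utr), 1L)
  expect_equal(utr$utr_pos, 500L)  # genomic-left base = UTR 3' extremity
  utr <- annotate_3utr_sites(s(1500, "-"), gmm)
  expect_equal(utr$utr_pos, 1L)    # adjacent to the stop codon

  # transcripts without CDS are skipped
  gm0 <- gm
  gm0$transcripts$tx1$cds <- NULL
  expect_equal(nrow(annotate_3utr_sites(s(4551), gm0)), 0L)
})

test_that("PARS scores map onto paired/unpaired/free constraints", {
  expect_equal(unclass(pars_to_constraints(c(3, -3, 0), threshold = 1)),
               c("paired", "unpaired", "free"))
  # unprobed bases stay free
  expect_equal(unclass(pars_to_constraints(c(NA, NA), threshold = 1)),
               c("free", "free"))
  # threshold is exclusive
  expect_equal(unclass(pars_to_constraints(c(1, -1), threshold = 1)),
               c("free", "free"))
  expect_error(pars_to_constraints(c(1, 2), threshold = 0), "positive")
  expect_error(pars_to_constraints(c(1, 2), len = 5), "length")
  # data.frame form fills unlisted positions with NA
  df <- data.frame(pos = c(1, 3), score = c(5, -5))
  expect_equal(unclass(pars_to_constraints(df, len = 3)),
               c("paired", "free", "unpaired"))
})

test_that("in-silico editing rewrites exactly the given adenosines", {
  expect_equal(apply_editing("AUAUA", 3), "AUGUA")
  expect_equal(apply_editing("AUAUA", integer(0)), "AUAUA")
  expect_equal(apply_editing("AUAUA", c(1, 5)), "GUAUG")
  expect_error(apply_editing("AUAUA", 2), "non-A")
  expect_error(apply_editing("AUA", 9), "outside")
})

test_that("reference fold handles hand-checkable sequences", {
  expect_equal(reference_fold("AAAA")$mfe, 0)
  f <- reference_fold("GGGAAACCC")
  expect_equal(f$mfe, -3)
  expect_equal(f$structure, "(((...)))")
  # minimum loop of 3 forbids pairing in short hairpins
  expect_equal(reference_fold("GAAAC")$mfe, -1)
  expect_equal(reference_fold("GAAC")$mfe, 0)
  # DNA alphabet is folded as RNA
  expect_equal(reference_fold("GGGTTTCCC")$mfe, -3)
})

test_that("reference fold equals exhaustive enumeration up to 14 nt", {
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(5:14, 1)
    seq <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
    f <- reference_fold(seq)
    expect_equal(-f$mfe, oracle_max_pairs(seq), info = seq)
    # returned structure is balanced and consistent with the energy
    expect_equal(nrow(fold_pairs(f$structure)), -f$mfe)
  }
})

test_that("constraints are honored and never add pairs", {
  # hard 'unpaired' excludes a base from the stem
  cons <- rep("free", 9)
  cons[1] <- "unpaired"
  f <- reference_fold("GGGAAACCC", cons)
  expect_equal(f$mfe, -2)
  expect_equal(-f$mfe, oracle_max_pairs("GGGAAACCC",
                                        blocked = c(TRUE, rep(FALSE, 8))))
  # satisfiable 'paired' flags are satisfied
  cons2 <- rep("free", 9)
  cons2[2] <- "paired"
  f2 <- reference_fold("GGGAAACCC", cons2)
  expect_equal(length(f2$unsatisfied), 0L)
  expect_true(2 %in% c(f2$pairs))
  # unsatisfiable 'paired' flag is relaxed with a warning and reported
  cons3 <- rep("free", 4)
  cons3[2] <- "paired"
  expect_warning(f3 <- reference_fold("AAAA", cons3), "relaxed")
  expect_equal(f3$unsatisfied, 2L)
  # monotonicity: constraining never increases the pair count
  set.seed(29)
  for (rep in 1:25) {
    seq <- paste(sample(c("A", "C", "G", "U"), 40, TRUE), collapse = "")
    free <- reference_fold(seq)
    cons <- rep("free", 40)
    cons[sample(40, 6)] <- "unpaired"
    constrained <- suppressWarnings(reference_fold(seq, cons))
    expect_gte(constrained$mfe, free$mfe)
  }
})

test_that("delta MFE is antisymmetric and detects stem-breaking edits", {
  # identical inputs for both states give delta 0
  d0 <- delta_mfe("GGGAAACCC", integer(0))
  expect_equal(d0$delta, 0)
  # editing an A inside the stem: delta equals the enumerated pair-count
  # difference between the two sequences
  hairpin <- "GCGAAACAAAGUUUCGC"
  dm4 <- delta_mfe(hairpin, 4)
  expect_equal(dm4$delta,
               oracle_max_pairs(hairpin) -
                 oracle_max_pairs(apply_editing(hairpin, 4)))
  # delta decomposes into the two independent folds
  seq <- "GGCAUAACCAAUGGCC"
  f <- reference_fold(seq)
  fe <- reference_fold(apply_editing(seq, 6))
  dm <- delta_mfe(seq, 6)
  expect_equal(dm$delta, fe$mfe - f$mfe)
  # constrained state ordering: fully 'unpaired' fold can never beat free
  cons <- structure(rep("unpaired", nchar(seq)), class = "fold_constraint")
  dmc <- suppressWarnings(delta_mfe(seq, integer(0),
                                    constraints_edited = cons,
                                    constraints_unedited = NULL))
  expect_gte(dmc$mfe_edited, dmc$mfe_unedited)
})

test_that("simulated hairpins weaken upon stem editing", {
  # editing a stem adenosine turns an A-U pair into a G-U wobble: the
  # combinatorial pair count never drops (the reference engine's delta is
  # <= 0), but the thermodynamic fold destabilizes
  cfg <- sim_config(n_sites = 50, n_rbps = 2, n_effects = 5,
                    n_transcripts = 4, seed = 5)
  sim <- simulate_counts(cfg)
  world <- simulate_peaks_and_model(cfg, sim)
  for (tx in names(world$transcripts)) {
    ep <- world$edit_pos[[tx]]
    if (!length(ep)) next
    dm <- delta_mfe(world$transcripts[[tx]], ep)
    expect_lte(dm$delta, 0)
    dmv <- delta_mfe(world$transcripts[[tx]], ep, folder = vienna_fold)
    expect_gt(dmv$delta, 0)
  }
})

test_that("RNAfold backend folds a stable hairpin when available", {
  f <- vienna_fold("GGGGGAAAACCCCC")
  expect_lt(f$mfe, 0)
  expect_equal(nchar(f$structure), 14L)
  expect_true(nrow(f$pairs) > 0)
  # constraint folding forces bases open
  cons <- structure(rep("unpaired", 14), class = "fold_constraint")
  fc <- vienna_fold("GGGGGAAAACCCCC", cons)
  expect_equal(nrow(fc$pairs), 0L)
  expect_gte(fc$mfe, f$mfe)
})
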