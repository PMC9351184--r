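## Seeded generators for every input the pipeline consumes, with planted
## ground truth: binomial edited/total counts per site per assay, planted
## eCLIP-vs-background editing differences, peak intervals covering the
## planted sites, a toy gene model, rMATS-style event tables, and
## hairpin-bearing toy 3'UTR transcripts with PARS-like scores.

#' Simulation configuration
#'
#' Defines the synthetic study: how many sites and RBPs, sequencing-depth
#' and background editing-level distributions, the planted effect size, and
#' the geometry of peaks, gene models and AS events.
#'
#' @param n_sites Number of catalog editing sites (default 2000).
#' @param n_rbps Number of RBPs (default 5).
#' @param n_effects Planted (RBP, site) effects in total (default 100).
#' @param true_delta Absolute planted editing-level difference (default
#'   0.4); sign is random per effect, with the background level drawn so
#'   the shifted level stays inside \[0, 1\].
#' @param depth_range Per-site per-assay depth bounds, drawn uniformly
#'   (default c(11, 100), i.e. every site passes the depth filter).
#' @param planted_depth_min Minimum depth at planted sites in both assays
#'   (default 50).
#' @param level_shape1,level_shape2 Beta parameters of the background
#'   editing-level distribution (default Beta(1.5, 6), right-skewed low
#'   levels as observed for A-to-I editing).
#' @param peak_halfwidth Peaks extend this many bases on each side of a
#'   covered site (default 100).
#' @param peak_null_cover Fraction of non-planted sites additionally
#'   covered by each RBP's peaks (default 0.3).
#' @param as_overlap Fraction of sites covered by differential AS-event
#'   blocks (default 0.3).
#' @param n_transcripts Toy hairpin transcripts for the structure module
#'   (default 10).
#' @param seed Integer seed; mandatory, all outputs are reproducible.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_sites = 2000L, n_rbps = 5L, n_effects = 100L,
                       true_delta = 0.4, depth_range = c(11L, 100L),
                       planted_depth_min = 50L, level_shape1 = 1.5,
                       level_shape2 = 6, peak_halfwidth = 100L,
                       peak_null_cover = 0.3, as_overlap = 0.3,
                       n_transcripts = 10L, seed) {
  if (missing(seed)) stopf("sim_config requires an explicit seed")
  stopifnot(n_sites >= 1, n_rbps >= 1, n_effects >= 0,
            abs(true_delta) <= 1, depth_range[1] >= 1,
            depth_range[1] <= depth_range[2])
  structure(list(n_sites = as.integer(n_sites), n_rbps = as.integer(n_rbps),
                 n_effects = as.integer(n_effects), true_delta = true_delta,
                 depth_range = as.integer(depth_range),
                 planted_depth_min = as.integer(planted_depth_min),
                 level_shape1 = level_shape1, level_shape2 = level_shape2,
                 peak_halfwidth = as.integer(peak_halfwidth),
                 peak_null_cover = peak_null_cover,
                 as_overlap = as_overlap,
                 n_transcripts = as.integer(n_transcripts),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.site_grid <- function(cfg) {
  # sites every 500 bp on two toy chromosomes
  chrom <- rep(c("chrS1", "chrS2"), length.out = cfg$n_sites)
  idx <- ave(seq_len(cfg$n_sites), chrom, FUN = seq_along)
  data.frame(chrom = chrom, pos = 1000L + idx * 500L,
             strand = rep_len(c("+", "-"), cfg$n_sites),
             stringsAsFactors = FALSE)
}

#' Simulate editing counts with planted eCLIP preferences
#'
#' Draws a true background editing level per site, then binomial
#' edited/total counts per assay: background fractions (whole, nucleus,
#' cytosol) all sample the same true level; each RBP's eCLIP counts sample
#' `clip(level + true_delta, 0, 1)` at its planted sites and the unshifted
#' level elsewhere. The binomial (no overdispersion) read model matches the
#' sampling assumption of the per-site Fisher test, so calibration checks
#' are directly interpretable. Use `overdispersion > 0` for a
#' beta-binomial robustness variant.
#'
#' @param cfg A [sim_config()].
#' @param overdispersion Beta-binomial intra-class correlation rho in
#'   `[0, 1)`; 0 (default) = pure binomial.
#' @return List: `catalog` (editing_sites-style data.frame), `background`
#'   (list of `editing_profile`s: whole, nucleus, cytosol), `eclip` (named
#'   list of per-RBP `editing_profile`s, unrestricted), `truth`
#'   (data.frame rbp, chrom, pos, strand, true_delta covering every
#'   planted effect), `levels` (per-site true background levels).
#' @export
simulate_counts <- function(cfg, overdispersion = 0) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  sites <- .site_grid(cfg)
  n <- cfg$n_sites
  level <- rbeta(n, cfg$level_shape1, cfg$level_shape2)
  # plant effects: spread over RBPs, sites sampled without replacement so
  # no (rbp, site) pair repeats and each planted site belongs to one RBP
  rbps <- sprintf("RBP%02d", seq_len(cfg$n_rbps))
  n_eff <- min(cfg$n_effects, n)
  eff_site <- sample.int(n, n_eff)
  eff_rbp <- rbps[rep_len(seq_len(cfg$n_rbps), n_eff)]
  eff_sign <- ifelse(runif(n_eff) < 0.5, 1, -1)
  # background level at planted sites redrawn so the shift is feasible
  level[eff_site] <- ifelse(eff_sign > 0, runif(n_eff, 0.1, 0.5),
                            runif(n_eff, 0.5, 0.9))
  draw_depth <- function(min_depth = cfg$depth_range[1]) {
    lo <- pmax(min_depth, cfg$depth_range[1])
    lo + floor(runif(n) * (pmax(cfg$depth_range[2], lo) - lo + 1))
  }
  rbinom2 <- function(size, prob) {
    if (overdispersion > 0) {
      rho <- overdispersion
      a <- prob * (1 - rho) / rho
      b <- (1 - prob) * (1 - rho) / rho
      prob <- rbeta(length(size), pmax(a, 1e-9), pmax(b, 1e-9))
    }
    rbinom(length(size), size, prob)
  }
  make_profile <- function(p_site, depth, id, assay, fraction) {
    edited <- rbinom2(depth, p_site)
    editing_profile(data.frame(chrom = sites$chrom, pos = sites$pos,
                               strand = sites$strand, edited = edited,
                               total = depth, stringsAsFactors = FALSE),
                    sample_id = id, assay = assay, fraction = fraction)
  }
  planted_any <- seq_len(n) %in% eff_site
  bg_depth <- function() {
    d <- draw_depth()
    d[planted_any] <- pmax(d[planted_any], cfg$planted_depth_min)
    d
  }
  background <- list(
    whole = make_profile(level, bg_depth(), "rnaseq_whole", "rnaseq", "whole"),
    nucleus = make_profile(level, bg_depth(), "rnaseq_nucleus", "rnaseq",
                           "nucleus"),
    cytosol = make_profile(level, bg_depth(), "rnaseq_cytosol", "rnaseq",
                           "cytosol"))
  truth <- data.frame(rbp = eff_rbp, chrom = sites$chrom[eff_site],
                      pos = sites$pos[eff_site],
                      strand = sites$strand[eff_site],
                      true_delta = eff_sign * cfg$true_delta,
                      stringsAsFactors = FALSE)
  infeasible <- level[eff_site] + truth$true_delta
  if (any(infeasible < 0 | infeasible > 1))
    warnf("%d planted effect(s) clipped at [0, 1]",
          sum(infeasible < 0 | infeasible > 1))
  eclip <- lapply(rbps, function(r) {
    p <- level
    mine <- eff_site[eff_rbp == r]
    p[mine] <- pmin(1, pmax(0, level[mine] +
                              truth$true_delta[match(mine, eff_site)]))
    d <- draw_depth()
    d[seq_len(n) %in% mine] <- pmax(d[seq_len(n) %in% mine],
                                    cfg$planted_depth_min)
    make_profile(p, d, paste0("eclip_", r), "eclip", "whole")
  })
  names(eclip) <- rbps
  catalog <- data.frame(sites, site_id = sprintf("site%05d", seq_len(n)),
                        stringsAsFactors = FALSE)
  class(catalog) <- c("editing_sites", "data.frame")
  list(catalog = catalog, background = background, eclip = eclip,
       truth = truth, levels = level)
}

#' Simulate peaks, gene model, AS events, PARS scores and transcripts
#'
#' Builds the interval-world companions of [simulate_counts()]: per-RBP
#' peaks guaranteed to cover that RBP's planted sites (plus a random share
#' of null sites), a toy gene model whose transcripts tile the site grid
#' with exons, introns and a CDS so sites land in introns near boundaries
#' and in 3'UTRs, rMATS-style differential-event tables whose blocks cover
#' a planted fraction of sites, and hairpin 3'UTR transcripts in which
#' editing a stem adenosine turns an A-U pair into a weaker G-U wobble
#' (conserving the combinatorial pair count while destabilizing a
#' thermodynamic fold), with matching PARS-like scores (positive over the
#' stem, negative over the loop).
#'
#' @param cfg A [sim_config()].
#' @param sim Output of [simulate_counts()] for the same config.
#' @return List: `peaks` (named list of `peak_set`), `gene_model`,
#'   `as_events` (`as_events` data.frame), `rmats` (data.frame in rMATS SE
#'   layout, including non-significant rows), `transcripts` (named
#'   character vector of 3'UTR sequences), `pars` (named list of per-base
#'   score vectors), `edit_pos` (named list of stem A positions),
#'   `as_truth` (logical: which catalog sites an AS block covers).
#' @export
simulate_peaks_and_model <- function(cfg, sim) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)
  sites <- sim$catalog
  n <- nrow(sites)
  hw <- cfg$peak_halfwidth
  peaks <- lapply(names(sim$eclip), function(r) {
    mine <- which(paste(sites$chrom, sites$pos) %in%
                    paste(sim$truth$chrom, sim$truth$pos)[sim$truth$rbp == r])
    extra <- which(runif(n) < cfg$peak_null_cover)
    cover <- sort(union(mine, extra))
    if (!length(cover)) cover <- 1L
    pk <- data.frame(chrom = sites$chrom[cover],
                     start = pmax(0L, sites$pos[cover] - 1L - hw),
                     end = sites$pos[cover] + hw,
                     name = sprintf("%s_peak%04d", r, seq_along(cover)),
                     score = 100, strand = sites$strand[cover],
                     stringsAsFactors = FALSE)
    as_peak_set(pk, rbp = r)
  })
  names(peaks) <- names(sim$eclip)

  # gene model: one transcript per 10 consecutive sites on each chromosome;
  # alternating exon/intron blocks 1000 bp wide starting 250 bp before the
  # first covered site, so sites alternate between exons and introns and
  # sit at fixed distances from the block boundaries; CDS ends one block
  # before the transcript end, leaving a 3'UTR exon
  txs <- list()
  for (ch in unique(sites$chrom)) {
    sp <- sites$pos[sites$chrom == ch]
    grp <- split(sp, (seq_along(sp) - 1) %/% 10)
    for (gi in seq_along(grp)) {
      lo <- min(grp[[gi]]) - 250L
      hi <- max(grp[[gi]]) + 750L
      bounds <- seq(lo, hi, by = 1000L)
      if (length(bounds) < 3) bounds <- c(lo, lo + 1000L, hi + 1000L)
      nb <- length(bounds) - 1L
      exon_idx <- seq(1L, nb, by = 2L)
      exons <- cbind(start = bounds[exon_idx] - 1L,
                     end = bounds[exon_idx + 1L] - 1L)
      strand <- if (gi %% 2 == 0) "-" else "+"
      cds <- if (strand == "+")
        c(exons[1, 1], exons[max(1, nrow(exons) - 1), 2])
      else c(exons[min(2, nrow(exons)), 1], exons[nrow(exons), 2])
      id <- sprintf("%s_tx%03d", ch, gi)
      txs[[id]] <- list(transcript_id = id, chrom = ch, strand = strand,
                        exons = exons, cds = cds)
    }
  }
  gene_model <- structure(list(transcripts = txs), class = "gene_model")

  # AS events: SE-style blocks centered on a planted fraction of sites
  as_hit <- runif(n) < cfg$as_overlap
  hit_idx <- which(as_hit)
  rmats <- data.frame(
    ID = seq_len(n), GeneID = sprintf("gene%04d", seq_len(n)),
    geneSymbol = sprintf("G%04d", seq_len(n)), chr = sites$chrom,
    strand = sites$strand,
    exonStart_0base = ifelse(as_hit, sites$pos - 1L - 50L,
                             sites$pos + 10000L),
    exonEnd = ifelse(as_hit, sites$pos + 50L, sites$pos + 10100L),
    upstreamES = sites$pos - 2000L, upstreamEE = sites$pos - 1900L,
    downstreamES = sites$pos + 1900L, downstreamEE = sites$pos + 2000L,
    # planted-overlap rows are differential; the remaining rows mix
    # significant and non-significant events so the p filter has work to do
    PValue = ifelse(as_hit, 0.001, ifelse(seq_len(n) %% 2 == 0, 0.5, 0.001)),
    FDR = 0.01, stringsAsFactors = FALSE)
  as_truth <- as_hit & rmats$PValue < 0.05

  # hairpin transcripts: 5' side GC-rich stem with one A, loop, complement
  n_tx <- cfg$n_transcripts
  transcripts <- character(n_tx)
  pars <- vector("list", n_tx)
  edit_pos <- vector("list", n_tx)
  names(transcripts) <- sprintf("utr%03d", seq_len(n_tx))
  for (i in seq_len(n_tx)) {
    stem5 <- c("G", "G", "C", "G", "A", "C", "G", "C")
    loop <- sample(c("A", "C"), 5, replace = TRUE)
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    stem3 <- rev(unname(comp[stem5]))
    tail <- sample(c("A", "C"), 6, replace = TRUE)
    seqv <- c(stem5, loop, stem3, tail)
    transcripts[i] <- paste(seqv, collapse = "")
    sc <- rep(NA_real_, length(seqv))
    sc[seq_along(stem5)] <- 3
    sc[length(stem5) + seq_along(loop)] <- -3
    pars[[i]] <- sc
    edit_pos[[i]] <- which(seqv == "A" & seq_along(seqv) <= length(stem5))
  }
  names(pars) <- names(transcripts)
  names(edit_pos) <- names(transcripts)

  ev <- rmats[rmats$PValue < 0.05, , drop = FALSE]
  as_events <- data.frame(event_id = as.character(ev$ID), event_type = "SE",
                          chrom = ev$chr, strand = ev$strand,
                          p_value = ev$PValue, start = ev$exonStart_0base,
                          end = ev$exonEnd, stringsAsFactors = FALSE)
  class(as_events) <- c("as_events", "data.frame")

  list(peaks = peaks, gene_model = gene_model, as_events = as_events,
       rmats = rmats, transcripts = transcripts, pars = pars,
       edit_pos = edit_pos, as_truth = as_truth)
}

#' Simulate a mini-alignment over one site
#'
#' Emits plain read records (usable directly by [count_site_alleles()] or
#' written as SAM via [write_sam()]) carrying a chosen number of edited and
#' unedited reads across the site, plus optional reads that each filter
#' should reject.
#'
#' @param chrom,pos,strand Site coordinates.
#' @param n_edited,n_unedited Reads carrying the edited / reference base.
#' @param read_len Read length (default 30).
#' @param mapq Mapping quality of passing reads (default 60).
#' @param baseq Base quality character for all bases (default "I" = Q40).
#' @param seed Seed for read placement.
#' @return Read-record data.frame.
#' @export
simulate_site_reads <- function(chrom, pos, strand, n_edited, n_unedited,
                                read_len = 30L, mapq = 60L, baseq = "I",
                                seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- n_edited + n_unedited
  # reads start so the site sits past the 5' trim region on both strands
  offs <- sample(8:(read_len - 8), n, replace = TRUE)
  ref_base <- if (strand == "+") "A" else "T"
  alt_base <- if (strand == "+") "G" else "C"
  base <- c(rep(alt_base, n_edited), rep(ref_base, n_unedited))
  rev <- rep_len(c(FALSE, TRUE), n)
  seqs <- vapply(seq_len(n), function(i) {
    s <- rep("C", read_len)
    s[offs[i]] <- base[i]
    paste(s, collapse = "")
  }, "")
  data.frame(qname = sprintf("r%04d", seq_len(n)),
             flag = ifelse(rev, 16L, 0L), chrom = chrom,
             pos = pos - offs + 1L, mapq = mapq,
             cigar = paste0(read_len, "M"), seq = seqs,
             qual = strrep(baseq, read_len), stringsAsFactors = FALSE)
}

#' Write the full synthetic fixture tree
#'
#' Emits every file of the synthetic study in the pipeline's standard
#' dialects: site catalog, per-profile counts TSVs, per-RBP peak BEDs, the
#' rMATS-style SE table, the gene model as BED12, the 3'UTR FASTA, the
#' PARS score TSV, the RBP location table and the planted-truth tables.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created).
#' @return Invisibly, the list of written paths.
#' @export
write_fixture_tree <- function(cfg, dir) {
  sim <- simulate_counts(cfg)
  world <- simulate_peaks_and_model(cfg, sim)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$catalog <- file.path(dir, "catalog.tsv")
  write_site_catalog(sim$catalog, paths$catalog)
  for (fr in names(sim$background)) {
    p <- file.path(dir, sprintf("counts_rnaseq_%s.tsv", fr))
    write_counts(sim$background[[fr]], p)
    paths[[paste0("counts_", fr)]] <- p
  }
  for (r in names(sim$eclip)) {
    p <- file.path(dir, sprintf("counts_eclip_%s.tsv", r))
    write_counts(sim$eclip[[r]], p)
    paths[[paste0("counts_eclip_", r)]] <- p
    pb <- file.path(dir, sprintf("peaks_%s.bed", r))
    write_peaks(world$peaks[[r]], pb)
    paths[[paste0("peaks_", r)]] <- pb
  }
  paths$rmats <- file.path(dir, "SE.MATS.JC.txt")
  write_tsv(world$rmats, paths$rmats)
  paths$gene_model <- file.path(dir, "gene_model.bed")
  .write_bed12(world$gene_model, paths$gene_model)
  paths$fasta <- file.path(dir, "utr3.fa")
  Biostrings::writeXStringSet(
    Biostrings::RNAStringSet(world$transcripts), paths$fasta)
  pars_df <- do.call(rbind, lapply(names(world$pars), function(tx) {
    sc <- world$pars[[tx]]
    ok <- !is.na(sc)
    data.frame(transcript = tx, pos = which(ok), score = sc[ok],
               stringsAsFactors = FALSE)
  }))
  paths$pars <- file.path(dir, "pars.tsv")
  write_tsv(pars_df, paths$pars)
  paths$truth <- file.path(dir, "truth.tsv")
  write_tsv(sim$truth, paths$truth)
  paths$locations <- file.path(dir, "locations.tsv")
  write_tsv(data.frame(rbp = names(sim$eclip), location = "whole",
                       stringsAsFactors = FALSE), paths$locations)
  utr_edits <- do.call(rbind, lapply(names(world$edit_pos), function(tx) {
    if (!length(world$edit_pos[[tx]])) return(NULL)
    data.frame(transcript = tx, pos = world$edit_pos[[tx]],
               stringsAsFactors = FALSE)
  }))
  paths$utr_edits <- file.path(dir, "utr_edit_sites.tsv")
  write_tsv(utr_edits, paths$utr_edits)
  invisible(paths)
}

.write_bed12 <- function(gene_model, path) {
  rows <- vapply(gene_model$transcripts, function(tx) {
    ex <- tx$exons
    chromStart <- ex[1, 1]
    chromEnd <- ex[nrow(ex), 2]
    cds <- tx$cds %||% c(chromStart, chromStart)
    sizes <- ex[, 2] - ex[, 1]
    starts <- ex[, 1] - chromStart
    paste(tx$chrom, chromStart, chromEnd, tx$transcript_id, 0, tx$strand,
          cds[1], cds[2], "0", nrow(ex),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","), sep = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}
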