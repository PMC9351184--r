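## End-to-end orchestration mirroring the analysis order: quantify ->
## cross-fraction concordance/blacklist -> per-RBP pairing + global and
## per-site preference tests -> editing / peak networks + permutation
## comparison -> splicing association -> PARS-constrained structure delta.

#' Pipeline run configuration
#'
#' All thresholds default to the analysis values: 5' trim 6, MAPQ > 20,
#' baseQ >= 30, depth > 10 with >= 1 edited read, global Wilcoxon p < 1e-5,
#' adjusted per-site p < 0.05 with |delta| > 0.1, AS p < 0.05, 200-nt
#' boundary bins, 2000 network permutations.
#'
#' @param catalog Site-catalog TSV path.
#' @param counts_background Named character vector (or list) of background
#'   counts TSVs, names = fractions (`whole`, `nucleus`, `cytosol`).
#' @param counts_eclip Named character vector of per-RBP eCLIP counts TSVs.
#' @param peaks Named character vector of per-RBP peak BED files.
#' @param exclusion,locations,rmats,gene_model,fasta,pars,utr_edits
#'   Optional input paths (`rmats` may be named by event type; unnamed
#'   entries are read as SE). `utr_edits` is a TSV (`transcript`, `pos`)
#'   of editable positions along the FASTA sequences.
#' @param out_dir Output directory.
#' @param seed Integer seed for the stochastic stages.
#' @param thresholds Named list overriding individual defaults.
#' @return List of class `run_config`.
#' @export
run_config <- function(catalog, counts_background, counts_eclip, peaks,
                       exclusion = NULL, locations = NULL, rmats = NULL,
                       gene_model = NULL, fasta = NULL, pars = NULL,
                       utr_edits = NULL, out_dir = "rbped_run", seed = 1L,
                       thresholds = list()) {
  th <- modifyList(list(min_depth = 11L, min_edited = 1L, fdr = 0.05,
                        alpha = 0.05, min_delta = 0.1, adjust = TRUE,
                        global_p = 1e-5, as_p = 0.05, bin_size = 200L,
                        n_bins = 10L, n_perm = 2000L, pars_threshold = 1),
                   thresholds)
  structure(list(catalog = catalog,
                 counts_background = as.list(counts_background),
                 counts_eclip = as.list(counts_eclip),
                 peaks = as.list(peaks), exclusion = exclusion,
                 locations = locations, rmats = rmats,
                 gene_model = gene_model, fasta = fasta, pars = pars,
                 utr_edits = utr_edits, out_dir = out_dir,
                 seed = as.integer(seed), thresholds = th),
            class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full pipeline
#'
#' Executes every analysis stage on the configured inputs and writes all
#' module outputs plus a JSON run manifest (package version, thresholds,
#' input checksums) under `cfg$out_dir`. Outputs are a pure function of
#' (inputs, thresholds, seed): a rerun with the same configuration is
#' byte-identical.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  th <- cfg$thresholds
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(catalog = cfg$catalog, unlist(cfg$counts_background),
              unlist(cfg$counts_eclip), unlist(cfg$peaks),
              exclusion = cfg$exclusion, locations = cfg$locations,
              rmats = cfg$rmats, gene_model = cfg$gene_model,
              fasta = cfg$fasta, pars = cfg$pars, utr_edits = cfg$utr_edits)
  missing_in <- inputs[!file.exists(unlist(inputs))]
  if (length(missing_in))
    stopf("pipeline stage 'inputs' failed: missing file(s): %s",
          paste(missing_in, collapse = ", "))

  catalog <- .stage("catalog", read_site_catalog(cfg$catalog, cfg$exclusion))

  background <- .stage("quantify", {
    lapply(stats::setNames(names(cfg$counts_background),
                           names(cfg$counts_background)), function(fr)
      retain_sites(read_counts(cfg$counts_background[[fr]],
                               sample_id = paste0("rnaseq_", fr),
                               assay = "rnaseq", fraction = fr),
                   min_depth = th$min_depth, min_edited = th$min_edited))
  })

  blacklist <- .stage("concordance", {
    bl <- data.frame(chrom = character(), pos = integer())
    fracs <- names(background)
    conc <- list()
    if (length(fracs) >= 2) {
      for (i in seq_len(length(fracs) - 1)) for (j in (i + 1):length(fracs)) {
        fc <- fraction_concordance(background[[fracs[i]]],
                                   background[[fracs[j]]], fdr = th$fdr)
        conc[[paste(fracs[i], fracs[j], sep = "_vs_")]] <- fc
        if (nrow(fc$blacklist))
          bl <- rbind(bl, fc$blacklist[, c("chrom", "pos")])
      }
    }
    conc_df <- do.call(rbind, lapply(names(conc), function(nm)
      data.frame(comparison = nm, n_shared = conc[[nm]]$n_shared,
                 pearson_r = conc[[nm]]$pearson_r,
                 n_blacklisted = nrow(conc[[nm]]$blacklist))))
    if (!is.null(conc_df)) write_tsv(conc_df,
                                     file.path(out, "concordance.tsv"))
    unique(bl)
  })
  write_tsv(blacklist, file.path(out, "blacklist.tsv"))

  locations <- if (!is.null(cfg$locations)) {
    lt <- read_tsv(cfg$locations)
    stats::setNames(lt$location, lt$rbp)
  } else NULL

  fits <- .stage("preference", {
    lapply(stats::setNames(names(cfg$counts_eclip),
                           names(cfg$counts_eclip)), function(r) {
      ec <- retain_sites(read_counts(cfg$counts_eclip[[r]],
                                     sample_id = r, assay = "eclip"),
                         min_depth = th$min_depth,
                         min_edited = th$min_edited)
      pk <- read_peaks(cfg$peaks[[r]], rbp = r)
      loc <- if (!is.null(locations) && r %in% names(locations))
        locations[[r]] else "whole"
      if (!loc %in% names(background)) loc <- "whole"
      rbped(ec, background[[loc]], peaks = pk, blacklist = blacklist,
            rbp = r, alpha = th$alpha, min_delta = th$min_delta,
            adjust = th$adjust, global_p = th$global_p)
    })
  })
  calls <- do.call(rbind, lapply(fits, as.data.frame))
  rownames(calls) <- NULL
  write_tsv(calls, file.path(out, "site_calls.tsv"))
  write_tsv(global_summary_table(fits), file.path(out, "global_summary.tsv"))

  comparison <- .stage("network", {
    net_edit <- build_editing_network(calls)
    peaks_all <- lapply(stats::setNames(names(cfg$peaks), names(cfg$peaks)),
                        function(r) read_peaks(cfg$peaks[[r]], rbp = r))
    net_peak <- build_peak_network(peaks_all)
    write_edge_list(net_edit, file.path(out, "network_editing.tsv"))
    write_edge_list(net_peak, file.path(out, "network_peaks.tsv"))
    cmp <- compare_networks(net_edit, net_peak, n_perm = th$n_perm,
                            seed = cfg$seed)
    jsonlite::write_json(unclass(cmp), file.path(out, "network_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    cmp
  })

  if (!is.null(cfg$rmats) || !is.null(cfg$gene_model)) .stage("splicing", {
    assoc <- calls[calls$call != "ns", , drop = FALSE]
    others <- calls[calls$call == "ns", , drop = FALSE]
    if (!is.null(cfg$gene_model)) {
      gm <- read_gene_model(cfg$gene_model)
      bins <- lapply(c("intron_5p", "intron_3p", "exon_5p", "exon_3p"),
                     function(anch) {
        fg <- bin_sites_by_boundary(assoc, gm, anchor = anch,
                                    bin_size = th$bin_size,
                                    n_bins = th$n_bins)
        bg <- bin_sites_by_boundary(catalog, gm, anchor = anch,
                                    bin_size = th$bin_size,
                                    n_bins = th$n_bins)
        enr <- if (sum(bg$counts) > 0 && sum(fg$counts) > 0)
          boundary_enrichment(fg, bg) else NULL
        cbind(anchor = anch, bin = seq_len(fg$n_bins), fore = fg$counts,
              back = bg$counts,
              p = if (is.null(enr)) NA_real_ else enr$p,
              p_adj = if (is.null(enr)) NA_real_ else enr$p_adj)
      })
      write_tsv(as.data.frame(do.call(rbind, bins)),
                file.path(out, "boundary_bins.tsv"))
    }
    if (!is.null(cfg$rmats)) {
      type <- names(cfg$rmats) %||% "SE"
      if (!length(type) || !nzchar(type[1])) type <- "SE"
      events <- read_rmats_events(unlist(cfg$rmats)[1], event_type = type[1],
                                  p_cutoff = th$as_p)
      per_rbp <- do.call(rbind, lapply(names(fits), function(r) {
        a <- assoc[assoc$rbp == r, , drop = FALSE]
        o <- others[others$rbp == r, , drop = FALSE]
        if (!nrow(a) || !nrow(o)) return(NULL)
        ae <- as_enrichment(a, o, events)
        data.frame(rbp = r, n_assoc_as = ae$n_assoc_as,
                   n_assoc_total = ae$n_assoc_total,
                   n_other_as = ae$n_other_as,
                   n_other_total = ae$n_other_total,
                   odds_ratio = ae$odds_ratio, p = ae$p,
                   or_corrected = ae$or_corrected)
      }))
      if (!is.null(per_rbp))
        write_tsv(per_rbp, file.path(out, "as_association.tsv"))
    }
  })

  if (!is.null(cfg$fasta)) .stage("structure", {
    seqs <- Biostrings::readBStringSet(cfg$fasta)
    seqs <- stats::setNames(as.character(seqs), names(seqs))
    pars <- if (!is.null(cfg$pars)) read_pars_scores(cfg$pars) else list()
    edits <- if (!is.null(cfg$utr_edits)) {
      ed <- read_tsv(cfg$utr_edits)
      split(ed$pos, ed$transcript)
    } else list()
    rows <- lapply(names(seqs), function(tx) {
      ep <- edits[[tx]]
      if (is.null(ep) || !length(ep)) return(NULL)
      cons <- if (!is.null(pars[[tx]]))
        pars_to_constraints(pars[[tx]], len = nchar(seqs[[tx]]),
                            threshold = th$pars_threshold) else NULL
      dm <- delta_mfe(seqs[[tx]], ep, constraints_edited = cons,
                      constraints_unedited = cons)
      data.frame(transcript = tx, n_edits = length(ep),
                 mfe_edited = dm$mfe_edited, mfe_unedited = dm$mfe_unedited,
                 delta = dm$delta,
                 structure_edited = dm$fold_edited$structure,
                 structure_unedited = dm$fold_unedited$structure,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (!is.null(tab)) write_tsv(tab, file.path(out, "structure_delta.tsv"))
  })

  manifest <- list(
    package = "rbped",
    version = as.character(utils::packageVersion("rbped")),
    seed = cfg$seed, thresholds = th,
    inputs = lapply(as.list(inputs), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    n_rbps = length(fits),
    n_calls = nrow(calls),
    network = list(p_strength = comparison$p_strength,
                   p_invariance = comparison$p_invariance))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
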