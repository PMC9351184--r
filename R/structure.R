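## Secondary-structure change upon in-silico A-to-I editing of 3'UTR
## sequences, folded under PARS-derived constraints.  The folding engine is
## pluggable: any function (sequence, constraint) -> list(structure, mfe)
## works.  The package ships a constrained maximum-base-pairing reference
## engine (energy = -1 per pair) and a wrapper around ViennaRNA's RNAfold
## for thermodynamic energies.

#' Assign editing sites to transcript 3'UTRs
#'
#' A site belongs to a transcript's 3'UTR when it falls in exonic sequence
#' 3' of the CDS end (strand-aware: genomic coordinates above the CDS end
#' on `+` transcripts, below the CDS start on `-` transcripts). The site's
#' position is also converted to a 1-based coordinate along the 3'UTR
#' sequence in transcript orientation (`utr_pos`), matching the coordinate
#' system of the PARS score tables and the extracted UTR FASTA.
#'
#' Transcripts without CDS annotation are skipped.
#'
#' @param sites Data.frame with `chrom`, `pos` (1-based), `strand`.
#' @param gene_model A `gene_model` whose transcripts carry `cds`.
#' @return Data.frame with `transcript_id`, `chrom`, `pos`, `strand`,
#'   `utr_pos`; one row per (site, transcript) assignment.
#' @export
annotate_3utr_sites <- function(sites, gene_model) {
  res <- list()
  for (tx in gene_model$transcripts) {
    if (is.null(tx$cds)) next
    utr <- .utr3_blocks(tx)
    if (is.null(utr) || !nrow(utr)) next
    hit <- which(sites$chrom == tx$chrom &
                   site_in_intervals(sites, data.frame(chrom = tx$chrom,
                                                       start = utr[, 1],
                                                       end = utr[, 2])))
    for (i in hit) {
      res[[length(res) + 1L]] <- data.frame(
        transcript_id = tx$transcript_id, chrom = sites$chrom[i],
        pos = sites$pos[i], strand = sites$strand[i],
        utr_pos = .utr_coord(utr, tx$strand, sites$pos[i] - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(transcript_id = character(), chrom = character(),
                      pos = integer(), strand = character(),
                      utr_pos = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## exonic 0-based half-open blocks 3' of the stop codon, in genomic order
.utr3_blocks <- function(tx) {
  ex <- tx$exons
  if (tx$strand == "+") {
    cut <- tx$cds[2]                     # first UTR base (0-based)
    keep <- ex[, 2] > cut
    if (!any(keep)) return(NULL)
    ex <- ex[keep, , drop = FALSE]
    ex[1, 1] <- max(ex[1, 1], cut)
  } else {
    cut <- tx$cds[1]                     # UTR is genomically left of CDS
    keep <- ex[, 1] < cut
    if (!any(keep)) return(NULL)
    ex <- ex[keep, , drop = FALSE]
    ex[nrow(ex), 2] <- min(ex[nrow(ex), 2], cut)
  }
  ex
}

## 1-based position along the UTR in transcript orientation
.utr_coord <- function(utr, strand, pos0) {
  widths <- utr[, 2] - utr[, 1]
  blk <- which(pos0 >= utr[, 1] & pos0 < utr[, 2])
  offset_genomic <- sum(widths[seq_len(blk - 1)]) + (pos0 - utr[blk, 1])
  if (strand == "+") offset_genomic + 1L
  else sum(widths) - offset_genomic
}

#' Convert PARS scores to folding constraints
#'
#' Positive PARS scores indicate double-strandedness: a base scoring above
#' `+threshold` is constrained paired, below `-threshold` unpaired, and
#' anything in between (or unprobed) is left free.
#'
#' @param scores Numeric vector of per-base PARS scores along the sequence
#'   (NA = unprobed), or a data.frame with `pos` (1-based) and `score`
#'   (requires `len`).
#' @param len Sequence length (required for the data.frame form; otherwise
#'   checked against `length(scores)`).
#' @param threshold Positive score threshold (default 1).
#' @return Character vector of class `fold_constraint` over
#'   `{"paired", "unpaired", "free"}`.
#' @export
pars_to_constraints <- function(scores, len = length(scores), threshold = 1) {
  if (threshold <= 0) stopf("PARS threshold must be positive")
  if (is.data.frame(scores)) {
    v <- rep(NA_real_, len)
    if (any(scores$pos < 1 | scores$pos > len))
      stopf("PARS position outside sequence of length %d", len)
    v[scores$pos] <- scores$score
    scores <- v
  }
  if (length(scores) != len)
    stopf("PARS profile length %d does not match sequence length %d",
          length(scores), len)
  out <- rep("free", len)
  out[!is.na(scores) & scores > threshold] <- "paired"
  out[!is.na(scores) & scores < -threshold] <- "unpaired"
  structure(out, class = "fold_constraint")
}

#' Edit a sequence in silico (A-to-I, read as G)
#'
#' Inosine is read as guanosine by polymerases and sequencers, so in-silico
#' editing replaces A with G at the given transcript positions.
#'
#' @param seq RNA or DNA sequence string in transcript orientation.
#' @param positions 1-based positions to edit; each must hold an A.
#' @return The edited sequence string.
#' @export
apply_editing <- function(seq, positions) {
  if (!length(positions)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  if (any(positions < 1 | positions > length(ch)))
    stopf("edit position outside sequence of length %d", length(ch))
  bad <- positions[toupper(ch[positions]) != "A"]
  if (length(bad))
    stopf("cannot edit non-A base '%s' at position %d", ch[bad[1]], bad[1])
  ch[positions] <- ifelse(ch[positions] == "A", "G", "g")
  paste(ch, collapse = "")
}

.can_pair <- function(x, y) {
  paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

#' Reference folding engine: constrained maximum base pairing
#'
#' Nussinov-style dynamic program maximizing the number of Watson-Crick or
#' GU wobble pairs with a minimum hairpin loop of 3 unpaired bases,
#' honoring per-base constraints: `unpaired` bases never pair (hard);
#' `paired` bases are driven into pairs whenever any structure allows it,
#' and positions whose `paired` flag cannot be satisfied are relaxed to
#' free with a warning and reported. Energy is `-1` per pair (a pair-count
#' surrogate, not kcal/mol). The traceback is deterministic, preferring
#' the 5'-most pairing partner.
#'
#' @param seq Sequence string (T is treated as U; case-insensitive).
#' @param constraint Optional `fold_constraint` (or character vector) of
#'   the sequence length.
#' @return List of class `fold_result`: `structure` (dot-bracket), `mfe`
#'   (= -pairs), `pairs` (2-column matrix of 1-based pair indices),
#'   `unsatisfied` (positions whose `paired` flag was relaxed).
#' @export
reference_fold <- function(seq, constraint = NULL) {
  ch <- toupper(strsplit(seq, "")[[1]])
  ch[ch == "T"] <- "U"
  n <- length(ch)
  stopifnot(n >= 1)
  if (is.null(constraint)) constraint <- rep("free", n)
  if (length(constraint) != n)
    stopf("constraint length %d does not match sequence length %d",
          length(constraint), n)
  forced <- constraint == "paired"
  blocked <- constraint == "unpaired"
  # bonus per satisfied 'paired' flag large enough to dominate pair count,
  # so the DP first maximizes satisfied flags, then pairs
  bonus <- n + 1
  sc <- function(i, j) 1 + bonus * (forced[i] + forced[j])
  M <- matrix(0, n, n)
  pairable <- function(i, j) {
    j - i >= 4 && !blocked[i] && !blocked[j] && .can_pair(ch[i], ch[j])
  }
  for (span in 4:max(4, n - 1)) {
    if (span > n - 1) break
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i + 1, j]                # i unpaired
      for (k in (i + 4):j) {
        if (!pairable(i, k)) next
        left <- if (k - 1 >= i + 1) M[i + 1, k - 1] else 0
        right <- if (k + 1 <= j) M[k + 1, j] else 0
        cand <- left + right + sc(i, k)
        if (cand > best) best <- cand
      }
      M[i, j] <- best
    }
  }
  # deterministic traceback, preferring the 5'-most partner of i
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1, n))
  if (n >= 2) {
    while (length(stack)) {
      ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      i <- ij[1]; j <- ij[2]
      if (i >= j || j - i < 4) next
      target <- M[i, j]
      found <- FALSE
      if (i + 4 <= j) for (k in (i + 4):j) {
        if (!pairable(i, k)) next
        left <- if (k - 1 >= i + 1) M[i + 1, k - 1] else 0
        right <- if (k + 1 <= j) M[k + 1, j] else 0
        if (left + right + sc(i, k) == target) {
          pairs <- rbind(pairs, c(i, k))
          if (k - 1 >= i + 1) stack[[length(stack) + 1]] <- c(i + 1, k - 1)
          if (k + 1 <= j) stack[[length(stack) + 1]] <- c(k + 1, j)
          found <- TRUE
          break
        }
      }
      if (!found) stack[[length(stack) + 1]] <- c(i + 1, j)
    }
  }
  db <- rep(".", n)
  if (nrow(pairs)) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  paired_pos <- c(pairs[, 1], pairs[, 2])
  unsat <- which(forced & !(seq_len(n) %in% paired_pos))
  if (length(unsat))
    warnf("%d 'paired' constraint(s) unsatisfiable; relaxed to free (positions %s)",
          length(unsat), paste(head(unsat, 5), collapse = ", "))
  structure(list(structure = paste(db, collapse = ""),
                 mfe = -nrow(pairs), pairs = pairs,
                 unsatisfied = unsat),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$structure, "\n")
  cat(sprintf("mfe = %g (%d pair(s))\n", x$mfe, nrow(x$pairs)))
  invisible(x)
}

#' Thermodynamic folding via ViennaRNA's RNAfold
#'
#' Wraps the `RNAfold` command-line program (default parameters, constraint
#' folding via `-C`): `paired` becomes `|`, `unpaired` `x`, `free` `.` in
#' the constraint string. Requires `RNAfold` on the PATH.
#'
#' @inheritParams reference_fold
#' @return A `fold_result` with `mfe` in kcal/mol.
#' @export
vienna_fold <- function(seq, constraint = NULL) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) stopf("RNAfold not found on PATH")
  args <- c("--noPS")
  input <- seq
  if (!is.null(constraint)) {
    cs <- c(free = ".", paired = "|", unpaired = "x")[constraint]
    args <- c(args, "-C")
    input <- c(seq, paste(cs, collapse = ""))
  }
  out <- system2(exe, args, input = input, stdout = TRUE)
  last <- out[length(out)]
  m <- regmatches(last, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", last))[[1]]
  if (length(m) != 3) stopf("could not parse RNAfold output: %s", last)
  db <- m[2]
  structure(list(structure = db, mfe = as.numeric(m[3]),
                 pairs = fold_pairs(db), unsatisfied = integer(0)),
            class = "fold_result")
}

#' Base pairs of a dot-bracket structure
#' @param structure Dot-bracket string.
#' @return 2-column matrix of 1-based (i, j) pairs.
#' @export
fold_pairs <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stopf("unbalanced dot-bracket string")
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stopf("unbalanced dot-bracket string")
  pairs
}

#' Folding-energy change upon in-silico editing
#'
#' Folds the edited sequence (A replaced by G at the edit positions) under
#' the control-condition constraints and the unedited sequence under the
#' knockdown-condition constraints, and reports the energy difference
#' `delta = mfe_edited - mfe_unedited` (negative delta = editing
#' stabilizes the fold under the chosen engine's energy).
#'
#' @param seq Unedited sequence in transcript orientation.
#' @param edit_positions 1-based positions to edit (must be A).
#' @param constraints_edited,constraints_unedited Optional
#'   `fold_constraint`s applied to the respective states.
#' @param folder Folding engine, e.g. [reference_fold] (default) or
#'   [vienna_fold].
#' @return List of class `delta_mfe`: `mfe_edited`, `mfe_unedited`,
#'   `delta`, `fold_edited`, `fold_unedited`.
#' @export
delta_mfe <- function(seq, edit_positions,
                      constraints_edited = NULL,
                      constraints_unedited = NULL,
                      folder = reference_fold) {
  edited <- apply_editing(seq, edit_positions)
  fe <- folder(edited, constraints_edited)
  fu <- folder(seq, constraints_unedited)
  structure(list(mfe_edited = fe$mfe, mfe_unedited = fu$mfe,
                 delta = fe$mfe - fu$mfe,
                 fold_edited = fe, fold_unedited = fu),
            class = "delta_mfe")
}

#' @export
print.delta_mfe <- function(x, ...) {
  cat(sprintf("delta MFE = %g (edited %g, unedited %g)\n",
              x$delta, x$mfe_edited, x$mfe_unedited))
  invisible(x)
}

#' Read per-base PARS scores
#' @param path TSV with columns `transcript`, `pos` (1-based along the
#'   3'UTR sequence), `score`.
#' @return Named list, transcript -> data.frame(pos, score).
#' @export
read_pars_scores <- function(path) {
  df <- read_tsv(path)
  need <- c("transcript", "pos", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s): %s", path,
                          paste(miss, collapse = ", "))
  lapply(split(df[, c("pos", "score")], df$transcript), function(x) {
    rownames(x) <- NULL
    x
  })
}
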