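---
title: "Methods: quantifying RBP preference for A-to-I edited RNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying RBP preference for A-to-I edited RNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbped)
```

## The measurement and its logic

A-to-I editing converts adenosines in double-stranded RNA into inosines,
which reverse transcription and sequencing report as guanosines. At a
catalogued editing site the *editing level* is therefore the fraction of
aligned reads carrying G (C for sites annotated on the minus strand) over
the total passing depth.

An eCLIP library is a biased sample of the transcriptome: it contains only
fragments crosslinked to one RBP. If the protein binds edited and unedited
copies of a sequence indifferently, the editing level of a site inside its
binding peaks should match the level of the same site in RNA-seq from the
same cellular compartment. A systematic excess (deficit) of the edited
allele among bound reads is evidence that the protein favors (disfavors)
the edited form. `rbped` turns that comparison into calibrated statistics
at two scales:

- **Globally per RBP**, a two-sided paired Wilcoxon signed-rank test on
  the per-site differences Δᵢ = levelᵢ(eCLIP) − levelᵢ(background). This
  is a rank test because editing-level differences are bounded, skewed and
  heteroskedastic; it asks only whether the bound transcriptome is shifted
  toward or away from editing overall.
- **Per site**, a two-sided Fisher exact test on the 2×2 table
  `[[edited, unedited]_eCLIP; [edited, unedited]_RNA-seq]`. The exact
  conditional test is the right tool here because many sites sit at low
  coverage, where normal approximations to a difference of proportions are
  unreliable; the read counts themselves carry the uncertainty.

Both read-count columns are assumed to be independent binomial samples of
the underlying allele fractions. That ignores overdispersion between
biological replicates (see *Limitations*).

## Filters and thresholds

All defaults are set in one place (`run_config()`) and every one is
overridable:

| parameter | default | meaning |
|---|---|---|
| `trim_5prime` | 6 nt | read bases masked at the 5′ end, in as-sequenced orientation (ligation/priming artifacts around crosslink sites) |
| `min_mapq` | 21 | keep mapping quality strictly above 20 |
| `min_baseq` | 30 | keep base calls with Phred quality ≥ 30 |
| `min_depth` | 11 | keep sites with total depth strictly above 10 |
| `min_edited` | 1 | require at least one edited read |
| `global_p` | 1e-5 | significance of the per-RBP signed-rank test |
| `alpha` | 0.05 | per-site threshold on the BH-adjusted Fisher p |
| `min_delta` | 0.1 | minimum absolute level difference for a call (strict) |
| `fdr` | 0.05 | adjusted-p cutoff for the cross-fraction blacklist |
| `as_p` | 0.05 | rMATS p-value cutoff defining differential AS events |
| `bin_size` | 200 nt | boundary-bin width |
| `n_perm` | 2000 | network permutations |
| `pars_threshold` | 1.0 | PARS score magnitude forcing a constraint |

Boundary readings are deliberately literal and covered by tests: "coverage
higher than 10" keeps depth ≥ 11; "quality less than 30 filtered out" keeps
baseQ ≥ 30; "difference higher than 10%" is a strict `|Δ| > 0.1`, so a site
at exactly 0.1 is `ns`. The 5′ trim is positional masking during counting
rather than physical read trimming, which avoids re-alignment artifacts; on
reverse-strand alignments the masked positions are counted from the
as-sequenced end of the stored sequence.

Replicates are merged by summing per-site counts *after* read filtering and
*before* site retention, so a site weakly covered in each replicate can
still clear the depth filter on pooled evidence. The merge is applied
symmetrically to RNA-seq and eCLIP replicates; only the former is strictly
required by the workflow, but there is no statistical reason to treat
bound-fragment replicates differently.

The background profile for an RBP is the RNA-seq fraction matching its
annotated subcellular location (a two-column `rbp location` table);
whole-cell is the fallback, and sites flagged as fraction-discordant by the
concordance step are excluded from pairing.

## Multiple testing

Per-site p-values are BH-adjusted within one (RBP, cell line) family —
each RBP's site calls stand on their own, and families of very different
sizes are not pooled. `classify_sites(adjust = FALSE)` reproduces the
raw-p reading. The adjustment family is a genuine design choice (per-RBP,
per-cell-line or global are all defensible); per-(RBP, cell line) is the
default because the calls are reported per RBP.

## Exactness of the two core tests

The Fisher p is computed by full enumeration of the conditional
hypergeometric distribution: p = Σ of point probabilities ≤ the observed
one, with a relative tolerance of 1e-7 guarding floating-point ties (the
convention of `stats::fisher.test`, which serves as an independent
cross-check in the tests). The suite sweeps every table with both row sums
≤ 30 against a `choose()`-based oracle at 1e-12.

The signed-rank test drops zero differences, midranks ties, and enumerates
the exact null for n ≤ 25 via a dynamic program over doubled ranks
(equivalent to the full 2ⁿ sign enumeration, which the tests perform
directly for n ≤ 12). Beyond n = 25 it switches to the normal
approximation with tie correction and continuity correction. Two-sided
p-values are `min(1, 2·min(lower, upper))`. With every difference zero the
test is degenerate and reports p = 1 with a flag.

## Networks and the permutation comparison

Two RBP–RBP networks summarize the association structure: edge weights are
either the number of shared associated editing sites (favored and
disfavored pooled — a site is "associated" either way) or the number of
bases shared by the two RBPs' merged peak sets (merging first, so
self-overlapping peaks count once).

Comparing the two requires a null in which only the assignment of weights
to networks is exchangeable. After dividing each network's weights by its
maximum (shared-site counts and base counts are not commensurable), the
test statistics are the global-strength difference `s = |Σw₁ − Σw₂|` and
the invariance statistic `m = max|w₁ − w₂|` over the union edge set. The
permutation null swaps the two weights of each union edge independently
with probability ½, preserving each edge's weight pair and the degree
structure while breaking any systematic assignment. This edge-swap scheme
is this package's operationalization of the network comparison test for
the situation where only the two networks (not the underlying multivariate
data) exist; alternative schemes can be plugged in upstream of
`compare_networks()`. P-values use the add-one estimator
`(1 + k)/(1 + N)`, which cannot reach zero and floors at 1/2001 for the
default 2000 permutations.

## Splicing association

Distances to exon/intron boundaries are measured strand-awarely (the 5′
end of a minus-strand intron is its genomic right end) inside the anchored
feature, in half-open 200-nt bins with distance 0 at the boundary base; a
site on several transcripts counts once at its minimum distance, which is
deterministic and avoids double-counting. Enrichment per bin is a
two-sided Fisher test of the foreground bin count against a background
site set binned the same way (the package also accepts any background the
user supplies — the choice of background is the main open degree of
freedom here, and the pipeline default is all catalog sites inside gene
bodies of the same cell line).

AS association compares the fraction of an RBP's associated sites inside
differential-event coordinate blocks against the *tested-but-ns* sites in
the same RBP's peaks — the natural control, since those sites share the
binding context but not the editing preference. The odds ratio is raw
unless the table has a zero cell, in which case the Haldane–Anscombe 0.5
correction is applied and flagged.

## Structure change upon editing

Sites are assigned to a transcript's 3′UTR when they fall in exonic
sequence 3′ of the stop codon (strand-aware), and converted to 1-based
coordinates along the UTR sequence — the coordinate system of the PARS
tables and the UTR FASTA. PARS scores follow the standard sign convention
(positive = double-stranded); scores above +t force a base paired, below
−t unpaired, everything else (including unprobed bases) stays free. The
threshold default of 1.0 is deliberately conservative: PARS scores near
zero are uninformative.

Folding is delegated to any engine satisfying the
`(sequence, constraint) → (structure, mfe)` contract. The shipped
reference engine is a Nussinov-style maximum-base-pairing dynamic program
(Watson–Crick + GU wobble, minimum hairpin loop 3, energy −1 per pair)
with constraint handling: `unpaired` is hard; `paired` positions receive a
bonus large enough to dominate the pair count, so the DP first satisfies
as many `paired` flags as any structure can, then maximizes pairs;
`paired` flags that no structure can satisfy are relaxed to free with a
warning and reported. The traceback prefers the 5′-most partner, making
structures deterministic. `vienna_fold()` wraps RNAfold (default
parameters, `-C` constraints) for thermodynamic energies in kcal/mol.

ΔMFE is defined as MFE(edited) − MFE(unedited); positive values mean
editing destabilizes the fold under the chosen engine. The sign convention
is a documented package choice. The two states may be folded under
different constraint sets — the intended use pairs the edited state with
control-condition PARS data and the unedited state with ADAR-knockdown
PARS data, since knocking down the editing enzyme shifts transcripts
toward the unedited structure; the pairing is configurable because probing
conditions vary between studies.

One consequence of the reference engine's combinatorics is worth stating
plainly: under maximum base pairing *with GU wobble*, an A→G edit can
never reduce the pair count, because every A–U pair remains admissible as
G–U; the reference ΔMFE of an edit is therefore ≤ 0. The thermodynamic
destabilization of replacing an A–U pair by a G–U wobble is only visible
to an energy-based engine, which is why the hairpin checks in the test
suite assert ΔMFE ≤ 0 for the reference engine and ΔMFE > 0 for RNAfold.

## The synthetic study

The generator produces every input the pipeline consumes, with planted
ground truth, under one seed. Its defaults are the study conditions used
throughout the tests and the acceptance script:

- 2000 catalog sites on two toy chromosomes, 5 RBPs, 100 planted
  (RBP, site) effects of |Δ| = 0.4;
- per-site background editing levels ~ Beta(1.5, 6) — right-skewed low
  levels, as observed for A-to-I catalogs;
- depths ~ DiscreteUniform(11, 100) per site per assay (every simulated
  site can pass the depth filter), with planted sites forced to depth
  ≥ 50 in both assays;
- edited counts ~ Binomial(depth, level), with the eCLIP success
  probability shifted by the planted Δ at planted sites. The binomial
  model matches the Fisher test's sampling assumption, which makes the
  calibration checks interpretable; a beta-binomial option
  (`overdispersion`) exists for robustness experiments. Planted deltas of
  +0.4 draw their background level from (0.1, 0.5) and −0.4 from
  (0.5, 0.9), so the shifted level stays inside [0, 1] without clipping;
- peaks of ±100 bp around each RBP's planted sites plus a 30% random
  cover of null sites; a tiling gene model with exon/intron blocks and
  3′UTR-bearing CDS transcripts; SE-type rMATS tables whose significant
  blocks cover a configurable 30% of sites; and designed 3′UTR hairpins
  whose stem contains one adenosine, with PARS-like scores positive over
  the stem and negative over the loop.

What the generator does *not* emulate: overdispersed replicate structure,
Alu clustering and the strong positional autocorrelation of real editing,
alignment artifacts (the mini-alignment emitter exists only to exercise
the counting filters), peak-calling noise, and genuinely shared sites
between RBPs beyond the random peak cover. Passing the planted-recovery
and calibration checks therefore demonstrates the statistics are correct
and calibrated under their stated sampling model — not that real eCLIP
noise is fully captured.

Problem sizes in the test suite (a few hundred to 2000 sites, 3–5 RBPs,
exhaustive sweeps bounded at row sums 30 / n = 12 / 14-mers) were chosen
so every property is checked at full strength while the whole suite runs
in about a minute.

## Determinism

Every stochastic stage takes an explicit seed, restores the caller's RNG
state, and the pipeline manifest records thresholds and input checksums
(no timestamps), so a rerun of `run_pipeline()` with the same inputs,
thresholds and seed is byte-identical — asserted file-by-file in the
tests.

## Limitations

- The binomial sampling model ignores biological overdispersion; with real
  replicate variability the per-site p-values are anti-conservative.
  Pooling replicates (the default) partially mitigates but does not remove
  this.
- Known-site restriction: the tool quantifies catalogued sites only; it
  performs no de novo editing discovery and no genotype-aware SNP
  filtering beyond the supplied exclusion list.
- eCLIP crosslinking-induced deletions/truncations near the binding site
  can distort base calls at editing sites inside peaks; the 5′ trim and
  base-quality filters reduce but cannot eliminate this.
- The network comparison tests exchangeability of the two weight
  assignments, not any generative model of network formation; its p-value
  should be read as evidence that the two similarity structures differ,
  nothing more.
- The reference folding engine is a pair-count surrogate intended for
  testing and for fast screening; energy-level conclusions need the
  thermodynamic backend.
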