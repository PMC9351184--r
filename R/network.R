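## RBP-RBP networks: edges weighted by shared associated editing sites or
## by overlapping binding-peak length, plus a seeded permutation comparison
## of two networks (global strength and maximum edge difference).

#' Construct an RBP network
#'
#' @param edges Data.frame with columns `rbp_a`, `rbp_b`, `weight`.
#'   Self-loops are dropped, pairs are stored unordered (`rbp_a < rbp_b`),
#'   and zero-weight edges are omitted.
#' @param nodes Character vector of node names (isolated nodes are kept so
#'   node sets stay comparable across networks).
#' @param weight_kind `"shared_sites"` or `"overlap_bp"`.
#' @return List of class `rbp_network` with `nodes`, `edges`,
#'   `weight_kind`.
#' @export
rbp_network <- function(edges, nodes, weight_kind = c("shared_sites",
                                                      "overlap_bp")) {
  weight_kind <- match.arg(weight_kind)
  if (!nrow(edges)) {
    edges <- data.frame(rbp_a = character(), rbp_b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    a <- pmin(edges$rbp_a, edges$rbp_b)
    b <- pmax(edges$rbp_a, edges$rbp_b)
    edges <- data.frame(rbp_a = a, rbp_b = b, weight = edges$weight,
                        stringsAsFactors = FALSE)
    edges <- edges[edges$rbp_a != edges$rbp_b & edges$weight > 0, ,
                   drop = FALSE]
    key <- paste(edges$rbp_a, edges$rbp_b)
    if (anyDuplicated(key)) {
      agg <- rowsum(edges$weight, key)
      parts <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
      edges <- data.frame(rbp_a = parts[, 1], rbp_b = parts[, 2],
                          weight = as.numeric(agg), stringsAsFactors = FALSE)
    }
    edges <- edges[order(edges$rbp_a, edges$rbp_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = sort(unique(c(nodes, edges$rbp_a, edges$rbp_b))),
                 edges = edges, weight_kind = weight_kind),
            class = "rbp_network")
}

#' @export
print.rbp_network <- function(x, ...) {
  cat(sprintf("RBP network (%s): %d node(s), %d edge(s)\n",
              x$weight_kind, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Network of RBPs sharing associated editing sites
#'
#' Edge weight between two RBPs is the number of editing sites associated
#' with both (favored and disfavored sites pooled: a site counts as
#' RBP-associated either way).
#'
#' @param assoc Named list, RBP name -> character vector of site keys
#'   (`chrom:pos:strand`), or a `site_preference_calls`-style data.frame
#'   with columns `rbp`, `chrom`, `pos`, `strand`, `call` (non-ns rows are
#'   used).
#' @return An `rbp_network` with `weight_kind = "shared_sites"`.
#' @export
build_editing_network <- function(assoc) {
  if (is.data.frame(assoc)) {
    sig <- assoc[assoc$call != "ns", , drop = FALSE]
    assoc <- split(site_key(sig$chrom, sig$pos, sig$strand), sig$rbp)
  }
  assoc <- lapply(assoc, unique)
  rbps <- sort(names(assoc))
  edges <- list()
  if (length(rbps) >= 2) {
    cmb <- utils::combn(rbps, 2)
    w <- apply(cmb, 2, function(pr)
      length(intersect(assoc[[pr[1]]], assoc[[pr[2]]])))
    edges <- data.frame(rbp_a = cmb[1, ], rbp_b = cmb[2, ], weight = w,
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(rbp_a = character(), rbp_b = character(),
                        weight = numeric())
  }
  rbp_network(edges, nodes = rbps, weight_kind = "shared_sites")
}

#' Network of RBPs with overlapping binding peaks
#'
#' Edge weight is the number of bases shared between two RBPs' binding
#' regions. Each RBP's peaks are merged first so self-overlapping peaks are
#' counted once.
#'
#' @param peaks Named list, RBP name -> `peak_set` (or any data.frame with
#'   `chrom`, `start`, `end` 0-based half-open).
#' @return An `rbp_network` with `weight_kind = "overlap_bp"`.
#' @export
build_peak_network <- function(peaks) {
  grl <- lapply(peaks, function(pk) {
    if (!nrow(pk)) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(GenomicRanges::GRanges(
      pk$chrom, IRanges::IRanges(start = pk$start + 1L, end = pk$end)))
  })
  rbps <- sort(names(peaks))
  if (length(rbps) >= 2) {
    cmb <- utils::combn(rbps, 2)
    w <- apply(cmb, 2, function(pr) {
      # disjoint chromosome sets are an ordinary zero-overlap case
      ov <- suppressWarnings(
        GenomicRanges::intersect(grl[[pr[1]]], grl[[pr[2]]]))
      sum(BiocGenerics::width(ov))
    })
    edges <- data.frame(rbp_a = cmb[1, ], rbp_b = cmb[2, ], weight = w,
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(rbp_a = character(), rbp_b = character(),
                        weight = numeric())
  }
  rbp_network(edges, nodes = rbps, weight_kind = "overlap_bp")
}

#' Permutation comparison of two RBP networks
#'
#' Tests whether two weighted networks over the same RBPs differ, in the
#' spirit of the network comparison test: after normalizing each network's
#' weights by its maximum (so shared-site counts and overlap lengths are
#' comparable), the observed statistics are the global-strength difference
#' `s = |sum(w1) - sum(w2)|` and the invariance statistic
#' `m = max |w1 - w2|` over the union edge set (a missing edge counts as
#' weight 0). The null swaps the two weights of each union edge
#' independently with probability 1/2 per permutation, preserving each
#' edge's weight pair while testing exchangeability of the two weight
#' assignments; p-values use the (1 + k) / (1 + n_perm) estimator, so the
#' smallest attainable p at 2000 permutations is 1/2001 (< 0.0005).
#'
#' @param n1,n2 `rbp_network` objects.
#' @param n_perm Number of permutations (default 2000).
#' @param seed Integer seed (mandatory; results are reproducible).
#' @return List of class `network_comparison`: `s_obs`, `m_obs`,
#'   `p_strength`, `p_invariance`, `n_perm`, `seed`, `n_edges`.
#' @export
compare_networks <- function(n1, n2, n_perm = 2000L, seed) {
  if (missing(seed)) stopf("compare_networks requires an explicit seed")
  if (!nrow(n1$edges) && !nrow(n2$edges))
    stopf("cannot compare two empty networks")
  norm_w <- function(net) {
    e <- net$edges
    w <- e$weight
    if (length(w) && max(w) > 0) w <- w / max(w)
    structure(w, names = paste(e$rbp_a, e$rbp_b, sep = "\r"))
  }
  w1 <- norm_w(n1); w2 <- norm_w(n2)
  union_edges <- sort(unique(c(names(w1), names(w2))))
  v1 <- ifelse(union_edges %in% names(w1), w1[union_edges], 0)
  v2 <- ifelse(union_edges %in% names(w2), w2[union_edges], 0)
  v1[is.na(v1)] <- 0; v2[is.na(v2)] <- 0
  s_obs <- abs(sum(v1) - sum(v2))
  m_obs <- max(abs(v1 - v2))
  ne <- length(union_edges)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  k_s <- 0L; k_m <- 0L
  for (b in seq_len(n_perm)) {
    swap <- stats::runif(ne) < 0.5
    p1 <- ifelse(swap, v2, v1)
    p2 <- ifelse(swap, v1, v2)
    if (abs(sum(p1) - sum(p2)) >= s_obs) k_s <- k_s + 1L
    if (max(abs(p1 - p2)) >= m_obs) k_m <- k_m + 1L
  }
  structure(list(s_obs = s_obs, m_obs = m_obs,
                 p_strength = (1 + k_s) / (1 + n_perm),
                 p_invariance = (1 + k_m) / (1 + n_perm),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 n_edges = ne),
            class = "network_comparison")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("network comparison (%d union edges, %d permutations, seed %d)\n",
              x$n_edges, x$n_perm, x$seed))
  cat(sprintf("  global strength: s = %.4f, p = %.4g\n", x$s_obs,
              x$p_strength))
  cat(sprintf("  invariance:      m = %.4f, p = %.4g\n", x$m_obs,
              x$p_invariance))
  invisible(x)
}

#' Read / write network edge lists
#'
#' Tab-separated edge list with columns `rbp_a`, `rbp_b`, `weight`.
#' @param path File path.
#' @param nodes,weight_kind Passed to [rbp_network()] on read.
#' @export
read_edge_list <- function(path, nodes = character(),
                           weight_kind = "shared_sites") {
  df <- read_tsv(path)
  rbp_network(df, nodes = nodes, weight_kind = weight_kind)
}

#' @rdname read_edge_list
#' @param net An `rbp_network`.
#' @export
write_edge_list <- function(net, path) {
  write_tsv(net$edges, path)
}

#' Export a network as GraphML (requires igraph)
#' @param net An `rbp_network`.
#' @param path Output `.graphml` path.
#' @export
write_graphml <- function(net, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stopf("GraphML export requires the igraph package")
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
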