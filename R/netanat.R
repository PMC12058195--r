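# Anatomy of selected edge sets: signed networks, overlap statistics,
# and network-pair enrichment.

NETWORK_LABELS <- c("VIS", "SOM", "DAN", "VAN", "LIM", "FPN", "DMN", "SUB")

#' ROI-to-network assignment
#'
#' Maps each ROI to one of the eight canonical functional networks
#' (visual, somatomotor, dorsal attention, ventral attention, limbic,
#' frontoparietal control, default mode, subcortical). The default
#' loads the synthetic 122-ROI assignment shipped with the package
#' (`inst/extdata/roi_network_synthetic_122.tsv`), a stand-in with
#' realistic network sizes for use with simulated data.
#'
#' @param x Either a path to a two-column TSV (`roi_index`, `label`),
#'   a data frame with those columns, or `NULL` for the shipped
#'   synthetic 122-ROI table.
#' @param n_roi Expected number of ROIs (checked when given).
#' @return A `network_assignment` tibble `roi`, `label` (factor over
#'   the 8 canonical labels).
#' @export
network_assignment <- function(x = NULL, n_roi = NULL) {
  if (is.null(x)) {
    x <- system.file("extdata", "roi_network_synthetic_122.tsv",
      package = "dyncpm", mustWork = TRUE)
  }
  df <- if (is.character(x)) {
    readr::read_tsv(x, col_types = readr::cols(
      roi_index = readr::col_integer(), label = readr::col_character()))
  } else {
    as_tibble(x)
  }
  if (!all(c("roi_index", "label") %in% names(df))) {
    abort("network_assignment(): need columns `roi_index`, `label`.")
  }
  bad <- setdiff(unique(df$label), NETWORK_LABELS)
  if (length(bad)) {
    abort(sprintf("network_assignment(): unknown network label(s): %s",
      paste(bad, collapse = ", ")))
  }
  df <- dplyr::arrange(df, .data$roi_index)
  if (!identical(df$roi_index, seq_len(nrow(df)))) {
    abort("network_assignment(): roi_index must be 1..n_roi with no gaps.")
  }
  if (!is.null(n_roi) && nrow(df) != n_roi) {
    abort(sprintf("network_assignment(): expected %d ROIs, got %d.",
      n_roi, nrow(df)))
  }
  out <- tibble(roi = df$roi_index,
    label = factor(df$label, levels = NETWORK_LABELS))
  class(out) <- c("network_assignment", class(out))
  out
}

#' Signed edge set (high / low network)
#'
#' Holds the positively and negatively target-correlated edges of a
#' selected network, under the canonical edge index of `n_roi` ROIs.
#'
#' @param positive,negative Integer edge ids (disjoint).
#' @param n_roi Parcellation size the ids refer to.
#' @param source Free-text provenance tag.
#' @return A `signed_edge_set` list.
#' @export
signed_edge_set <- function(positive, negative, n_roi, source = "") {
  positive <- sort(unique(as.integer(positive)))
  negative <- sort(unique(as.integer(negative)))
  m <- n_edges(n_roi)
  if (length(intersect(positive, negative))) {
    abort("signed_edge_set(): positive and negative sets overlap.")
  }
  ids <- c(positive, negative)
  if (length(ids) && (min(ids) < 1L || max(ids) > m)) {
    abort("signed_edge_set(): edge id outside the edge index.")
  }
  structure(
    list(positive = positive, negative = negative,
      n_roi = as.integer(n_roi), edge_hash = edge_index_hash(n_roi),
      source = source),
    class = "signed_edge_set"
  )
}

#' Sign-wise intersection of two signed edge sets
#'
#' The overlap network: edges positive in both inputs form the
#' positive (high) set, edges negative in both the negative (low) set.
#'
#' @param a,b `signed_edge_set`s on the same edge index.
#' @return A `signed_edge_set`.
#' @export
intersect_networks <- function(a, b) {
  stopifnot(inherits(a, "signed_edge_set"), inherits(b, "signed_edge_set"))
  if (!identical(a$edge_hash, b$edge_hash)) {
    abort("intersect_networks(): edge-index mismatch.")
  }
  signed_edge_set(intersect(a$positive, b$positive),
    intersect(a$negative, b$negative), a$n_roi,
    source = paste(a$source, "&", b$source))
}

#' Hypergeometric test of edge-set overlap
#'
#' Probability of the observed overlap between two edge sets of sizes
#' `K` and `n` drawn from `M` edges. The default is the literal
#' survival form `P(X > x) = 1 - F(x)`; `inclusive = TRUE` gives the
#' conventional `P(X >= x)`. The two differ by one probability mass
#' point, negligible at whole-connectome scales but visible on toy
#' instances.
#'
#' @param x Observed overlap count.
#' @param M Total number of edges in the index.
#' @param K,n Sizes of the two edge sets.
#' @param inclusive Use `P(X >= x)` instead of `P(X > x)`.
#' @return Right-tail p-value.
#' @examples
#' hypergeometric_overlap_test(169, 7381, 439, 848) # far below .001
#' @export
hypergeometric_overlap_test <- function(x, M, K, n, inclusive = FALSE) {
  for (v in list(x = x, M = M, K = K, n = n)) {
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != floor(v)) {
      abort("hypergeometric_overlap_test(): counts must be non-negative integers.")
    }
  }
  if (x > min(K, n) || K > M || n > M) {
    abort("hypergeometric_overlap_test(): inconsistent counts (need x <= min(K, n) <= M).")
  }
  q <- if (inclusive) x - 1 else x
  phyper(q, K, M - K, n, lower.tail = FALSE)
}

#' Jaccard similarity of two edge sets with a shuffle null
#'
#' `J = |a intersect b| / |a union b|`, compared against a null in
#' which the edge positions of both sets are re-drawn uniformly from
#' the `M` edges with their sizes fixed (set `shuffle = "b"` to
#' re-draw only the second set).
#'
#' @param a,b Integer edge-id vectors (subsets of `1:M`, not both
#'   empty).
#' @param M Total number of edges.
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @param shuffle `"both"` or `"b"`.
#' @return A list: `jaccard`, `p` (one-tailed greater), `nulls`.
#' @export
jaccard_overlap_test <- function(a, b, M, n_perm = 10000, seed = 1L,
                                 shuffle = c("both", "b")) {
  shuffle <- match.arg(shuffle)
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  if (length(a) == 0L && length(b) == 0L) {
    abort("jaccard_overlap_test(): both sets empty; J undefined.")
  }
  ids <- c(a, b)
  if (length(ids) && (min(ids) < 1L || max(ids) > M)) {
    abort("jaccard_overlap_test(): edge id outside 1..M.")
  }
  jac <- function(u, v) length(intersect(u, v)) / length(union(u, v))
  j_obs <- jac(a, b)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 0L, salt = 13L))
  nulls <- vapply(seq_len(n_perm), function(i) {
    aa <- if (shuffle == "both") sample.int(M, length(a)) else a
    bb <- sample.int(M, length(b))
    jac(aa, bb)
  }, numeric(1))
  list(jaccard = j_obs, p = permutation_pvalue(j_obs, nulls, "greater"),
    nulls = nulls)
}

#' Number of possible edges between (or within) two networks
#'
#' @param assignment A [network_assignment()].
#' @param netA,netB Network labels.
#' @return `|A| * |B|` for distinct networks, `|A| * (|A| - 1) / 2`
#'   within a network.
#' @export
pair_possible_edges <- function(assignment, netA, netB) {
  if (!netA %in% NETWORK_LABELS || !netB %in% NETWORK_LABELS) {
    abort("pair_possible_edges(): unknown network label.")
  }
  sizes <- table(assignment$label)
  na <- as.integer(sizes[[netA]])
  nb <- as.integer(sizes[[netB]])
  if (netA == netB) na * (na - 1L) %/% 2L else na * nb
}

# per-edge network-pair cell id (1..36) under the canonical edge index
edge_pair_cells <- function(assignment) {
  n_roi <- nrow(assignment)
  ei <- edge_index(n_roi)
  la <- as.integer(assignment$label[ei$i])
  lb <- as.integer(assignment$label[ei$j])
  lo <- pmin(la, lb)
  hi <- pmax(la, lb)
  # unordered pair (lo, hi) among 8 labels -> cell 1..36
  cell <- (lo - 1L) * 8L - (lo * (lo - 1L)) %/% 2L + (hi - lo) + lo
  list(cell = cell, ei = ei)
}

# the 36 unordered label pairs in cell order
pair_cell_table <- function() {
  out <- list()
  k <- 0L
  for (a in 1:8) {
    for (b in a:8) {
      k <- k + 1L
      out[[k]] <- tibble(cell = k, netA = NETWORK_LABELS[a],
        netB = NETWORK_LABELS[b])
    }
  }
  dplyr::bind_rows(out)
}

#' Network-pair enrichment of a selected edge set
#'
#' For each of the 36 network pairs (8 within + 28 between), the
#' proportion of selected edges among all possible edges of that
#' pair, compared against a null in which the same number of edges is
#' re-placed uniformly in the connectome (`n_perm` draws); one-tailed
#' greater permutation p-values, BH-FDR corrected across the 36 pairs.
#' Run once per sign of a [signed_edge_set()].
#'
#' @param edges Integer edge ids of one sign.
#' @param assignment A [network_assignment()] covering the
#'   parcellation the ids refer to.
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @param q FDR level (default 0.05).
#' @return A `cpm_enrichment` tibble: `netA`, `netB`, `possible`,
#'   `selected`, `proportion`, `p`, `p_adj`, `significant`.
#' @export
networkpair_enrichment <- function(edges, assignment, n_perm = 10000,
                                   seed = 1L, q = 0.05) {
  edges <- unique(as.integer(edges))
  pc <- edge_pair_cells(assignment)
  m <- length(pc$cell)
  if (length(edges) && (min(edges) < 1L || max(edges) > m)) {
    abort("networkpair_enrichment(): edge id outside the edge index.")
  }
  possible <- tabulate(pc$cell, nbins = 36L)
  counts <- tabulate(pc$cell[edges], nbins = 36L)
  prop <- ifelse(possible > 0L, counts / possible, 0)
  tab <- pair_cell_table()
  if (length(edges) == 0L) {
    out <- dplyr::mutate(tab, possible = possible, selected = 0L,
      proportion = 0, p = 1, p_adj = 1, significant = FALSE)
    out$cell <- NULL
    class(out) <- c("cpm_enrichment", class(out))
    return(out)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 0L, salt = 14L))
  exceed <- integer(36L)
  for (i in seq_len(n_perm)) {
    null_counts <- tabulate(pc$cell[sample.int(m, length(edges))],
      nbins = 36L)
    null_prop <- ifelse(possible > 0L, null_counts / possible, 0)
    exceed <- exceed + (null_prop >= prop)
  }
  p <- (1 + exceed) / (1 + n_perm)
  fdr <- bh_fdr(p, q = q)
  out <- dplyr::mutate(tab, possible = possible,
    selected = counts, proportion = prop, p = p, p_adj = fdr$p_adj,
    significant = fdr$reject)
  out$cell <- NULL
  class(out) <- c("cpm_enrichment", class(out))
  out
}

#' Percentage of a network shared with another
#'
#' @param shared Overlap count.
#' @param total Size of the reference set (> 0).
#' @return Percentage, rounded to two decimals.
#' @examples
#' overlap_fraction(361, 593) # 60.88
#' @export
overlap_fraction <- function(shared, total) {
  assert_count(shared, "shared", min = 0L)
  assert_count(total, "total", min = 1L)
  if (shared > total) abort("overlap_fraction(): shared exceeds total.")
  round(100 * shared / total, 2)
}
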