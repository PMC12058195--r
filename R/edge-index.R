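#' Canonical edge index for an ROI parcellation
#'
#' Every module in the package refers to functional connections
#' (edges) through this shared index: the upper triangle of the
#' ROI-by-ROI matrix enumerated row-major, i.e. (1,2), (1,3), ...,
#' (1,n), (2,3), ... With 122 ROIs this yields the familiar 7381
#' edges of the whole-brain connectome.
#'
#' @param n_roi Number of ROIs (>= 2).
#' @return A tibble with columns `edge` (1-based edge id), `i`, `j`
#'   (ROI indices, `i < j`), carrying `n_roi` as an attribute.
#' @examples
#' edge_index(3)
#' nrow(edge_index(122)) # 7381
#' @export
edge_index <- function(n_roi) {
  assert_count(n_roi, "n_roi", min = 2L)
  n_roi <- as.integer(n_roi)
  i <- rep.int(seq_len(n_roi - 1L), times = (n_roi - 1L):1L)
  j <- sequence((n_roi - 1L):1L) + i
  out <- tibble(edge = seq_along(i), i = i, j = j)
  attr(out, "n_roi") <- n_roi
  class(out) <- c("edge_index", class(out))
  out
}

#' Number of edges for a parcellation
#' @param n_roi Number of ROIs.
#' @return `n_roi * (n_roi - 1) / 2`.
#' @export
n_edges <- function(n_roi) {
  assert_count(n_roi, "n_roi", min = 2L)
  as.integer(n_roi * (n_roi - 1) / 2)
}

# map (i, j) pairs to edge ids under the canonical row-major ordering
edge_id <- function(i, j, n_roi) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  if (any(lo < 1L | hi > n_roi | lo == hi)) {
    abort("edge_id(): ROI pair outside the parcellation or self-pair.")
  }
  as.integer((lo - 1L) * n_roi - lo * (lo - 1L) / 2 + (hi - lo))
}

# short fingerprint so sets/masks from different parcellations cannot mix
edge_index_hash <- function(n_roi) sprintf("edges-%d-%d", n_roi, n_edges(n_roi))
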