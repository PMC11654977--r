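#' Canonical edge index of a p-node undirected graph
#'
#' Enumerates all q = p(p-1)/2 unordered node pairs (i, j) with i < j in
#' lexicographic order. This is the row order used by every edge-indexed
#' vector and frequency table in the package, and coincides with
#' \code{lower.tri} column-major order, so \code{A[lower.tri(A)]} extracts a
#' symmetric matrix in canonical edge order.
#'
#' @param p number of nodes (taxa); must be >= 2.
#' @return integer matrix with q rows and columns \code{i}, \code{j}.
#' @examples
#' edge_index(4)
#' @export
edge_index <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1, p >= 2)
  p <- as.integer(p)
  j <- unlist(lapply(seq_len(p - 1), function(i) seq.int(i + 1L, p)))
  i <- rep.int(seq_len(p - 1), times = (p - 1):1)
  cbind(i = i, j = j)
}

#' Number of candidate edges for p nodes
#' @param p number of nodes.
#' @return integer p(p-1)/2.
#' @export
n_edges <- function(p) as.integer(p * (p - 1) / 2)

# Position of pair (i, j), i < j, in the canonical edge order (vectorized).
edge_id <- function(i, j, p) {
  swap <- i > j
  if (any(swap)) { tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp }
  as.integer((i - 1) * p - i * (i - 1) / 2 + (j - i))
}

# Symmetric hollow binary adjacency from an edge-id subset.
edges_to_adjacency <- function(ids, p, taxon_ids = NULL) {
  A <- matrix(0L, p, p)
  if (length(ids)) {
    ei <- edge_index(p)[ids, , drop = FALSE]
    A[ei] <- 1L
    A[ei[, c(2, 1), drop = FALSE]] <- 1L
  }
  if (!is.null(taxon_ids)) dimnames(A) <- list(taxon_ids, taxon_ids)
  A
}

# Edge ids present in a symmetric binary adjacency.
adjacency_to_edges <- function(A) {
  stopifnot(nrow(A) == ncol(A))
  which(A[lower.tri(A)] != 0)
}

validate_adjacency <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE)))
    stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal")
  if (!all(A %in% c(0, 1))) stop("adjacency entries must be 0/1")
  invisible(A)
}
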