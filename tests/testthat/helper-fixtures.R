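# Shared fixtures and independent oracles used across test files.

# Small count matrix with ids.
toy_counts <- function(n = 6, p = 4, seed = 42, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n * p, lambda), n, p)
  dimnames(m) <- list(sprintf("s%02d", seq_len(n)), sprintf("t%02d", seq_len(p)))
  m
}

# Frequency table built from random monotone per-resample paths, so entries
# sit on the {0, 1/B, ..., 1} lattice and columns densify along the grid.
toy_freq_table <- function(p = 8, K = 6, B = 10, seed = 1, tag = "toy",
                           never_frac = 0.3) {
  set.seed(seed)
  q <- consenet::n_edges(p)
  f <- matrix(0, q, K)
  extra <- max(1L, round(K * never_frac / (1 - never_frac)))
  for (b in seq_len(B)) {
    entry <- sample.int(K + extra, q, replace = TRUE)   # > K = never selected
    f <- f + outer(entry, seq_len(K), "<=")
  }
  grid <- exp(seq(log(1), log(0.01), length.out = K))
  attr(grid, "scale") <- "penalty"
  structure(list(f = f / B, grid = grid, B = B, method_tag = tag, p = p,
                 taxon_ids = sprintf("t%02d", seq_len(p))),
            class = "frequency_table")
}

toy_run <- function(...) consenet::method_run(toy_freq_table(...))

# ---- spanning-tree enumeration oracle (independent of the package's
# matrix-tree implementation) -------------------------------------------------

# connectivity of an edge subset via union-find
uf_connected <- function(ids, ei, p) {
  parent <- seq_len(p)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  for (e in ids) {
    ra <- find(ei[e, 1]); rb <- find(ei[e, 2])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(p), find, integer(1)))) == 1
}

# all spanning trees of K_p as edge-id sets
spanning_trees_of_complete <- function(p) {
  ei <- consenet::edge_index(p)
  q <- nrow(ei)
  combs <- utils::combn(q, p - 1)
  keep <- apply(combs, 2, function(ids) uf_connected(ids, ei, p))
  combs[, keep, drop = FALSE]
}

# brute-force edge probabilities under the weighted spanning-tree measure
tree_prob_oracle <- function(W, trees = NULL) {
  p <- nrow(W)
  ei <- consenet::edge_index(p)
  if (is.null(trees)) trees <- spanning_trees_of_complete(p)
  probs <- numeric(nrow(ei)); Z <- 0
  for (cidx in seq_len(ncol(trees))) {
    ids <- trees[, cidx]
    w <- prod(W[ei[ids, , drop = FALSE]])
    if (w == 0) next
    Z <- Z + w
    probs[ids] <- probs[ids] + w
  }
  if (Z == 0) stop("no spanning tree with positive weight")
  probs / Z
}

# symmetric adjacency from canonical edge ids (test-local mirror of the
# package's internal helper, kept separate so evaluation tests do not lean on
# the code under test)
edges_to_adjacency_test <- function(ids, p) {
  ei <- consenet::edge_index(p)
  A <- matrix(0L, p, p)
  for (e in ids) { A[ei[e, 1], ei[e, 2]] <- 1L; A[ei[e, 2], ei[e, 1]] <- 1L }
  A
}
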