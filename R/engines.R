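#' Largest useful penalty for a gaussianized matrix
#'
#' Returns the maximum absolute off-diagonal entry of the empirical
#' correlation matrix. Both the graphical lasso and node-wise lasso paths are
#' empty for penalties at or above this value, so it anchors the top of the
#' penalty grid.
#'
#' @param x numeric matrix, samples x taxa (gaussianized data).
#' @return a positive scalar.
#' @export
lambda_max <- function(x) {
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop(sprintf("zero-variance column '%s'; filter or transform upstream",
                 colnames(x)[which(sds == 0)[1]] %||% which(sds == 0)[1]))
  r <- cor(x)
  max(abs(r[lower.tri(r)]))
}

#' Regularization grid for an engine family
#'
#' For penalized engines (\code{glasso}, \code{mb}): K log-spaced penalties
#' decreasing from \code{lambda_max(x)} down to \code{ratio * lambda_max(x)}.
#' For the tree-averaging engine: K linear probability thresholds decreasing
#' over (0.02, 0.98). Grids are strictly decreasing, so walking the grid
#' always densifies the graph.
#'
#' @param x gaussianized matrix (used only on the penalty scale).
#' @param K grid length (default 30).
#' @param scale \code{"penalty"} or \code{"probability_threshold"}.
#' @param ratio smallest/largest penalty ratio (default 0.01).
#' @return numeric vector of length K, strictly decreasing, with
#'   \code{attr(, "scale")} set.
#' @export
lambda_grid <- function(x = NULL, K = 30,
                        scale = c("penalty", "probability_threshold"),
                        ratio = 0.01) {
  scale <- match.arg(scale)
  stopifnot(K >= 2)
  g <- if (scale == "penalty") {
    lmax <- lambda_max(x)
    exp(seq(log(lmax), log(ratio * lmax), length.out = K))
  } else {
    seq(0.98, 0.02, length.out = K)
  }
  attr(g, "scale") <- scale
  g
}

# Correlation matrix with zero-variance columns rendered inert (correlation 0
# to everything) rather than NA; used inside per-subsample fits where a rare
# taxon may vanish from the resample.
safe_cor <- function(x) {
  sds <- apply(x, 2, sd)
  r <- suppressWarnings(cor(x))
  if (any(sds == 0)) { r[sds == 0, ] <- 0; r[, sds == 0] <- 0; diag(r) <- 1 }
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r
}

# Cumulative-union monotone envelope: once an edge enters the path it stays,
# so density is non-decreasing as the grid is descended.
envelope_path <- function(path) {
  if (ncol(path) > 1)
    path <- t(apply(path, 1, cummax))
  storage.mode(path) <- "integer"
  path
}

#' Graphical lasso support path
#'
#' Runs an l1-penalized Gaussian precision estimate (penalty on off-diagonal
#' entries only) on the empirical correlation matrix at every grid penalty,
#' with warm starts down the path, and reports the edge support. Entries of
#' the estimated precision with magnitude <= 1e-8 count as zero. Raw paths
#' are made monotone by cumulative union along decreasing penalties.
#'
#' @param x gaussianized matrix, samples x taxa.
#' @param grid strictly decreasing penalty vector (see \code{lambda_grid}).
#' @param ridge_retry ridge jitter added to the correlation diagonal when the
#'   solver fails to converge at some penalty (retried once, with a message).
#' @param tol convergence tolerance on the working covariance (relative to
#'   the mean absolute off-diagonal of the input correlation).
#' @param inner_tol coordinate-descent tolerance of the lasso subproblems.
#' @return binary integer matrix, q edges x K grid points, in canonical edge
#'   order.
#' @export
glasso_path <- function(x, grid, ridge_retry = 1e-3, tol = 1e-4, inner_tol = 1e-4) {
  S <- safe_cor(x)
  res <- .glasso_path_cpp(S, as.numeric(grid), tol = tol, inner_tol = inner_tol)
  if (!all(res$converged)) {
    bad <- which(!res$converged)
    message(sprintf("glasso: %d grid point(s) not converged; retrying with ridge %.1e",
                    length(bad), ridge_retry))
    res2 <- .glasso_path_cpp(S + diag(ridge_retry, nrow(S)),
                             as.numeric(grid)[bad],
                             tol = tol, inner_tol = inner_tol)
    res$support[, bad] <- res2$support
    if (!all(res2$converged))
      warning(sprintf("glasso: %d grid point(s) flagged non-converged after retry",
                      sum(!res2$converged)))
  }
  envelope_path(res$support)
}

#' Neighborhood-selection (Meinshausen-Buhlmann) support path
#'
#' Per node, a lasso regression of that taxon on all others (in covariance
#' form on the empirical correlation matrix) at every grid penalty; an edge
#' is present under the OR rule when either endpoint selects it, under AND
#' when both do. Paths are warm-started and envelope-corrected as in
#' \code{glasso_path}.
#'
#' @inheritParams glasso_path
#' @param symmetrize \code{"OR"} (default) or \code{"AND"}.
#' @return binary integer matrix, q x K.
#' @export
mb_path <- function(x, grid, symmetrize = c("OR", "AND"), inner_tol = 1e-4) {
  symmetrize <- match.arg(symmetrize)
  S <- safe_cor(x)
  votes <- .mb_path_cpp(S, as.numeric(grid), inner_tol = inner_tol)
  path <- if (symmetrize == "OR") (votes > 0L) else (votes == 2L)
  storage.mode(path) <- "integer"
  envelope_path(path)
}

#' Spanning-tree edge probabilities from a weight matrix
#'
#' Given symmetric non-negative edge weights, computes for every edge the
#' probability that it belongs to a random spanning tree drawn with
#' probability proportional to the product of its edge weights, via the
#' weighted matrix-tree theorem: P(e = (i,j)) equals w_ij times the effective
#' resistance between i and j in the weighted Laplacian. Probabilities sum
#' to p - 1.
#'
#' @param W symmetric p x p non-negative weight matrix (diagonal ignored).
#' @return numeric edge vector (canonical order) of probabilities in [0, 1].
#' @export
tree_edge_prob_from_weights <- function(W) {
  p <- nrow(W)
  stopifnot(p >= 2, isTRUE(all.equal(W, t(W), check.attributes = FALSE)))
  diag(W) <- 0
  if (any(W < 0)) stop("weights must be non-negative")
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected"))
  if (comp$no > 1) stop("weight graph is disconnected; spanning trees undefined")
  L <- diag(rowSums(W)) - W
  M <- solve(L + 1 / p)                 # (L + J/p)^{-1}; J/p removes the null space
  ei <- edge_index(p)
  i <- ei[, 1]; j <- ei[, 2]
  reff <- M[cbind(i, i)] + M[cbind(j, j)] - 2 * M[cbind(i, j)]
  pr <- W[ei] * reff
  pmin(pmax(pr, 0), 1)
}

#' Tree-averaging edge probabilities from data
#'
#' Edge weights are the Gaussian mutual information of each taxon pair,
#' \eqn{w_{ij} = -\frac{1}{2}\log(1 - r_{ij}^2)} from the empirical
#' correlations, and edge scores are spanning-tree membership probabilities
#' under those weights (see \code{\link{tree_edge_prob_from_weights}}).
#' Perfect correlations are clamped to keep weights finite.
#'
#' @param x gaussianized matrix, samples x taxa.
#' @return numeric edge vector of probabilities; \code{sum} equals p - 1.
#' @export
tree_edge_probabilities <- function(x) {
  r <- safe_cor(x)
  r2 <- r^2
  if (any(r2[lower.tri(r2)] >= 1 - 1e-12)) {
    warning("perfect correlation clamped for tree weights")
    r2 <- pmin(r2, 1 - 1e-12)
  }
  W <- -0.5 * log(1 - r2)
  diag(W) <- 0
  tree_edge_prob_from_weights(W)
}

#' Threshold tree-averaging probabilities along a grid
#'
#' @param probabilities edge-probability vector (canonical order).
#' @param grid strictly decreasing probability thresholds in (0, 1).
#' @return binary integer matrix, q x K; edge present at grid point t iff its
#'   probability is strictly greater than t.
#' @export
treeavg_path <- function(probabilities, grid) {
  path <- outer(as.numeric(probabilities), as.numeric(grid), ">")
  storage.mode(path) <- "integer"
  path
}

#' Engine specification
#'
#' An engine is a base-inference family paired with a normalization; the
#' default six-member ensemble instantiates the three families (graphical
#' lasso, neighborhood selection, tree averaging) on CLR, CLR+rank and
#' GMPR-log normalized data, emulating the spread of published
#' microbiome-network methods these families summarize.
#'
#' @param family \code{"glasso"}, \code{"mb"} or \code{"tree"}.
#' @param normalization a \code{\link{gaussianize}} method.
#' @param symmetrize MB symmetrization rule.
#' @return an object of class \code{"engine"} with a printable tag.
#' @export
engine <- function(family = c("glasso", "mb", "tree"),
                   normalization = c("clr", "clr_npn", "gmpr", "rle"),
                   symmetrize = c("OR", "AND")) {
  family <- match.arg(family)
  normalization <- match.arg(normalization)
  symmetrize <- match.arg(symmetrize)
  structure(list(family = family, normalization = normalization,
                 symmetrize = symmetrize,
                 tag = paste(family, normalization, sep = "-")),
            class = "engine")
}

#' @export
print.engine <- function(x, ...) {
  cat("<engine>", x$tag, if (x$family == "mb") paste0("(", x$symmetrize, ")"), "\n")
  invisible(x)
}

#' Default engine ensemble
#'
#' @return list of six \code{\link{engine}} objects: glasso-clr, mb-clr,
#'   mb-clr_npn, glasso-gmpr, mb-gmpr, tree-gmpr.
#' @export
default_engines <- function() {
  list(engine("glasso", "clr"), engine("mb", "clr"), engine("mb", "clr_npn"),
       engine("glasso", "gmpr"), engine("mb", "gmpr"), engine("tree", "gmpr"))
}

# Run one engine on (already gaussianized) data over its grid -> q x K binary.
engine_path <- function(eng, x, grid) {
  switch(eng$family,
    glasso = glasso_path(x, grid),
    mb = mb_path(x, grid, symmetrize = eng$symmetrize),
    tree = treeavg_path(tree_edge_probabilities(x), grid),
    stop("unknown engine family: ", eng$family))
}

# Grid appropriate for an engine family.
engine_grid <- function(eng, x, K = 30, ratio = 0.01) {
  if (eng$family == "tree")
    lambda_grid(K = K, scale = "probability_threshold")
  else
    lambda_grid(x, K = K, scale = "penalty", ratio = ratio)
}
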