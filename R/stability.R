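#' Subsample size for stability selection
#'
#' Standard StARS recommendation: 80% of the samples for small datasets,
#' \eqn{\lfloor 10\sqrt{n} \rfloor} beyond n = 144 (the point where the two
#' rules coincide).
#'
#' @param n number of samples; must be >= 10.
#' @return integer subsample size n' < n.
#' @export
subsample_size <- function(n) {
  if (n < 10) stop("too few samples for stability selection (n < 10)")
  if (n <= 144) floor(0.8 * n) else floor(10 * sqrt(n))
}

#' Draw resampling indices shared by all engines
#'
#' B subsamples of size \code{subsample_size(n)} drawn without replacement,
#' reproducible from the seed. The same subsamples feed every engine so that
#' consensus differences reflect methods, not resampling noise.
#'
#' @param n number of samples.
#' @param B number of resamples (>= 2; 40 is a typical choice).
#' @param seed integer seed.
#' @return object of class \code{"subsample_set"}: list of index vectors plus
#'   \code{n}, \code{n_sub}, \code{B}, \code{seed}.
#' @export
make_subsamples <- function(n, B = 40, seed = 1) {
  if (B < 2) stop("B must be >= 2")
  n_sub <- subsample_size(n)
  set.seed(seed)
  idx <- lapply(seq_len(B), function(b) sort(sample.int(n, n_sub)))
  structure(list(indices = idx, n = n, n_sub = n_sub, B = B, seed = seed),
            class = "subsample_set")
}

#' Edge selection frequencies of one engine over the resamples
#'
#' Fits the engine's whole regularization path on every subsample and records,
#' for each candidate edge and grid point, the fraction of subsample graphs
#' containing the edge. An engine failure on one subsample contributes an
#' empty graph (with a message) rather than aborting the table.
#'
#' @param eng an \code{\link{engine}}.
#' @param x gaussianized matrix for this engine (full data; rows are
#'   subsampled from it).
#' @param grid engine grid (strictly decreasing).
#' @param subs a \code{\link{make_subsamples}} result.
#' @return object of class \code{"frequency_table"}: list with \code{f}
#'   (q x K matrix of frequencies on the lattice \{0, 1/B, ..., 1\}),
#'   \code{grid}, \code{B}, \code{method_tag}, \code{p}, \code{taxon_ids}.
#' @export
selection_frequencies <- function(eng, x, grid, subs) {
  p <- ncol(x)
  q <- n_edges(p)
  K <- length(grid)
  acc <- matrix(0L, q, K)
  for (idx in subs$indices) {
    path <- tryCatch(engine_path(eng, x[idx, , drop = FALSE], grid),
                     error = function(e) {
                       message(sprintf("engine %s failed on a subsample (%s); counted as empty",
                                       eng$tag, conditionMessage(e)))
                       matrix(0L, q, K)
                     })
    acc <- acc + path
  }
  structure(list(f = acc / subs$B, grid = grid, B = subs$B,
                 method_tag = eng$tag, p = p, taxon_ids = colnames(x)),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("<frequency_table> %s: %d edges x %d grid points, B = %d\n",
              x$method_tag, nrow(x$f), ncol(x$f), x$B))
  invisible(x)
}

#' Network stability profile along the grid
#'
#' Network-level stability at grid point k is one minus four times the mean
#' edge-level Bernoulli variance of the selection frequencies,
#' \eqn{S_k = 1 - \frac{4}{q}\sum_e f_{ek}(1 - f_{ek})}; S = 1 means every
#' edge decision is perfectly reproducible across resamples. Density is the
#' size of the reproducible-edge set \{e : f_ek > c\}. A monotone envelope
#' (running minimum on S, running maximum on density along decreasing
#' penalties) removes sampling wiggle before selection.
#'
#' @param freqs a \code{\link{selection_frequencies}} table.
#' @param c frequency cutoff defining the reproducible-edge sets
#'   (default 0.9).
#' @return object of class \code{"stability_profile"}: \code{S} and
#'   \code{density} vectors of length K, the raw (pre-envelope) versions,
#'   \code{grid} and \code{c}.
#' @export
stability_profile <- function(freqs, c = 0.9) {
  f <- freqs$f
  S_raw <- 1 - 4 * colMeans(f * (1 - f))
  d_raw <- colSums(f > c)
  structure(list(S = cummin(S_raw), density = as.integer(cummax(d_raw)),
                 S_raw = S_raw, density_raw = as.integer(d_raw),
                 grid = freqs$grid, c = c),
            class = "stability_profile")
}

#' StARS penalty selection from a stability profile
#'
#' Picks the smallest penalty (densest grid point) whose enveloped stability
#' still meets the target. When no grid point does, the largest penalty is
#' returned with attribute \code{fallback = TRUE} and a warning.
#'
#' @param profile a \code{\link{stability_profile}}.
#' @param stab target stability in (0, 1), classically 0.8 or 0.9.
#' @return grid index (integer); largest index with S >= stab.
#' @export
stars_select <- function(profile, stab = 0.9) {
  ok <- which(profile$S >= stab)
  if (!length(ok)) {
    warning("no grid point reaches the stability target; falling back to the largest penalty")
    return(structure(1L, fallback = TRUE))
  }
  max(ok)
}

#' Reproducible-edge set at one grid point
#'
#' Edges whose selection frequency at grid point k is strictly greater than
#' the cutoff c.
#'
#' @param freqs a \code{\link{selection_frequencies}} table.
#' @param k grid index.
#' @param c cutoff in (0, 1).
#' @return integer vector of canonical edge ids, with attributes
#'   \code{lambda} and \code{c}.
#' @export
edge_set <- function(freqs, k, c = 0.9) {
  stopifnot(k >= 1, k <= ncol(freqs$f))
  ids <- which(freqs$f[, k] > c)
  structure(ids, lambda = freqs$grid[k], c = c, p = freqs$p)
}
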