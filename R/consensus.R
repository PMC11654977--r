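#' Bundle one engine's stability-selection output
#'
#' @param freqs a \code{\link{selection_frequencies}} table.
#' @param c frequency cutoff used for densities and edge sets.
#' @param weight positive method weight used by the weighted summaries
#'   (default 1).
#' @return object of class \code{"method_run"} holding the frequency table,
#'   its stability profile and an (initially unset) harmonized grid index.
#' @export
method_run <- function(freqs, c = 0.9, weight = 1) {
  stopifnot(weight > 0)
  structure(list(method_tag = freqs$method_tag, freqs = freqs,
                 profile = stability_profile(freqs, c = c),
                 chosen_k = NA_integer_, weight = weight, c = c,
                 harmonized = NA),
            class = "method_run")
}

#' @export
print.method_run <- function(x, ...) {
  cat(sprintf("<method_run> %s: K = %d, chosen_k = %s\n", x$method_tag,
              length(x$profile$S), x$chosen_k))
  invisible(x)
}

#' Harmonize per-method regularization by density
#'
#' Rather than selecting each method's penalty at a fixed stability (which
#' yields edge sets of very different sizes), all methods are driven to a
#' common target density: the largest reproducible-edge-set size d such that
#' the mean across methods of the stability at the first grid point reaching
#' density d is still at least \code{stab}. Every method then contributes a
#' similar number of edges while the ensemble stays reproducible on average.
#'
#' @param runs list of \code{\link{method_run}} objects (profiles already
#'   enveloped by construction).
#' @param stab mean-stability target (default 0.9).
#' @return the runs with \code{chosen_k} set and \code{harmonized = TRUE};
#'   when no positive density satisfies the constraint, each run falls back
#'   to its own \code{\link{stars_select}} index and is flagged
#'   \code{harmonized = FALSE}. The achieved target density is attached as
#'   \code{attr(, "target_density")}.
#' @export
harmonize_densities <- function(runs, stab = 0.9) {
  stopifnot(length(runs) >= 2)
  dens <- lapply(runs, function(r) r$profile$density)
  stabs <- lapply(runs, function(r) r$profile$S)
  candidates <- sort(unique(unlist(dens)), decreasing = TRUE)
  candidates <- candidates[candidates > 0]
  first_k <- function(d_vec, d) {
    k <- which(d_vec >= d)[1]
    if (is.na(k)) length(d_vec) else k     # unreachable: cap at densest point
  }
  for (d in candidates) {
    ks <- vapply(seq_along(runs), function(m) first_k(dens[[m]], d), integer(1))
    mean_S <- mean(vapply(seq_along(runs), function(m) stabs[[m]][ks[m]], numeric(1)))
    if (mean_S >= stab) {
      for (m in seq_along(runs)) {
        runs[[m]]$chosen_k <- ks[m]
        runs[[m]]$harmonized <- TRUE
      }
      attr(runs, "target_density") <- d
      attr(runs, "mean_stability") <- mean_S
      return(runs)
    }
  }
  warning("no common density satisfies the mean-stability constraint; ",
          "falling back to per-method StARS selection")
  for (m in seq_along(runs)) {
    runs[[m]]$chosen_k <- as.integer(stars_select(runs[[m]]$profile, stab))
    runs[[m]]$harmonized <- FALSE
  }
  attr(runs, "target_density") <- NA_integer_
  runs
}

# q x M matrix of per-method frequencies at each run's chosen grid point.
frequency_matrix <- function(runs) {
  stopifnot(all(vapply(runs, function(r) !is.na(r$chosen_k), logical(1))))
  F <- vapply(runs, function(r) r$freqs$f[, r$chosen_k], numeric(nrow(runs[[1]]$freqs$f)))
  colnames(F) <- vapply(runs, function(r) r$method_tag, character(1))
  F
}

#' Summarize selection frequencies across methods
#'
#' Per-edge ensemble score from the frequencies \eqn{f_m} each method reports
#' at its harmonized penalty:
#' \describe{
#'   \item{mean}{\eqn{\sum_m w_m f_m / \sum_m w_m} -- the most restrictive
#'     summary at a high threshold.}
#'   \item{norm2}{\eqn{(\sum_m w_m f_m^2)^{1/2} / (\sum_m w_m)^{1/2}} --
#'     skewed toward high frequencies.}
#'   \item{ivw}{inverse-variance weighted mean with Bernoulli variances
#'     \eqn{f_m(1-f_m)}; frequencies are clamped into
#'     \code{[clamp_eps, 1 - clamp_eps]} first, since 0/1 frequencies have
#'     zero variance and infinite weight.}
#'   \item{minp}{binary vote: 1 when at least \code{p_min} methods have
#'     \eqn{f_m > c}.}
#' }
#'
#' @param runs list of \code{\link{method_run}}s with \code{chosen_k} set
#'   (see \code{\link{harmonize_densities}}).
#' @param summary_tag one of \code{"mean"}, \code{"norm2"}, \code{"ivw"},
#'   \code{"minp"}.
#' @param c frequency cutoff for the minp vote.
#' @param p_min vote count for minp (default 3).
#' @param clamp_eps IVW clamping constant; default \code{1/(2B)}, half the
#'   frequency-lattice spacing.
#' @return object of class \code{"consensus_scores"}: \code{scores} edge
#'   vector in [0, 1] (binary for minp), plus the parameters and the
#'   per-method frequency matrix as provenance.
#' @export
summarize_frequencies <- function(runs, summary_tag = c("mean", "norm2", "ivw", "minp"),
                                  c = 0.9, p_min = 3, clamp_eps = NULL) {
  summary_tag <- match.arg(summary_tag)
  F <- frequency_matrix(runs)
  M <- ncol(F)
  w <- vapply(runs, function(r) r$weight, numeric(1))
  if (summary_tag == "minp" && p_min > M)
    stop(sprintf("p_min (%d) exceeds the number of methods (%d)", p_min, M))
  if (is.null(clamp_eps)) clamp_eps <- 1 / (2 * runs[[1]]$freqs$B)
  stopifnot(clamp_eps > 0, clamp_eps < 0.5)
  scores <- switch(summary_tag,
    mean  = as.numeric(F %*% w) / sum(w),
    norm2 = sqrt(as.numeric(F^2 %*% w) / sum(w)),
    ivw   = {
      Fc <- pmin(pmax(F, clamp_eps), 1 - clamp_eps)
      iv <- 1 / (Fc * (1 - Fc))
      as.numeric(rowSums(Fc * iv * rep(w, each = nrow(F))) /
                 rowSums(iv * rep(w, each = nrow(F))))
    },
    minp  = as.numeric(rowSums(F > c) >= p_min))
  structure(list(summary_tag = summary_tag, scores = scores,
                 params = list(c = c, p_min = p_min, clamp_eps = clamp_eps),
                 freq_matrix = F, p = runs[[1]]$freqs$p,
                 taxon_ids = runs[[1]]$freqs$taxon_ids),
            class = "consensus_scores")
}

#' Threshold consensus scores into a consensus graph
#'
#' @param scores a \code{\link{summarize_frequencies}} result.
#' @param c score threshold (strict \code{>}); ignored for minp scores,
#'   which are already binary votes.
#' @return object of class \code{"consensus_graph"}: edge ids, the summary
#'   tag, threshold, taxon ids and the per-method frequency provenance of the
#'   retained edges.
#' @export
consensus_graph <- function(scores, c = 0.9) {
  ids <- if (scores$summary_tag == "minp") which(scores$scores == 1)
         else which(scores$scores > c)
  structure(list(edges = ids, summary_tag = scores$summary_tag, c = c,
                 scores = scores$scores[ids], p = scores$p,
                 taxon_ids = scores$taxon_ids,
                 provenance = scores$freq_matrix[ids, , drop = FALSE]),
            class = "consensus_graph")
}

#' @export
print.consensus_graph <- function(x, ...) {
  cat(sprintf("<consensus_graph> %s summary: %d edges over %d taxa\n",
              x$summary_tag, length(x$edges), x$p))
  invisible(x)
}

#' Majority-rule consensus baseline
#'
#' The classical alternative to frequency summaries: each method selects its
#' own penalty by StARS at the target stability (no density harmonization),
#' refits on the full dataset at that penalty, and edges present in at least
#' half of the refit graphs are retained.
#'
#' @param runs list of \code{\link{method_run}}s.
#' @param engines list of \code{\link{engine}}s matching \code{runs}.
#' @param data named list of gaussianized full-data matrices, one per
#'   engine tag.
#' @param stab per-method StARS stability target.
#' @return a \code{"consensus_graph"} with summary tag \code{"mrc"}.
#' @export
mrc_consensus <- function(runs, engines, data, stab = 0.9) {
  stopifnot(length(runs) >= 2, length(runs) == length(engines))
  q <- nrow(runs[[1]]$freqs$f)
  votes <- integer(q)
  M <- 0L
  for (m in seq_along(runs)) {
    k <- as.integer(stars_select(runs[[m]]$profile, stab))
    adj <- tryCatch(
      engine_path(engines[[m]], data[[engines[[m]]$tag]], runs[[m]]$freqs$grid)[, k],
      error = function(e) {
        warning(sprintf("MRC refit failed for %s (%s); method dropped from the vote",
                        engines[[m]]$tag, conditionMessage(e)))
        NULL
      })
    if (is.null(adj)) next
    votes <- votes + adj
    M <- M + 1L
  }
  if (M < 1) stop("all MRC refits failed")
  ids <- which(votes >= ceiling(M / 2))
  structure(list(edges = ids, summary_tag = "mrc", c = NA_real_,
                 scores = votes[ids] / M, p = runs[[1]]$freqs$p,
                 taxon_ids = runs[[1]]$freqs$taxon_ids,
                 provenance = NULL, n_voting = M),
            class = "consensus_graph")
}
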