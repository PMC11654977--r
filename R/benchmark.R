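#' Replicated synthetic benchmark of consensus and single-engine recovery
#'
#' For each replicate: simulate a dataset with known truth
#' (\code{\link{simulate_dataset}}), run the consensus pipeline, and score
#' (a) every consensus summary graph and (b) every single engine's own
#' stability-selected reproducible-edge set against the truth adjacency.
#'
#' @param n sample size per dataset.
#' @param reps number of independent datasets (fresh graph and marginals).
#' @param seed master seed; replicate seeds are \code{seed * 1000 + rep_offset}.
#' @param rep_offset offset added to replicate indices when deriving seeds,
#'   so different sample sizes use disjoint seed streams.
#' @param p taxa per dataset.
#' @param engines,B,K,stab,cutoff,summaries,p_min,mrc passed to
#'   \code{\link{infer_consensus}}.
#' @param within_prob,k_clusters,diag_boost,max_zero_prob passed to
#'   \code{\link{simulate_dataset}}.
#' @return data.frame with one row per replicate x scored network:
#'   \code{rep}, \code{n}, \code{seed}, \code{method}, \code{kind}
#'   (\code{"consensus"}, \code{"engine"} or \code{"mrc"}), \code{n_edges},
#'   \code{TP}, \code{FP}, \code{FN}, \code{PPV}, \code{TPR}.
#' @export
evaluate_benchmark <- function(n, reps = 10, seed = 1, rep_offset = 0L, p = 100,
                               engines = default_engines(), B = 20, K = 25,
                               stab = 0.9, cutoff = 0.9,
                               summaries = c("mean", "norm2", "ivw", "minp"),
                               p_min = 3, mrc = FALSE,
                               within_prob = 0.3,
                               k_clusters = max(1L, round(p / 15)),
                               diag_boost = 0.1, max_zero_prob = 0.5) {
  rows <- list()
  for (r in seq_len(reps)) {
    ds_seed <- as.integer((seed * 1000 + rep_offset + r) %% .Machine$integer.max)
    res <- tryCatch({
      ds <- simulate_dataset(n = n, p = p, k_clusters = k_clusters,
                             within_prob = within_prob, diag_boost = diag_boost,
                             max_zero_prob = max_zero_prob, seed = ds_seed)
      infer_consensus(ds$counts, engines = engines, B = B, K = K,
                      stab = stab, cutoff = cutoff, summaries = summaries,
                      p_min = p_min, mrc = mrc, seed = ds_seed + 500L)
    }, error = function(e) {
      warning(sprintf("replicate %d (seed %d) failed and was skipped: %s",
                      r, ds_seed, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    add <- function(method, kind, ids) {
      m <- ppv_tpr(ids, ds$truth$A)
      rows[[length(rows) + 1]] <<- data.frame(
        rep = r, n = n, seed = ds_seed, method = method, kind = kind,
        n_edges = length(ids), TP = m$TP, FP = m$FP, FN = m$FN,
        PPV = m$PPV, TPR = m$TPR)
    }
    for (nm in names(res$graphs)) add(nm, "consensus", res$graphs[[nm]]$edges)
    if (!is.null(res$mrc)) add("mrc", "mrc", res$mrc$edges)
    for (run in res$runs) {
      k_star <- as.integer(stars_select(run$profile, stab))
      add(run$method_tag, "engine", as.integer(edge_set(run$freqs, k_star, cutoff)))
    }
  }
  do.call(rbind, rows)
}
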