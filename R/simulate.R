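#' Random cluster graph
#'
#' Partitions p taxa into balanced groups and draws within-group edges
#' independently; there are no between-group edges, so the truth graph is a
#' union of dense communities, mimicking microbial guilds.
#'
#' @param p number of taxa.
#' @param k_clusters number of groups (1 <= k <= p).
#' @param within_prob probability of each within-group edge, in (0, 1].
#' @param seed integer seed.
#' @return list with \code{A} (p x p symmetric binary adjacency) and
#'   \code{cluster} (integer group labels of length p).
#' @export
cluster_graph <- function(p, k_clusters, within_prob = 0.3, seed = 1) {
  stopifnot(k_clusters >= 1, k_clusters <= p, within_prob > 0, within_prob <= 1)
  cl <- sort(rep_len(seq_len(k_clusters), p))
  set.seed(seed)
  ei <- edge_index(p)
  same <- cl[ei[, 1]] == cl[ei[, 2]]
  draw <- rep(0L, nrow(ei))
  draw[same] <- rbinom(sum(same), 1, within_prob)
  A <- edges_to_adjacency(which(draw == 1L), p)
  list(A = A, cluster = cl)
}

#' Precision matrix from a truth adjacency
#'
#' Builds the graph Laplacian of the adjacency and adds a small ridge to the
#' diagonal (a pure Laplacian is singular): \eqn{\Omega = D - A + \epsilon I}.
#' The off-diagonal support of the result is exactly the adjacency, so the
#' conditional-dependence graph of the simulated data is known.
#'
#' @param A symmetric binary adjacency.
#' @param diag_boost positive ridge (default 0.1).
#' @return positive-definite precision matrix.
#' @export
graph_to_precision <- function(A, diag_boost = 0.1) {
  stopifnot(diag_boost > 0)
  validate_adjacency(A)
  Omega <- diag(rowSums(A) + diag_boost) - A
  ch <- tryCatch(chol(Omega), error = function(e)
    stop("precision not positive definite; increase diag_boost"))
  Omega
}

#' Correlation matrix implied by a precision matrix
#'
#' Inverts the precision and rescales to unit diagonal. The partial
#' correlation structure (the graph) is preserved by the rescaling.
#'
#' @param Omega positive-definite precision matrix.
#' @return correlation matrix with exactly unit diagonal.
#' @export
precision_to_correlation <- function(Omega) {
  if (kappa(Omega, exact = FALSE) > 1e12) stop("precision matrix is near-singular")
  Sigma <- solve(Omega)
  d <- 1 / sqrt(diag(Sigma))
  Sigma <- Sigma * tcrossprod(d)
  diag(Sigma) <- 1
  (Sigma + t(Sigma)) / 2
}

#' Empirical-quantile marginals from a reference count table
#'
#' Per taxon, the empirical quantile function Q(u) = smallest observed count
#' with ECDF >= u (right-continuous, quantile type 1). Feeding these to the
#' copula reproduces each reference taxon's marginal distribution.
#'
#' @param reference samples x taxa count matrix with at least 20 samples.
#' @return object of class \code{"marginal_spec"} (type \code{"ecdf"}).
#' @export
ecdf_marginals <- function(reference) {
  stopifnot(nrow(reference) >= 20)
  structure(list(type = "ecdf",
                 sorted = lapply(seq_len(ncol(reference)),
                                 function(j) sort(reference[, j])),
                 p = ncol(reference), taxon_ids = colnames(reference)),
            class = "marginal_spec")
}

#' Zero-inflated negative binomial marginals
#'
#' Parametric marginals so the simulator needs no reference dataset: with
#' probability \code{pi} a structural zero, otherwise a negative binomial
#' with mean \code{mu} and dispersion \code{theta} (gamma-Poisson; variance
#' \eqn{\mu + \mu^2/\theta}).
#'
#' @param pi zero-inflation mass per taxon, in [0, 1).
#' @param mu negative binomial mean per taxon (> 0).
#' @param theta dispersion per taxon (> 0; smaller = more overdispersed).
#' @return object of class \code{"marginal_spec"} (type \code{"zinb"}).
#' @export
zinb_marginals <- function(pi, mu, theta) {
  stopifnot(length(pi) == length(mu), length(mu) == length(theta),
            all(pi >= 0), all(pi < 1), all(mu > 0), all(theta > 0))
  structure(list(type = "zinb", pi = pi, mu = mu, theta = theta,
                 p = length(pi), taxon_ids = NULL),
            class = "marginal_spec")
}

#' Random ZINB marginals emulating a prevalence-filtered community
#'
#' Draws per-taxon ZINB parameters (zero mass uniform, mean log-uniform,
#' dispersion uniform). With \code{max_zero_prob} set, parameter triples are
#' rejection-sampled until each taxon's total zero probability
#' \eqn{\pi + (1-\pi)(\theta/(\theta+\mu))^\theta} falls below it, emulating
#' taxa that survive a prevalence filter at that level.
#'
#' @param p number of taxa.
#' @param pi_range,mu_range,theta_range parameter ranges (mu log-uniform).
#' @param max_zero_prob optional upper bound on the zero probability.
#' @param seed integer seed.
#' @return a ZINB \code{"marginal_spec"}.
#' @export
zinb_random_marginals <- function(p, pi_range = c(0.1, 0.6),
                                  mu_range = c(1, 200),
                                  theta_range = c(0.1, 2),
                                  max_zero_prob = NULL, seed = 1) {
  set.seed(seed)
  draw1 <- function() {
    c(pi = runif(1, pi_range[1], pi_range[2]),
      mu = exp(runif(1, log(mu_range[1]), log(mu_range[2]))),
      theta = runif(1, theta_range[1], theta_range[2]))
  }
  zero_prob <- function(par)
    par["pi"] + (1 - par["pi"]) * (par["theta"] / (par["theta"] + par["mu"]))^par["theta"]
  pars <- matrix(NA_real_, p, 3, dimnames = list(NULL, c("pi", "mu", "theta")))
  for (j in seq_len(p)) {
    par <- draw1()
    if (!is.null(max_zero_prob)) {
      tries <- 0
      while (zero_prob(par) >= max_zero_prob) {
        par <- draw1()
        tries <- tries + 1
        if (tries > 10000) stop("cannot satisfy max_zero_prob with these ranges")
      }
    }
    pars[j, ] <- par
  }
  zinb_marginals(pars[, "pi"], pars[, "mu"], pars[, "theta"])
}

#' Marginal quantile function
#'
#' @param spec a \code{"marginal_spec"}.
#' @param j taxon index.
#' @param u probabilities in (0, 1).
#' @return counts Q_j(u).
#' @export
marginal_quantile <- function(spec, j, u) {
  stopifnot(inherits(spec, "marginal_spec"), j >= 1, j <= spec$p)
  if (spec$type == "ecdf") {
    x <- spec$sorted[[j]]
    unname(x[pmax(1L, ceiling(u * length(x)))])  # smallest value with ECDF >= u
  } else {
    v <- pmax(0, (u - spec$pi[j]) / (1 - spec$pi[j]))
    qnbinom(v, size = spec$theta[j], mu = spec$mu[j])
  }
}

#' Simulation truth object
#'
#' @param A truth adjacency.
#' @param cluster cluster assignment.
#' @param diag_boost Laplacian ridge.
#' @return object of class \code{"simulation_truth"} holding \code{A},
#'   \code{Omega}, \code{Sigma} and \code{cluster}.
#' @export
simulation_truth <- function(A, cluster = NULL, diag_boost = 0.1) {
  Omega <- graph_to_precision(A, diag_boost)
  structure(list(A = A, Omega = Omega,
                 Sigma = precision_to_correlation(Omega),
                 cluster = cluster, diag_boost = diag_boost),
            class = "simulation_truth")
}

#' Draw copula counts with a known dependence graph
#'
#' Latent Gaussian rows are drawn with the truth correlation, mapped to
#' uniforms by the standard normal CDF, and pushed through each taxon's
#' marginal quantile function. The counts therefore have (approximately) the
#' requested marginals and a latent conditional-dependence graph equal to
#' the truth adjacency.
#'
#' @param truth a \code{\link{simulation_truth}}.
#' @param marginals a \code{"marginal_spec"} of matching length.
#' @param n number of samples.
#' @param seed integer seed.
#' @return list with \code{counts} (n x p matrix with ids), \code{Z} latent
#'   normals and \code{U} uniforms.
#' @export
copula_counts <- function(truth, marginals, n, seed = 1) {
  p <- nrow(truth$A)
  stopifnot(marginals$p == p, n >= 2)
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p) %*% chol(truth$Sigma)
  U <- pnorm(Z)                                  # Sigma has unit diagonal
  counts <- vapply(seq_len(p), function(j) marginal_quantile(marginals, j, U[, j]),
                   numeric(n))
  rownames(counts) <- sprintf("sample_%03d", seq_len(n))
  colnames(counts) <- marginals$taxon_ids %||% sprintf("taxon_%03d", seq_len(p))
  list(counts = counts, Z = Z, U = U)
}

#' Simulate one benchmark dataset
#'
#' Cluster-graph truth, Laplacian precision, Gaussian copula, ZINB marginals.
#'
#' @param n samples.
#' @param p taxa.
#' @param k_clusters number of clusters (default ~15 taxa per cluster).
#' @param within_prob within-cluster edge probability.
#' @param diag_boost Laplacian ridge.
#' @param marginals optional \code{"marginal_spec"}; by default random ZINB
#'   marginals restricted to zero probability < \code{max_zero_prob}.
#' @param max_zero_prob zero-probability cap for the default marginals.
#' @param seed integer seed controlling graph, marginals and counts.
#' @return list with \code{counts}, \code{truth}
#'   (\code{\link{simulation_truth}}) and \code{seed}.
#' @export
simulate_dataset <- function(n, p = 100, k_clusters = max(1L, round(p / 15)),
                             within_prob = 0.3, diag_boost = 0.1,
                             marginals = NULL, max_zero_prob = 0.5, seed = 1) {
  g <- cluster_graph(p, k_clusters, within_prob, seed = seed)
  truth <- simulation_truth(g$A, g$cluster, diag_boost)
  if (is.null(marginals))
    marginals <- zinb_random_marginals(p, max_zero_prob = max_zero_prob,
                                       seed = seed + 1L)
  cs <- copula_counts(truth, marginals, n, seed = seed + 2L)
  list(counts = cs$counts, truth = truth, marginals = marginals, seed = seed)
}

#' Replicated benchmark datasets over several sample sizes
#'
#' @param n_values vector of sample sizes.
#' @param p taxa per dataset.
#' @param reps independent datasets per sample size (fresh graph and
#'   marginals each).
#' @param seed master seed; replicate seeds are derived deterministically.
#' @param ... passed to \code{\link{simulate_dataset}}.
#' @return list of datasets, each as in \code{\link{simulate_dataset}} plus
#'   \code{n}; seeds recorded per dataset.
#' @export
benchmark_suite <- function(n_values, p = 100, reps = 10, seed = 1, ...) {
  stopifnot(reps >= 1)
  out <- list()
  for (n in n_values) {
    for (r in seq_len(reps)) {
      ds_seed <- (seed * 1000L + n + 7L * r) %% .Machine$integer.max
      ds <- simulate_dataset(n = n, p = p, seed = as.integer(ds_seed), ...)
      ds$n <- n
      out[[length(out) + 1L]] <- ds
    }
  }
  out
}
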