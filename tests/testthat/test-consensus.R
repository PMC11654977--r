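# helper: method_run with a prescribed (enveloped) profile
run_with_profile <- function(S, density, freqs = NULL, K = length(S), tag = "m") {
  fr <- freqs %||% toy_freq_table(p = 6, K = K, seed = 1, tag = tag)
  r <- method_run(fr)
  r$profile$S <- S
  r$profile$density <- as.integer(density)
  r
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical runs harmonize to the StARS point of any one of them", {
  fr <- toy_freq_table(p = 8, K = 8, B = 10, seed = 5)
  fr$f[1:3, ] <- 1      # a few perfectly reproducible edges keep S high early
  runs <- list(method_run(fr), method_run(fr), method_run(fr))
  out <- harmonize_densities(runs, stab = 0.6)
  ks <- vapply(out, function(r) r$chosen_k, integer(1))
  expect_true(all(ks == ks[1]))
  expect_equal(ks[1], as.integer(stars_select(runs[[1]]$profile, 0.6)))
  expect_true(all(vapply(out, function(r) r$harmonized, logical(1))))
})

test_that("mean-stability constraint admits denser selections than per-method StARS", {
  # run A perfectly stable everywhere; run B decays: the pooled constraint
  # accepts B's densest point because (1 + 0.80)/2 = 0.90
  A <- run_with_profile(c(1, 1, 1), c(1, 1, 1), K = 3, tag = "A")
  B <- run_with_profile(c(1.0, 0.92, 0.80), c(1, 2, 3), K = 3, tag = "B")
  out <- harmonize_densities(list(A, B), stab = 0.9)
  expect_equal(attr(out, "target_density"), 3L)
  expect_equal(out[[2]]$chosen_k, 3L)
  expect_gt(out[[2]]$chosen_k, as.integer(stars_select(B$profile, 0.9)))
  expect_equal(attr(out, "mean_stability"), 0.9)
})

test_that("harmonization falls back to StARS when no density satisfies the constraint", {
  A <- run_with_profile(c(0.5, 0.4, 0.3), c(1, 2, 3), K = 3, tag = "A")
  B <- run_with_profile(c(0.6, 0.5, 0.4), c(2, 3, 4), K = 3, tag = "B")
  expect_warning(out <- harmonize_densities(list(A, B), stab = 0.9),
                 "falling back")
  expect_false(any(vapply(out, function(r) r$harmonized, logical(1))))
  expect_true(all(!is.na(vapply(out, function(r) r$chosen_k, integer(1)))))
})

test_that("summaries match hand-computed oracles", {
  # three methods with fixed frequencies at chosen_k
  mk_run <- function(fcol, tag) {
    fr <- structure(list(f = matrix(fcol, ncol = 1),
                         grid = structure(0.2, scale = "penalty"), B = 40,
                         method_tag = tag, p = 3, taxon_ids = paste0("t", 1:3)),
                    class = "frequency_table")
    r <- method_run(fr)
    r$chosen_k <- 1L
    r
  }
  runs <- list(mk_run(c(0.8, 1.0, 0.2), "a"), mk_run(c(1.0, 1.0, 0.5), "b"),
               mk_run(c(0.9, 1.0, 0.95), "c"))
  expect_equal(summarize_frequencies(runs, "mean")$scores[1], mean(c(0.8, 1, 0.9)))
  expect_equal(summarize_frequencies(runs, "norm2")$scores[2], 1.0)
  expect_equal(summarize_frequencies(runs, "norm2")$scores[1],
               sqrt(sum(c(0.8, 1, 0.9)^2) / 3))
  # minp vote with p_min = 3, c = 0.9: edge2 has all three above, edge1 only one
  mp <- summarize_frequencies(runs, "minp", c = 0.9, p_min = 3)$scores
  expect_equal(mp, c(0, 1, 0))
  mp2 <- summarize_frequencies(list(mk_run(c(0.95, 0, 0), "a"),
                                    mk_run(c(0.92, 0, 0), "b"),
                                    mk_run(c(0.91, 0, 0), "c"),
                                    mk_run(c(0.20, 0, 0), "d")),
                               "minp", c = 0.9, p_min = 3)$scores
  expect_equal(mp2[1], 1)
  expect_error(summarize_frequencies(runs, "minp", p_min = 4), "exceeds")
})

test_that("IVW clamps zero-variance frequencies and matches hand arithmetic", {
  mk_run <- function(fcol, tag, B = 40) {
    fr <- structure(list(f = matrix(fcol, ncol = 1),
                         grid = structure(0.2, scale = "penalty"), B = B,
                         method_tag = tag, p = 2, taxon_ids = paste0("t", 1:2)),
                    class = "frequency_table")
    r <- method_run(fr); r$chosen_k <- 1L; r
  }
  runs <- list(mk_run(c(1.0, 0.3), "a"), mk_run(c(0.5, 0.3), "b"))
  sc <- summarize_frequencies(runs, "ivw")   # clamp_eps = 1/80
  f1 <- 1 - 1 / 80
  w1 <- 1 / (f1 * (1 - f1)); w2 <- 1 / 0.25
  expect_equal(sc$scores[1], (w1 * f1 + w2 * 0.5) / (w1 + w2), tolerance = 1e-12)
  expect_equal(sc$scores[1], 0.9646, tolerance = 5e-4)
  expect_equal(sc$scores[2], 0.3)
})

test_that("consensus graphs threshold strictly and mean is nested in norm2", {
  for (seed in 1:10) {
    runs <- lapply(1:4, function(m) {
      r <- method_run(toy_freq_table(p = 8, K = 6, B = 10, seed = seed * 10 + m,
                                     tag = paste0("m", m)))
      r$chosen_k <- 4L
      r
    })
    g_mean <- consensus_graph(summarize_frequencies(runs, "mean"), c = 0.7)
    g_norm2 <- consensus_graph(summarize_frequencies(runs, "norm2"), c = 0.7)
    expect_true(all(g_mean$edges %in% g_norm2$edges))   # power-mean inequality
  }
  # empty and single-edge cases
  sc <- structure(list(summary_tag = "mean", scores = c(0, 0.95, 0),
                       params = list(), freq_matrix = NULL, p = 3,
                       taxon_ids = paste0("t", 1:3)),
                  class = "consensus_scores")
  expect_equal(consensus_graph(sc, 0.9)$edges, 2L)
  sc$scores <- rep(0, 3)
  expect_equal(length(consensus_graph(sc, 0.9)$edges), 0L)
})

test_that("summaries are invariant to method permutations at equal weights", {
  runs <- lapply(1:5, function(m) {
    r <- method_run(toy_freq_table(p = 7, K = 5, B = 10, seed = 100 + m,
                                   tag = paste0("m", m)))
    r$chosen_k <- 3L
    r
  })
  perm <- sample(5)
  for (s in c("mean", "norm2", "ivw", "minp")) {
    s1 <- summarize_frequencies(runs, s, p_min = 3)$scores
    s2 <- summarize_frequencies(runs[perm], s, p_min = 3)$scores
    expect_equal(s1, s2, info = s)
  }
})

test_that("high mean-consensus edges are supported by most methods (pigeonhole)", {
  # with M = 7 and mean f > 0.9, at least 6 methods must exceed 0.5
  runs <- lapply(1:7, function(m) {
    r <- method_run(toy_freq_table(p = 10, K = 6, B = 20, seed = 300 + m,
                                   never_frac = 0.5, tag = paste0("m", m)))
    r$chosen_k <- 5L
    r
  })
  sc <- summarize_frequencies(runs, "mean")
  g <- consensus_graph(sc, c = 0.9)
  if (length(g$edges)) {
    support <- rowSums(sc$freq_matrix[g$edges, , drop = FALSE] > 0.5)
    expect_true(all(support >= 6))
  }
  succeed()
})

test_that("majority-rule consensus votes over refit graphs", {
  set.seed(21)
  n <- 60; p <- 8
  A <- cluster_graph(p, 2, 0.8, seed = 3)$A
  x <- matrix(rnorm(n * p), n, p) %*% chol(simulation_truth(A)$Sigma)
  colnames(x) <- paste0("t", 1:p)
  counts <- matrix(rpois(n * p, exp(x + 3)), n, p,
                   dimnames = list(paste0("s", 1:n), paste0("t", 1:p)))
  engines <- list(engine("mb", "clr"), engine("glasso", "clr"), engine("tree", "clr"))
  res <- infer_consensus(counts, engines = engines, B = 6, K = 8, seed = 5,
                         mrc = TRUE)
  expect_s3_class(res$mrc, "consensus_graph")
  expect_equal(res$mrc$summary_tag, "mrc")
  # votes recorded as fractions of voting methods
  expect_true(all(res$mrc$scores >= 0.5 - 1e-12))

  # unanimity: identical runs vote in every refit graph
  x2 <- res$runs[[1]]
  runs <- list(x2, x2)
  engs <- list(engine("mb", "clr"), engine("mb", "clr"))
  data <- setNames(list(gaussianize(counts, "clr")), "mb-clr")
  g <- mrc_consensus(runs, engs, data, stab = 0.9)
  k <- as.integer(stars_select(x2$profile, 0.9))
  refit <- mb_path(data[["mb-clr"]], x2$freqs$grid)[, k]
  expect_equal(g$edges, which(refit == 1))
})
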