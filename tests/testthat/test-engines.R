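test_that("lambda_max anchors the empty end of the path", {
  # p = 2 with known sample correlation
  set.seed(1)
  x <- cbind(a = rnorm(50), b = rnorm(50))
  x[, 2] <- 0.6 * scale(x[, 1]) + sqrt(1 - 0.36) * scale(resid(lm(x[, 2] ~ x[, 1])))
  r <- cor(x)[1, 2]
  expect_equal(lambda_max(x), abs(r))

  # perfectly correlated pair
  y <- cbind(a = rnorm(20), b = 1:20)
  y[, 1] <- 2 * y[, 2] + 3
  expect_equal(lambda_max(y), 1)

  # independent large-n columns: max |cor| <= 3/sqrt(n) with high probability
  set.seed(99)
  z <- matrix(rnorm(4000 * 5), 4000, 5)
  expect_lt(lambda_max(z), 3 / sqrt(4000))

  expect_error(lambda_max(cbind(a = rep(1, 10), b = rnorm(10))), "zero-variance")
})

test_that("glasso path matches the 2x2 closed-form threshold rule", {
  # closed form: edge present iff |r| > lambda
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    x <- matrix(rnorm(2 * n), n, 2)
    x[, 2] <- x[, 2] + runif(1, -1.5, 1.5) * x[, 1]
    r <- abs(cor(x)[1, 2])
    grid <- lambda_grid(x, K = 12, ratio = 0.02)
    path <- glasso_path(x, grid, tol = 1e-6, inner_tol = 1e-8)
    expect_equal(as.integer(path[1, ]), as.integer(r > grid + 1e-12))
  }
})

test_that("glasso endpoints: empty above lambda_max, complete near zero", {
  set.seed(3)
  x <- matrix(rnorm(60 * 6), 60, 6)
  lmax <- lambda_max(x)
  grid <- c(lmax * 1.01, lmax * 0.9, 1e-4)
  attr(grid, "scale") <- "penalty"
  path <- glasso_path(x, grid)
  expect_equal(sum(path[, 1]), 0)
  expect_equal(sum(path[, 3]), n_edges(6))
})

test_that("glasso solution satisfies the KKT conditions (independent oracle)", {
  set.seed(7)
  p <- 8; n <- 60
  x <- matrix(rnorm(n * p), n, p)
  x[, 2] <- 0.7 * x[, 1] + rnorm(n, sd = 0.6)
  x[, 5] <- -0.5 * x[, 4] + rnorm(n, sd = 0.8)
  S <- cor(x)
  for (lam in c(0.3, 0.15, 0.05)) {
    res <- consenet:::.glasso_path_cpp(S, c(0.5, lam), 1e-7, 500, 1e-9, 1000, TRUE)
    Th <- res$theta[[2]]
    W <- solve(Th)
    D <- W - S; diag(D) <- 0
    expect_lt(max(abs(D)), lam * (1 + 1e-6))           # subgradient bound
    nz <- which(abs(Th) > 1e-8 & row(Th) != col(Th))
    expect_lt(max(abs(D[nz] - lam * sign(Th[nz]))), 1e-6)  # active-edge equality
  }
})

test_that("MB path agrees with node-wise glmnet lasso (independent oracle)", {
  skip_if_not_installed("glmnet")
  set.seed(2)
  n <- 150; p <- 7
  x <- matrix(rnorm(n * p), n, p)
  x[, 2] <- 0.8 * x[, 1] + rnorm(n, sd = 0.5)
  x[, 3] <- -0.6 * x[, 2] + rnorm(n, sd = 0.7)
  grid <- lambda_grid(x, K = 10, ratio = 0.05)
  for (rule in c("OR", "AND")) {
    mb <- mb_path(x, grid, symmetrize = rule, inner_tol = 1e-9)
    xs <- scale(x) * sqrt(n / (n - 1))   # unit 1/n-variance to match cor scale
    sel <- lapply(seq_len(p), function(j) {
      fit <- glmnet::glmnet(xs[, -j], xs[, j], lambda = as.numeric(grid),
                            standardize = FALSE, intercept = FALSE, thresh = 1e-14)
      as.matrix(fit$beta) != 0
    })
    # the first grid point sits exactly at lambda_max, where the strongest
    # pair is on the soft-threshold boundary and inclusion is a numerical
    # coin flip; compare strictly interior points
    for (k in 2:length(grid)) {
      Avote <- matrix(0L, p, p)
      for (j in seq_len(p)) {
        nb <- (seq_len(p))[-j][sel[[j]][, k]]
        Avote[j, nb] <- Avote[j, nb] + 1L
      }
      votes <- Avote + t(Avote)
      A <- if (rule == "OR") votes > 0 else votes == 2
      expect_equal(which(mb[, k] == 1), which(A[lower.tri(A)]),
                   info = sprintf("rule %s, grid point %d", rule, k))
    }
  }
})

test_that("MB symmetrization rules and null threshold behave as defined", {
  set.seed(11)
  x <- matrix(rnorm(80 * 5), 80, 5)
  lmax <- lambda_max(x)
  grid <- c(lmax * 1.05, lmax * 0.5)
  attr(grid, "scale") <- "penalty"
  expect_equal(sum(mb_path(x, grid)[, 1]), 0)   # empty at lambda >= lambda_max
  # OR is at least as dense as AND everywhere
  g2 <- lambda_grid(x, K = 8)
  expect_true(all(mb_path(x, g2, "OR") >= mb_path(x, g2, "AND")))
})

test_that("MB recovers a 3-variable chain without the transitive edge", {
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  truth <- simulation_truth(A, diag_boost = 1)
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    x <- matrix(rnorm(500 * 3), 500, 3) %*% chol(truth$Sigma)
    grid <- lambda_grid(x, K = 15)
    path <- mb_path(x, grid)
    k <- 8   # mid-path
    if (all(path[c(1, 3), k] == 1) && path[2, k] == 0) hits <- hits + 1
  }
  expect_gt(hits, 10)   # majority of seeds
})

test_that("tree probabilities match spanning-tree enumeration", {
  # triangle with equal weights: every edge in 2 of 3 trees
  W <- matrix(1, 3, 3); diag(W) <- 0
  expect_equal(tree_edge_prob_from_weights(W), rep(2 / 3, 3), tolerance = 1e-12)

  # weights supported on a spanning tree only: probabilities are 0/1
  p <- 5
  Wt <- matrix(0, p, p)
  for (i in 1:(p - 1)) { Wt[i, i + 1] <- 1.5; Wt[i + 1, i] <- 1.5 }
  pr <- tree_edge_prob_from_weights(Wt)
  onpath <- edge_id_pairs <- edge_index(p)
  chain <- which(edge_id_pairs[, 2] - edge_id_pairs[, 1] == 1)
  expect_equal(pr[chain], rep(1, p - 1), tolerance = 1e-9)
  expect_equal(pr[-chain], rep(0, n_edges(p) - (p - 1)), tolerance = 1e-9)

  # random weighted graphs, p = 4 and 5, vs brute-force enumeration
  for (p in 4:5) {
    trees <- spanning_trees_of_complete(p)
    for (seed in 1:5) {
      set.seed(seed)
      W <- matrix(0, p, p)
      W[lower.tri(W)] <- runif(n_edges(p), 0.1, 2) * rbinom(n_edges(p), 1, 0.8)
      W <- W + t(W)
      ok <- tryCatch({ pr <- tree_edge_prob_from_weights(W); TRUE },
                     error = function(e) FALSE)
      if (!ok) next   # disconnected draw
      expect_equal(pr, tree_prob_oracle(W, trees), tolerance = 1e-8)
      expect_equal(sum(pr), p - 1, tolerance = 1e-8)
    }
  }
})

test_that("tree probabilities from data sum to p - 1 and clamp perfect correlation", {
  set.seed(5)
  x <- matrix(rnorm(40 * 6), 40, 6)
  pr <- tree_edge_probabilities(x)
  expect_equal(sum(pr), 5, tolerance = 1e-8)
  expect_true(all(pr >= 0 & pr <= 1))

  x2 <- cbind(x, 2 * x[, 1] + 1)
  expect_warning(pr2 <- tree_edge_probabilities(x2), "clamp")
  expect_equal(sum(pr2), 6, tolerance = 1e-6)
})

test_that("treeavg_path thresholds strictly", {
  pr <- c(0.9, 0.5, 0.1)
  grid <- c(0.8, 0.4)
  attr(grid, "scale") <- "probability_threshold"
  path <- treeavg_path(pr, grid)
  expect_equal(colSums(path), c(1L, 2L))
  expect_equal(sum(treeavg_path(pr, c(0.95, 0.91))), 0)
  expect_equal(colSums(treeavg_path(pr, c(0.5, 1e-9)))[2], c(3L), ignore_attr = TRUE)
})

test_that("paths are monotone and grids well-formed", {
  set.seed(8)
  x <- matrix(rnorm(50 * 8), 50, 8)
  for (path in list(glasso_path(x, lambda_grid(x, K = 10)),
                    mb_path(x, lambda_grid(x, K = 10)))) {
    expect_true(all(diff(colSums(path)) >= 0))
    expect_true(all(path %in% 0:1))
  }
  g <- lambda_grid(x, K = 10)
  expect_true(all(diff(g) < 0))
  gt <- lambda_grid(K = 10, scale = "probability_threshold")
  expect_true(all(diff(gt) < 0) && all(gt > 0 & gt < 1))
})
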