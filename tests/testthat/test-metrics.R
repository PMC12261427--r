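test_that("mmd_rbf matches its closed form and oracle", {
  set.seed(1)
  X <- matrix(rnorm(40), 20, 2)
  # identical multisets -> 0
  expect_equal(as.numeric(mmd_rbf(X, X)), 0, tolerance = 1e-12)
  # symmetry (exact)
  Y <- matrix(rnorm(30), 15, 2)
  expect_equal(as.numeric(mmd_rbf(X, Y)), as.numeric(mmd_rbf(Y, X)))
  # singleton clouds {0}, {d} at one scale gamma: MMD^2 = 2(1 - exp(-g d^2))
  for (d0 in c(1, 2.5)) {
    for (g in c(0.3, 2)) {
      expect_equal(as.numeric(mmd_rbf(rbind(0), rbind(d0), scales = g)),
                   2 * (1 - exp(-g * d0^2)), tolerance = 1e-12)
    }
  }
  # double-loop kernel-sum oracle at several scales, n, m <= 50
  set.seed(2)
  A <- matrix(rnorm(50 * 3), 50, 3)
  B <- matrix(rnorm(40 * 3), 40, 3) + 0.5
  gammas <- c(0.1, 1, 5)
  expect_equal(as.numeric(mmd_rbf(A, B, scales = gammas)),
               mmd_oracle(A, B, gammas), tolerance = 1e-10)
  # invariant to identical column permutations of both inputs
  p <- c(3, 1, 2)
  expect_equal(as.numeric(mmd_rbf(A[, p], B[, p])), as.numeric(mmd_rbf(A, B)))
  expect_error(mmd_rbf(A[0, ], B), "empty")
})

test_that("feature-mean metrics follow their definitions", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  expect_equal(as.numeric(r2_means(X, X)), 1)
  expect_equal(l2_means(X, X), 0)
  # 3-4-5 triangle on the mean vectors
  A <- rbind(c(0, 0))
  B <- rbind(c(3, 4))
  expect_equal(l2_means(A, B), 5)
  # anti-correlated means: squared Pearson is 1, signed r is -1
  U <- rbind(c(1, 2, 3))
  V <- rbind(c(3, 2, 1))
  r2 <- r2_means(U, V)
  expect_equal(as.numeric(r2), 1)
  expect_equal(attr(r2, "pearson"), -1)
  # zero-variance mean vector -> missing
  expect_true(is.na(r2_means(rbind(c(1, 1, 1)), V)))
  # column-permutation invariance
  Y <- matrix(rnorm(60), 20, 3)
  p <- c(2, 3, 1)
  expect_equal(l2_means(X[, p], Y[, p]), l2_means(X, Y))
  expect_equal(as.numeric(r2_means(X[, p], Y[, p])), as.numeric(r2_means(X, Y)))
})

test_that("monotonicity violations are detected on constructed pairs", {
  X <- rbind(c(0, 0), c(1, 0))
  pairs <- rbind(c(1L, 2L))
  # order preserved: unit vectors sum to (2, 0)
  expect_equal(monotonicity_violation_rate(X, rbind(c(2, 0), c(3, 0)), pairs), 0)
  # order inverted: unit vectors cancel
  expect_equal(monotonicity_violation_rate(X, rbind(c(3, 0), c(2, 0)), pairs), 1)
  # identity map never violates
  set.seed(4)
  Z <- matrix(rnorm(200), 100, 2)
  expect_equal(monotonicity_violation_rate(Z, Z, n_pairs = 2000, seed = 1), 0)
  # coincident points are skipped, not counted
  W <- rbind(c(0, 0), c(0, 0))
  expect_equal(monotonicity_violation_rate(W, W, rbind(c(1L, 2L))), 0)
})

test_that("rank_de_genes ranks by the standardized rank-sum statistic", {
  set.seed(5)
  ctrl <- matrix(rnorm(100 * 10), 100, 10)
  pert <- matrix(rnorm(100 * 10), 100, 10)
  pert[, 7] <- pert[, 7] + 10 # one feature shifted by 10 sd
  top <- rank_de_genes(ctrl, pert, k = 3)
  expect_equal(top[1], 7L)
  expect_length(unique(top), 3L)
  # cross-check the winning feature against the base-R rank-sum oracle
  p <- vapply(1:10, function(j) {
    suppressWarnings(wilcox.test(ctrl[, j], pert[, j])$p.value)
  }, numeric(1))
  expect_equal(top[1], which.min(p))
  # identical inputs: deterministic tie-break by feature index
  expect_equal(rank_de_genes(ctrl, ctrl, k = 4), 1:4)
  expect_error(rank_de_genes(ctrl, pert, k = 11), "exceeds")
})

test_that("logfc_mae measures log2 mean ratios on selected features", {
  set.seed(6)
  obs <- matrix(rexp(50 * 6), 50, 6)
  expect_equal(logfc_mae(obs, obs, 1:6), 0)
  # predicted means exactly 2x observed -> MAE = 1
  expect_equal(logfc_mae(obs * 2, obs, c(2, 4)), 1, tolerance = 1e-6)
  # invariant to row order
  expect_equal(logfc_mae(obs[sample(50), ], obs, 1:3), 0, tolerance = 1e-12)
})

test_that("metrics_report assembles the panel", {
  set.seed(7)
  X <- matrix(rnorm(100), 50, 2)
  Y <- matrix(rnorm(100), 50, 2) + 1
  rep <- metrics_report(X, Y, source = X, gene_idx = 1:2)
  expect_s3_class(rep, "metrics_report")
  expect_true(all(is.finite(c(rep$r2_means, rep$l2_means, rep$mmd))))
  expect_gte(rep$mmd, 0)
  expect_equal(rep$monotonicity_violation_rate, 0) # identity prediction
  expect_length(rep$mmd_scales, 6L)
})
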