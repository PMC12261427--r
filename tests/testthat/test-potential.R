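test_that("layer weights are (semi-)orthonormal for any raw parameters", {
  for (method in c("cayley", "bjorck")) {
    net <- lipschitz_potential(3, hidden = c(8L, 8L), group_size = 4L,
                               method = method, seed = 2)
    # perturb the raw parameters and re-orthonormalize (parameter update path)
    set.seed(9)
    for (l in seq_along(net$layers)) {
      net$layers[[l]]$raw <- net$layers[[l]]$raw +
        matrix(rnorm(length(net$layers[[l]]$raw), sd = 0.1),
               nrow(net$layers[[l]]$raw))
    }
    net <- w1map:::.potential_refresh(net)
    for (l in seq_along(net$layers)) {
      W <- net$layers[[l]]$W
      G <- if (nrow(W) <= ncol(W)) tcrossprod(W) else crossprod(W)
      expect_lt(max(abs(G - diag(min(dim(W))))), 1e-5)
      expect_lt(svd(W, nu = 0, nv = 0)$d[1], 1 + 1e-5)
      # norm non-expansion on random vectors
      V <- matrix(rnorm(5 * ncol(W)), ncol = ncol(W))
      expect_true(all(sqrt(rowSums((V %*% t(W))^2)) <=
                        sqrt(rowSums(V^2)) + 1e-10))
    }
  }
})

test_that("hidden widths must be divisible by the group size", {
  expect_error(lipschitz_potential(2, hidden = c(6L, 6L), group_size = 4L),
               "divisible")
})

test_that("degenerate parameterization gives an exactly affine potential", {
  # group size 1 + zero raw parameters -> identity weights -> f(x) = x[1] + b
  net <- affine_potential(d = 3, bias = 1.5)
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(potential_forward(net, X), X[, 1] + 1.5)
  # gradient is the unit row w = e1 at every point
  G <- potential_gradient(net, X)
  expect_equal(G, matrix(rep(c(1, 0, 0), each = 10), 10, 3))
})

test_that("the network is 1-Lipschitz for arbitrary parameter settings", {
  set.seed(31)
  for (cfg in list(list(d = 2L, hidden = c(64L, 64L, 64L, 64L), g = 4L),
                   list(d = 7L, hidden = c(16L, 16L), g = 2L))) {
    net <- lipschitz_potential(cfg$d, hidden = cfg$hidden, group_size = cfg$g)
    X <- matrix(runif(2 * 2000 * cfg$d, -5, 5), ncol = cfg$d)
    f <- potential_forward(net, X)
    i <- seq_len(2000)
    j <- 2000 + i
    ratio <- abs(f[i] - f[j]) / sqrt(rowSums((X[i, , drop = FALSE] -
                                                X[j, , drop = FALSE])^2))
    expect_lte(max(ratio), 1 + 1e-4)
  }
})

test_that("potential gradients match central finite differences", {
  for (method in c("cayley", "bjorck")) {
    net <- lipschitz_potential(3, hidden = c(8L, 8L), group_size = 4L,
                               method = method, seed = 13)
    set.seed(14)
    X <- matrix(rnorm(5 * 3), 5, 3)
    expect_equal(potential_gradient(net, X), fd_gradient(net, X),
                 tolerance = 1e-4)
  }
})

test_that("gradient row norms never exceed 1", {
  set.seed(40)
  net <- lipschitz_potential(4, hidden = c(32L, 32L), group_size = 4L)
  X <- matrix(rnorm(500 * 4, sd = 3), 500, 4)
  expect_lte(max(sqrt(rowSums(potential_gradient(net, X)^2))), 1 + 1e-4)
})

test_that("forward pass validates input dimension", {
  net <- lipschitz_potential(3, hidden = c(8L), group_size = 4L, seed = 1)
  expect_error(potential_forward(net, matrix(0, 2, 5)), "expects")
})
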