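test_that("generators are pure functions of (parameters, seed)", {
  gens <- list(
    function() make_bookshelf(200, seed = 5),
    function() make_circles_pair(200, seed = 5),
    function() make_swiss_roll_pair(200, seed = 5),
    function() make_moons_pair(200, seed = 5),
    function() make_gaussian_pair(c(1, 2), n = 200, seed = 5)
  )
  for (gen in gens) {
    a <- gen()
    b <- gen()
    expect_identical(a$source$points, b$source$points)
    expect_identical(a$target$points, b$target$points)
  }
})

test_that("bookshelf strips have the documented supports", {
  pair <- make_bookshelf(1000, seed = 2)
  src <- pair$source$points
  tgt <- pair$target$points
  expect_true(all(src[, 1] >= 0 & src[, 1] <= 1))
  expect_true(all(tgt[, 1] >= 2 & tgt[, 1] <= 3))
  # y noise has standard deviation ~0.001 (within 20% at n = 1000)
  expect_lt(abs(sd(src[, 2]) - 0.001) / 0.001, 0.2)
  expect_lt(abs(sd(tgt[, 2]) - 0.001) / 0.001, 0.2)
  expect_length(pair$markers, 5L)
  expect_true(all(pair$markers %in% seq_len(1000)))
  # the ideal strips are a translation by 2: W1 = 2; the empirical mean gap
  # estimates it within sampling error
  expect_equal(mean(tgt[, 1]) - mean(src[, 1]), 2, tolerance = 0.05)
})

test_that("circles have four rings with exact labels", {
  pair <- make_circles_pair(400, noise = 0, seed = 3)
  r_src <- sqrt(rowSums(pair$source$points^2))
  r_tgt <- sqrt(rowSums(pair$target$points^2))
  # noiseless points lie on exact circles
  expect_lt(max(abs(r_src - ifelse(pair$source$labels == "inner", 0.5, 1))), 1e-9)
  expect_lt(max(abs(r_tgt - ifelse(pair$target$labels == "inner", 2, 4))), 1e-9)
  # 4 distinct radii present overall
  expect_equal(sort(unique(round(c(r_src, r_tgt), 6))), c(0.5, 1, 2, 4))
  # labels partition the points exactly
  expect_equal(sort(unique(pair$source$labels)), c("inner", "outer"))
  expect_equal(length(pair$source$labels), 400L)
})

test_that("swiss roll pairs a standard Gaussian with a scaled spiral", {
  pair <- make_swiss_roll_pair(2000, seed = 4)
  src <- pair$source$points
  expect_true(all(abs(colMeans(src)) < 3 / sqrt(2000) * 1.5))
  expect_lt(max(abs(stats::cov(src) - diag(2))), 0.15)
  # spiral radius equals t * scale with t in [1.5 pi, 4.5 pi]; the default
  # noise (sd 0.05) perturbs it slightly
  r <- sqrt(rowSums(pair$target$points^2))
  expect_true(all(r > 1.5 * pi * 0.1 - 0.5 & r < 4.5 * pi * 0.1 + 0.5))
  rexact <- sqrt(rowSums(make_swiss_roll_pair(500, noise = 0, seed = 4)$target$points^2))
  expect_true(all(rexact >= 1.5 * pi * 0.1 - 1e-9 &
                    rexact <= 4.5 * pi * 0.1 + 1e-9))
})

test_that("moons are two interleaving half-circles with disjoint labels", {
  pair <- make_moons_pair(500, noise = 0, seed = 6)
  src <- pair$source$points
  tgt <- pair$target$points
  expect_lt(max(abs(sqrt(rowSums(src^2)) - 1)), 1e-9) # upper unit half-circle
  expect_true(all(src[, 2] >= -1e-9))
  # lower moon is centred at (1, 0.5), radius 1, opening upward
  expect_lt(max(abs(sqrt((tgt[, 1] - 1)^2 + (tgt[, 2] - 0.5)^2) - 1)), 1e-9)
  expect_true(all(tgt[, 2] <= 0.5 + 1e-9))
  expect_true(all(pair$source$labels == "upper"))
  expect_true(all(pair$target$labels == "lower"))
})

test_that("gaussian pairs realize the requested translation", {
  pair <- make_gaussian_pair(c(4, 0), n = 4000, seed = 8)
  gap <- colMeans(pair$target$points) - colMeans(pair$source$points)
  # standard-error oracle: per-component variance of the gap is 2/n
  expect_true(all(abs(gap - c(4, 0)) < 3 * sqrt(2 / 4000)))
  # the W1 reference is the shift norm, invariant under rotation of the shift
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(sqrt(sum((R %*% c(4, 0))^2)), 4)
})

test_that("overexpression simulator upregulates eligible features", {
  X <- make_expression_matrix(1000, d = 48, seed = 9)
  sim <- simulate_overexpression(X, n_genes = 5, fold = 2, expr_frac = 0.6,
                                 seed = 10)
  expect_length(sim$genes, 5L)
  # chosen features pass the expression-fraction filter in the base matrix
  expect_true(all(colMeans(X[, sim$genes] > 0) >= 0.6))
  # the two subsets are disjoint halves of the rows
  expect_equal(nrow(sim$source) + nrow(sim$target), 1000L)
  # the true log2 fold change on the modified subset is exactly log2(fold)
  # for expression-positive cells: verify on the matched unperturbed rows
  base_target <- sim$target
  base_target[, sim$genes] <- base_target[, sim$genes] / 2
  pos <- base_target[, sim$genes] > 0
  lfc <- log2(sim$target[, sim$genes][pos] / base_target[, sim$genes][pos])
  expect_equal(unname(range(lfc)), c(1, 1))
  # non-perturbed columns are untouched
  other <- setdiff(seq_len(48), sim$genes)
  expect_equal(colMeans(sim$target[, other] > 0), colMeans(base_target[, other] > 0))
  # too few eligible genes -> error naming the threshold
  Xlow <- matrix(0, 100, 10)
  expect_error(simulate_overexpression(Xlow, n_genes = 5), "60%")
})
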