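test_that("dual_loss is the empirical dual objective", {
  net <- lipschitz_potential(2, hidden = c(8L, 8L), group_size = 4L, seed = 4)
  set.seed(8)
  bx <- matrix(rnorm(20), 10, 2)
  by <- matrix(rnorm(20), 10, 2) + 2
  expect_equal(dual_loss(net, bx, by),
               -mean(potential_forward(net, bx)) +
                 mean(potential_forward(net, by)))
  # identical batches cancel exactly, for any potential
  expect_equal(dual_loss(net, bx, bx), 0)
  # point masses under the affine potential f(x) = x1: loss = y1 - x1, and
  # the dual estimate never exceeds the distance (weak duality)
  aff <- affine_potential(d = 2)
  x0 <- c(0, 0)
  y0 <- c(4, 0)
  expect_equal(dual_loss(aff, rbind(x0), rbind(y0)), 4)
  expect_lte(-dual_loss(aff, rbind(y0), rbind(x0)), 4) # f = x1 attains W1 here
  expect_error(dual_loss(net, bx[0, , drop = FALSE], by), "empty|at least")
})

test_that("transport_apply implements x - eta(x) * direction", {
  aff <- affine_potential(d = 2) # grad f = e1 everywhere
  eta2 <- constant_step_size(2, 2)
  map <- transport_map(aff, eta2)
  expect_equal(transport_apply(map, rbind(c(5, 3))), rbind(c(3, 3)))
  # normalized-direction flag: e1 is already unit, same answer
  map_n <- transport_map(aff, eta2, normalize_direction = TRUE)
  expect_equal(transport_apply(map_n, rbind(c(5, 3))), rbind(c(3, 3)))
  # no step-size network -> identity map
  X <- matrix(rnorm(10), 5, 2)
  expect_identical(transport_apply(transport_map(aff), X), X)
  expect_equal(predict(map, rbind(c(5, 3))), rbind(c(3, 3)))
})

test_that("adversarial_losses computes the saturating GAN objectives", {
  aff <- affine_potential(d = 2)
  map <- transport_map(aff, constant_step_size(2, 2))
  # constant D = 0.5
  D <- mock_discriminator(2)
  losses <- adversarial_losses(D, map, rbind(c(0, 0)), rbind(c(1, 1)))
  expect_equal(unname(losses["gen"]), log(2), tolerance = 1e-12)
  expect_equal(unname(losses["disc"]), 2 * log(2), tolerance = 1e-12)
  # near-perfect separator D(x) = sigmoid(500 x1): real at x1 = 1 scores ~1,
  # transported source at x1 = -1 scores ~0 -> disc loss ~0, gen loss ~ -log(eps)
  Dsep <- mock_discriminator(2, logit_gain = 500)
  losses <- adversarial_losses(Dsep, map, rbind(c(1, 0)), rbind(c(1, 0)))
  expect_lt(unname(losses["disc"]), 1e-5)
  expect_equal(unname(losses["gen"]), -log(1e-7), tolerance = 1e-3)
})

test_that("step sizes are strictly positive everywhere", {
  pair <- make_gaussian_pair(c(2, 0), n = 200, seed = 3)
  s1 <- train_potential(pair$source, pair$target,
                        potential_training_config(iterations = 30L,
                                                  batch_size = 64L, seed = 1))
  s2 <- train_step_size(s1$potential, pair$source, pair$target,
                        gan_training_config(iterations = 30L, batch_size = 64L,
                                            hidden = c(16L, 16L), seed = 2))
  set.seed(4)
  X <- matrix(rnorm(2 * 10000, sd = 5), ncol = 2)
  expect_true(all(w1map:::.eta_forward(s2$step_size, X) > 0))
})

test_that("stage 2 leaves the potential untouched and fits are deterministic", {
  pair <- make_gaussian_pair(c(3, 0), n = 300, seed = 5)
  pcfg <- potential_training_config(iterations = 40L, batch_size = 64L,
                                    hidden = c(16L, 16L))
  gcfg <- gan_training_config(iterations = 40L, batch_size = 64L,
                              hidden = c(16L, 16L))
  fit1 <- fit_w1ot(pair$source, pair$target, pcfg, gcfg, seed = 123)
  fit2 <- fit_w1ot(pair$source, pair$target, pcfg, gcfg, seed = 123)
  # same master seed -> bit-identical traces and parameters
  expect_identical(fit1$potential_trace, fit2$potential_trace)
  expect_identical(fit1$gan_trace, fit2$gan_trace)
  expect_identical(w1map:::.potential_params(fit1$map$potential),
                   w1map:::.potential_params(fit2$map$potential))
  # different seed -> different trajectory
  fit3 <- fit_w1ot(pair$source, pair$target, pcfg, gcfg, seed = 124)
  expect_false(identical(fit1$potential_trace, fit3$potential_trace))
})

test_that("transporting a distribution onto itself stays close to identity", {
  set.seed(77)
  X <- matrix(rnorm(400), 200, 2)
  fit <- fit_w1ot(X, X,
                  potential_training_config(iterations = 150L, batch_size = 64L,
                                            hidden = c(16L, 16L)),
                  gan_training_config(iterations = 300L, batch_size = 64L,
                                      hidden = c(16L, 16L)),
                  seed = 9)
  # the dual estimate of W1(mu, mu) is ~0
  expect_lt(abs(fit$w1_estimate), 0.15)
  TX <- transport_apply(fit$map, X)
  expect_lt(as.numeric(mmd_rbf(TX, X)), 0.05)
})

test_that("configs validate their arguments", {
  expect_error(potential_training_config(iterations = 0L))
  expect_error(gan_training_config(lr = -1))
  expect_error(autoencoder_config(val_fraction = 0))
})
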