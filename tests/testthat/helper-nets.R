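# Shared fixtures and small oracles for the test suite. Everything is
# generated in code under fixed seeds; nothing is read from disk.

# Central finite-difference gradient of the potential at the rows of X.
fd_gradient <- function(net, X, h = 1e-5) {
  d <- ncol(X)
  out <- matrix(0, nrow(X), d)
  for (k in seq_len(d)) {
    E <- matrix(0, nrow(X), d)
    E[, k] <- h
    out[, k] <- (potential_forward(net, X + E) -
                   potential_forward(net, X - E)) / (2 * h)
  }
  out
}

# Double-loop kernel-sum oracle for the biased squared-MMD estimator.
mmd_oracle <- function(X, Y, gammas) {
  k <- function(a, b, g) exp(-g * sum((a - b)^2))
  mean(vapply(gammas, function(g) {
    kxx <- mean(outer(seq_len(nrow(X)), seq_len(nrow(X)),
                      Vectorize(function(i, j) k(X[i, ], X[j, ], g))))
    kyy <- mean(outer(seq_len(nrow(Y)), seq_len(nrow(Y)),
                      Vectorize(function(i, j) k(Y[i, ], Y[j, ], g))))
    kxy <- mean(outer(seq_len(nrow(X)), seq_len(nrow(Y)),
                      Vectorize(function(i, j) k(X[i, ], Y[j, ], g))))
    kxx + kyy - 2 * kxy
  }, numeric(1)))
}

# An exactly affine potential f(x) = w . x + b: with group size 1 (GroupSort
# degenerates to the identity) and all raw parameters zero the Cayley
# parameterization gives identity weights, so the network computes x[1] plus
# biases. Optionally rotated by writing a raw parameter into layer 1.
affine_potential <- function(d = 2L, bias = 0) {
  net <- lipschitz_potential(d, hidden = d, group_size = 1L, seed = 1L)
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$raw[] <- 0
    net$layers[[l]]$bias[] <- 0
  }
  net$layers[[2]]$bias[] <- bias
  w1map:::.potential_refresh(net)
}

# A mock step-size network returning a constant value: all weights zero, the
# final bias set to the softplus inverse of the constant.
constant_step_size <- function(d, value, hidden = c(8L, 8L)) {
  net <- w1map:::.mlp_new(c(d, hidden, 1L), seed = 1L)
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W[] <- 0
    net$layers[[l]]$b[] <- 0
  }
  net$layers[[length(net$layers)]]$b <- log(exp(value) - 1) # softplus inverse
  structure(list(net = net), class = "step_size_network")
}

# A constant-probability discriminator (all-zero weights -> logit 0 -> 0.5),
# or with `logit_gain` a 1-d separator D(x) = sigmoid(gain * x[1]).
mock_discriminator <- function(d, logit_gain = NULL) {
  net <- w1map:::.mlp_new(c(d, 2L, 1L), seed = 1L)
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W[] <- 0
    net$layers[[l]]$b[] <- 0
  }
  if (!is.null(logit_gain)) {
    net$layers[[1]]$W[1, 1] <- 1
    net$layers[[1]]$W[2, 1] <- -1
    net$layers[[2]]$W[1, ] <- c(logit_gain, -logit_gain)
  }
  structure(list(net = net), class = "discriminator_network")
}
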