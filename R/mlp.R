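# Plain fully-connected network with ReLU hidden activations and manual
# reverse-mode differentiation. Used for the step-size network, the GAN
# discriminator and the autoencoder halves -- none of which need the
# Lipschitz machinery. Parameters: per-layer list(W out x in, b).

.mlp_new <- function(dims, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(dims) - 1L
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    # He initialization for the ReLU hiddens
    layers[[l]] <- list(
      W = matrix(stats::rnorm(dims[l + 1L] * dims[l], sd = sqrt(2 / dims[l])),
                 dims[l + 1L], dims[l]),
      b = numeric(dims[l + 1L])
    )
  }
  structure(list(layers = layers, dims = dims), class = "w1map_mlp")
}

# Forward with cache; output layer is linear (any squashing applied by caller).
.mlp_forward_cache <- function(net, X) {
  n <- nrow(X)
  L <- length(net$layers)
  H <- X
  inputs <- vector("list", L)
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    lay <- net$layers[[l]]
    inputs[[l]] <- H
    Z <- H %*% t(lay$W) + rep(lay$b, each = n)
    if (l < L) {
      masks[[l]] <- Z > 0
      H <- Z * masks[[l]]
    } else {
      H <- Z
    }
  }
  list(out = H, inputs = inputs, masks = masks)
}

.mlp_forward <- function(net, X) .mlp_forward_cache(net, X)$out

# Returns parameter grads and dL/dX given upstream dL/d(out).
.mlp_backward <- function(net, cache, G) {
  L <- length(net$layers)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    if (l < L) G <- G * cache$masks[[l]]
    grads[[l]] <- list(
      W = crossprod(G, cache$inputs[[l]]),
      b = colSums(G)
    )
    G <- G %*% net$layers[[l]]$W
  }
  list(grads = grads, g_input = G)
}

# ---- Adam -------------------------------------------------------------------

# `params` is any nested list of numeric arrays; state mirrors its shape.
.adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L,
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       weight_decay = weight_decay)
}

# One Adam step; returns list(params, state). `lr` overrides the stored rate
# (used for schedules). Weight decay is classic L2 added to the gradient.
.adam_step <- function(state, params, grads, lr = NULL) {
  if (is.null(lr)) lr <- state$lr
  state$t <- state$t + 1L
  b1 <- state$beta1
  b2 <- state$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  wd <- state$weight_decay
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(step, p, g, m, v, SIMPLIFY = FALSE)
      return(list(
        p = lapply(out, `[[`, "p"),
        m = lapply(out, `[[`, "m"),
        v = lapply(out, `[[`, "v")
      ))
    }
    if (wd > 0) g <- g + wd * p
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + state$eps)
    list(p = p, m = m, v = v)
  }
  out <- step(params, grads, state$m, state$v)
  state$m <- out$m
  state$v <- out$v
  list(params = out$p, state = state)
}

# Cosine annealing from lr_max to lr_min over `total` steps.
.cosine_lr <- function(step, total, lr_max, lr_min) {
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * min(step, total) / total))
}

.softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Deterministic 32-bit sub-seed derivation from a master seed.
.derive_seed <- function(seed, salt) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.double(seed) * 48271 + 1103515245 * salt) %% 2147483647)
}
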