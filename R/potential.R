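#' Construct a 1-Lipschitz GroupSort potential network
#'
#' Builds the Kantorovich potential \eqn{f_\theta : R^d \to R} as a
#' feed-forward network whose every layer is non-expansive: linear maps use
#' orthonormal (spectral norm 1) weight matrices obtained from an
#' unconstrained raw parameter through the Cayley transform (default) or
#' Björck iterations, and the activation is [groupsort()], whose Jacobian is a
#' permutation matrix. The composition is therefore 1-Lipschitz for *any*
#' parameter setting, and its input-output gradient norm is preserved layer by
#' layer — at the dual optimum the gradient norm is 1 almost everywhere, and
#' this architecture can actually attain that.
#'
#' Rectangular layers (input dimension `d` or the final scalar output differ
#' from the hidden width): the Cayley transform produces square orthogonal
#' matrices only, so a square orthogonal matrix of size `max(in, out)` is
#' built and its leading `out` rows / `in` columns are taken. Since one of the
#' two dimensions is always the full square size, the slice is exactly
#' semi-orthogonal (the Gram matrix of the smaller dimension is the identity),
#' which preserves the non-expansiveness guarantee with a single mechanism for
#' all shapes.
#'
#' Orthonormalization is a *parameterization*, not a projection: it is
#' re-applied from the raw parameters after every optimizer step, so the
#' constraint holds exactly at all times. Bias vectors are unconstrained
#' (translations are 1-Lipschitz).
#'
#' @param input_dim Input dimension `d`.
#' @param hidden Integer vector of hidden widths; default `c(64, 64, 64, 64)`.
#'   Every width must be divisible by `group_size`.
#' @param group_size GroupSort group width; default 4.
#' @param method `"cayley"` (fast, default) or `"bjorck"` (high precision).
#' @param bjorck_iterations Iterations for the Björck route.
#' @param init_sd Standard deviation of the raw-parameter initialization.
#' @param seed Optional integer seed for reproducible initialization.
#' @return An object of class `lipschitz_potential`.
#' @seealso [potential_forward()], [potential_gradient()], [train_potential()]
#' @export
lipschitz_potential <- function(input_dim, hidden = c(64L, 64L, 64L, 64L),
                                group_size = 4L, method = c("cayley", "bjorck"),
                                bjorck_iterations = 15L, init_sd = NULL,
                                seed = NULL) {
  method <- match.arg(method)
  input_dim <- as.integer(input_dim)
  hidden <- as.integer(hidden)
  group_size <- as.integer(group_size)
  stopifnot(input_dim >= 1L, length(hidden) >= 1L, all(hidden >= 1L))
  bad <- hidden[hidden %% group_size != 0L]
  if (length(bad)) {
    stop("hidden widths must be divisible by the group size (", group_size,
         "); offending width(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  in_dims <- c(input_dim, hidden)
  out_dims <- c(hidden, 1L)
  layers <- vector("list", length(in_dims))
  for (l in seq_along(layers)) {
    s <- max(in_dims[l], out_dims[l])
    sd_l <- if (is.null(init_sd)) 1 / sqrt(s) else init_sd
    layers[[l]] <- list(
      raw = matrix(stats::rnorm(s * s, sd = sd_l), s, s),
      bias = numeric(out_dims[l]),
      in_dim = in_dims[l],
      out_dim = out_dims[l],
      size = s
    )
  }
  net <- structure(
    list(layers = layers, input_dim = input_dim, hidden = hidden,
         group_size = group_size, method = method,
         bjorck_iterations = as.integer(bjorck_iterations)),
    class = "lipschitz_potential"
  )
  .potential_refresh(net)
}

#' @export
print.lipschitz_potential <- function(x, ...) {
  cat("<lipschitz_potential> ", x$input_dim, " -> [",
      paste(x$hidden, collapse = ", "), "] -> 1; GroupSort(",
      x$group_size, "), ", x$method, " orthonormalization\n", sep = "")
  invisible(x)
}

# Recompute the cached orthonormal weight (and Cayley factor B / Bjorck
# iterates) of every layer from its raw parameters. Called at construction and
# after every optimizer step.
.potential_refresh <- function(net) {
  for (l in seq_along(net$layers)) {
    lay <- net$layers[[l]]
    if (net$method == "cayley") {
      fac <- .cayley_factors(lay$raw)
      Q <- fac$W
      lay$B <- fac$B
    } else {
      cache <- .bjorck_cache(lay$raw, iterations = net$bjorck_iterations)
      Q <- cache$W
      lay$bjorck <- cache
    }
    W <- Q[seq_len(lay$out_dim), seq_len(lay$in_dim), drop = FALSE]
    lay$Q <- Q
    lay$W <- W
    lay$tW <- t(W)
    net$layers[[l]] <- lay
  }
  net
}

#' Evaluate the potential on a batch of points
#'
#' @param net A [lipschitz_potential()].
#' @param X Numeric matrix (rows = points) or a vector treated as one point.
#' @return Numeric vector of potential values, one per row of `X`.
#' @export
potential_forward <- function(net, X) {
  .potential_forward_cache(net, .as_points(X, net$input_dim))$f
}

#' Gradient of the potential at a batch of points
#'
#' Computes \eqn{\nabla f(x_i)} for every row by reverse-mode differentiation
#' through the cached orthonormal weights and the GroupSort permutations. At
#' GroupSort tie points the (stable-sort) subgradient convention of
#' [groupsort()] applies, so the result is deterministic. Row norms are
#' bounded by 1 up to floating-point error because every layer is
#' norm-non-expanding.
#'
#' @inheritParams potential_forward
#' @return Numeric matrix of the same shape as `X`.
#' @export
potential_gradient <- function(net, X) {
  X <- .as_points(X, net$input_dim)
  cache <- .potential_forward_cache(net, X)
  .potential_backward_input(net, cache, rep(1, nrow(X)))
}

.as_points <- function(X, d = NULL) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  storage.mode(X) <- "double"
  if (!is.null(d) && ncol(X) != d) {
    stop("input has ", ncol(X), " columns but the network expects ", d)
  }
  X
}

# Forward pass keeping the per-layer inputs and GroupSort permutations.
.potential_forward_cache <- function(net, X) {
  n <- nrow(X)
  L <- length(net$layers)
  H <- X
  inputs <- vector("list", L)
  perms <- vector("list", L)
  g <- net$group_size
  for (l in seq_len(L)) {
    lay <- net$layers[[l]]
    inputs[[l]] <- H
    Z <- H %*% lay$tW + rep(lay$bias, each = n)
    if (l < L) {
      gs <- .groupsort_rows(Z, g)
      H <- gs$values
      perms[[l]] <- gs$perm
    } else {
      H <- Z
    }
  }
  list(f = drop(H), inputs = inputs, perms = perms)
}

# dL/dX given upstream dL/df (a length-n vector v).
.potential_backward_input <- function(net, cache, v) {
  L <- length(net$layers)
  g <- net$group_size
  G <- matrix(v, ncol = 1L)
  for (l in rev(seq_len(L))) {
    if (l < L) G <- .groupsort_backward(G, cache$perms[[l]], g)
    G <- G %*% net$layers[[l]]$W
  }
  G
}

# Parameter gradients given upstream dL/df. Returns per-layer list with
# g_raw (through the orthonormal parameterization, including the slice
# embedding for rectangular layers) and g_bias.
.potential_backward_params <- function(net, cache, v) {
  L <- length(net$layers)
  g <- net$group_size
  G <- matrix(v, ncol = 1L)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    if (l < L) G <- .groupsort_backward(G, cache$perms[[l]], g)
    lay <- net$layers[[l]]
    gW <- crossprod(G, cache$inputs[[l]]) # out x in
    g_bias <- colSums(G)
    # embed the slice gradient into the full square matrix
    gQ <- matrix(0, lay$size, lay$size)
    gQ[seq_len(lay$out_dim), seq_len(lay$in_dim)] <- gW
    g_raw <- if (net$method == "cayley") {
      .cayley_backward(gQ, lay$Q, lay$B)
    } else {
      .bjorck_backward(gQ, lay$bjorck)
    }
    grads[[l]] <- list(raw = g_raw, bias = g_bias)
    if (l > 1L) G <- G %*% lay$W
  }
  grads
}
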