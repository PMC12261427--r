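# Reference predictors: identity, observed, and the balanced mean-shift
# (scGen-style latent arithmetic reduced to its essential operation).

#' Equalize the sizes of two samples
#'
#' Subsamples the larger of the two matrices, without replacement, down to the
#' row count of the smaller one. Used before fitting the mean-shift baseline
#' so that neither condition dominates the displacement estimate.
#'
#' @param A,B Numeric matrices with at least one row each.
#' @param seed Optional integer seed.
#' @return List with elements `A` and `B` of equal row counts; the subsample
#'   is always a subset of the original rows.
#' @export
balance_samples <- function(A, B, seed = NULL) {
  A <- .as_points(A)
  B <- .as_points(B)
  if (!is.null(seed)) set.seed(seed)
  m <- min(nrow(A), nrow(B))
  if (nrow(A) > m) A <- A[sample.int(nrow(A), m), , drop = FALSE]
  if (nrow(B) > m) B <- B[sample.int(nrow(B), m), , drop = FALSE]
  list(A = A, B = B)
}

#' Fit the balanced mean-shift baseline
#'
#' Computes the displacement between the means of the (balanced) target and
#' source samples, \eqn{\delta = \bar{y} - \bar{x}}, to be applied uniformly
#' as the predicted transport. On the balanced training sets the shifted
#' source mean matches the target mean to machine precision. The baseline can
#' operate in the ambient feature space or, for high-dimensional expression
#' data, in an autoencoder latent space (see [mean_shift_latent_predict()]).
#'
#' @param mu,nu Source / target [empirical_distribution()]s or matrices.
#' @param seed Seed for the balancing subsample.
#' @param space Informational tag, `"ambient"` or `"latent"`.
#' @return An object of class `mean_shift_model` with the shift vector
#'   `delta`.
#' @export
mean_shift_fit <- function(mu, nu, seed = NULL, space = c("ambient", "latent")) {
  space <- match.arg(space)
  X <- .dist_points(mu)
  Y <- .dist_points(nu)
  if (ncol(X) != ncol(Y)) stop("source and target dimensions differ")
  bal <- balance_samples(X, Y, seed = seed)
  structure(list(delta = colMeans(bal$B) - colMeans(bal$A), space = space),
            class = "mean_shift_model")
}

#' Apply a mean-shift model
#'
#' Translates every row of `X` by the fitted shift; a rigid translation, so
#' all within-cloud pairwise distances are preserved exactly.
#'
#' @param model A [mean_shift_fit()] result.
#' @param X Points to transport.
#' @return Shifted matrix.
#' @export
mean_shift_predict <- function(model, X) {
  X <- .as_points(X)
  if (ncol(X) != length(model$delta)) stop("dimension mismatch")
  X + rep(model$delta, each = nrow(X))
}

#' Mean shift in an autoencoder latent space
#'
#' Encodes source and target, fits the balanced mean shift on the latent
#' codes, applies it to the encoded query points, and decodes back: the
#' scGen-style predictor for high-dimensional expression data.
#'
#' @param ae A trained [train_autoencoder()] model.
#' @param mu,nu Training source / target matrices (ambient space).
#' @param X Query points (ambient space).
#' @param seed Seed for balancing.
#' @return Decoded predictions with the dimensionality of `X`.
#' @export
mean_shift_latent_predict <- function(ae, mu, nu, X, seed = NULL) {
  model <- mean_shift_fit(encode(ae, .dist_points(mu)),
                          encode(ae, .dist_points(nu)),
                          seed = seed, space = "latent")
  decode(ae, mean_shift_predict(model, encode(ae, .as_points(X))))
}

#' Identity baseline
#'
#' Returns its input unchanged: the lower-bound predictor in which no
#' perturbation response is modeled.
#'
#' @param X Points.
#' @return `X`, bit-identical.
#' @export
identity_predict <- function(X) X

#' Observed baseline
#'
#' Uses the training-set target sample itself as the prediction — the
#' practical upper bound any generative predictor is compared against.
#'
#' @param nu_train Target training sample ([empirical_distribution()] or
#'   matrix).
#' @return The target points.
#' @export
observed_baseline <- function(nu_train) .dist_points(nu_train)
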