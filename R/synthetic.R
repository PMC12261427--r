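# Toy-data generators. Every generator is a pure function of its parameters
# and seed: two calls with the same arguments return bit-identical objects.

.toy_pair <- function(source, target, source_labels = NULL,
                      target_labels = NULL, markers = NULL, seed = NULL) {
  structure(list(
    source = empirical_distribution(source, source_labels),
    target = empirical_distribution(target, target_labels),
    markers = markers, seed = seed
  ), class = "toy_pair")
}

#' @export
print.toy_pair <- function(x, ...) {
  cat("<toy_pair> source ", nrow(x$source$points), " x ", ncol(x$source$points),
      ", target ", nrow(x$target$points), " x ", ncol(x$target$points),
      if (!is.null(x$markers)) paste0(", ", length(x$markers), " markers") else "",
      "\n", sep = "")
  invisible(x)
}

#' Bookshelf dataset: two narrow parallel strips
#'
#' The collinear 1-D stress test for monotonicity. Source points have
#' x-values uniform on \[0, 1\] and y-values normal with standard deviation
#' 0.001 around zero; target points are identical in law but with x uniform
#' on \[2, 3\]. The ideal strips are a pure translation by 2, so the exact
#' Wasserstein-1 distance between them is 2. Five marker points are placed at
#' the 10/30/50/70/90% quantiles of the source x-values so that order
#' preservation after transport can be checked.
#'
#' @param n Points per strip.
#' @param seed Optional integer seed.
#' @return A `toy_pair` with a `markers` field of 5 source row indices.
#' @export
make_bookshelf <- function(n = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  src <- cbind(x = stats::runif(n, 0, 1), y = stats::rnorm(n, 0, 0.001))
  tgt <- cbind(x = stats::runif(n, 2, 3), y = stats::rnorm(n, 0, 0.001))
  q <- stats::quantile(src[, 1], probs = c(0.1, 0.3, 0.5, 0.7, 0.9))
  markers <- vapply(q, function(v) which.min(abs(src[, 1] - v)), integer(1))
  .toy_pair(src, tgt, markers = unname(markers), seed = seed)
}

#' Concentric-circles dataset: four rings
#'
#' Source points lie on two concentric circles (radii 0.5 and 1.0 by
#' default); target points lie on the same two circles scaled by
#' `target_scale` (default 4, giving radii 2 and 4). Gaussian noise is added
#' to both coordinates. Ring membership labels (`"inner"`/`"outer"`) are
#' retained so cross-ring transport can be detected: a monotone map sends the
#' inner source ring to the inner target ring.
#'
#' @param n Total points per cloud (split evenly between rings).
#' @param noise Standard deviation of the additive Gaussian noise.
#' @param radii The two source radii.
#' @param target_scale Multiplicative factor between source and target radii.
#' @param seed Optional integer seed.
#' @return A `toy_pair` with ring labels on both clouds.
#' @export
make_circles_pair <- function(n = 1000L, noise = 0.05, radii = c(0.5, 1.0),
                              target_scale = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ring_cloud <- function(radii, noise) {
    n_in <- n %/% 2L
    n_out <- n - n_in
    theta <- stats::runif(n, 0, 2 * pi)
    r <- c(rep(radii[1], n_in), rep(radii[2], n_out))
    pts <- cbind(x = r * cos(theta), y = r * sin(theta))
    if (noise > 0) pts <- pts + matrix(stats::rnorm(2 * n, 0, noise), n, 2)
    list(pts = pts, labels = c(rep("inner", n_in), rep("outer", n_out)))
  }
  src <- ring_cloud(radii, noise)
  tgt <- ring_cloud(radii * target_scale, noise)
  .toy_pair(src$pts, tgt$pts, src$labels, tgt$labels, seed = seed)
}

#' Swiss-roll dataset: Gaussian source, spiral target
#'
#' The nonlinearity stress test. The source is a standard 2D Gaussian; the
#' target takes the (x, z) coordinates of the classic 3D swiss roll
#' \eqn{(t\cos t,\; y,\; t\sin t)} with \eqn{t = 1.5\pi(1 + 2u)},
#' \eqn{u \sim U(0,1)}, scaled by `scale` (default 0.1) so the spiral has an
#' extent comparable to the Gaussian, plus Gaussian noise in the scaled
#' (data) coordinates.
#'
#' @param n Points per cloud.
#' @param noise Standard deviation of the additive noise, in data units
#'   (applied after scaling, like the other generators).
#' @param scale Multiplier applied to the spiral coordinates.
#' @param seed Optional integer seed.
#' @return A `toy_pair`.
#' @export
make_swiss_roll_pair <- function(n = 2000L, noise = 0.05, scale = 0.1,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  src <- matrix(stats::rnorm(2 * n), n, 2, dimnames = list(NULL, c("x", "y")))
  t <- 1.5 * pi * (1 + 2 * stats::runif(n))
  tgt <- cbind(x = t * cos(t), y = t * sin(t)) * scale
  if (noise > 0) tgt <- tgt + matrix(stats::rnorm(2 * n, 0, noise), n, 2)
  .toy_pair(src, tgt, seed = seed)
}

#' Moons dataset: two interleaving half-circles
#'
#' The source cloud is the upper half-circle \eqn{(\cos t, \sin t)},
#' \eqn{t \in [0, \pi]}; the target is the interleaved lower half-circle
#' \eqn{(1 - \cos t,\; 0.5 - \sin t)}, each with additive Gaussian noise.
#'
#' @param n Points per moon.
#' @param noise Standard deviation of the additive noise.
#' @param seed Optional integer seed.
#' @return A `toy_pair` with moon labels (`"upper"` source, `"lower"` target).
#' @export
make_moons_pair <- function(n = 1000L, noise = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t1 <- stats::runif(n, 0, pi)
  src <- cbind(x = cos(t1), y = sin(t1))
  t2 <- stats::runif(n, 0, pi)
  tgt <- cbind(x = 1 - cos(t2), y = 0.5 - sin(t2))
  if (noise > 0) {
    src <- src + matrix(stats::rnorm(2 * n, 0, noise), n, 2)
    tgt <- tgt + matrix(stats::rnorm(2 * n, 0, noise), n, 2)
  }
  .toy_pair(src, tgt, rep("upper", n), rep("lower", n), seed = seed)
}

#' Translated Gaussian pair with known Wasserstein-1 distance
#'
#' Both clouds are unit-covariance Gaussians; the target mean is the source
#' mean plus `shift`. For a pure translation the optimal transport map is the
#' translation itself and \eqn{W_1 = \lVert \mathrm{shift} \rVert}, giving a
#' closed-form reference for solver validation.
#'
#' @param shift Numeric shift vector (its length sets the dimension unless
#'   `d` is given).
#' @param n Points per cloud.
#' @param d Dimension; defaults to `length(shift)`.
#' @param seed Optional integer seed.
#' @return A `toy_pair`.
#' @export
make_gaussian_pair <- function(shift, n = 1000L, d = length(shift),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shift <- rep_len(as.numeric(shift), d)
  src <- matrix(stats::rnorm(n * d), n, d)
  tgt <- matrix(stats::rnorm(n * d), n, d) + rep(shift, each = n)
  .toy_pair(src, tgt, seed = seed)
}

#' Synthetic positive expression-feature matrix
#'
#' Generates an `n x d` matrix emulating de-duplicated single-cell imaging
#' intensity features: per-feature log-normal baseline levels, log-normal
#' cell-to-cell variation, and per-feature dropout (exact zeros) with
#' probability uniform on \[0, `max_dropout`\], so features differ in the
#' fraction of cells expressing them. This is the substrate for
#' [simulate_overexpression()]; it does not emulate count noise of scRNA-seq.
#'
#' @param n Number of cells.
#' @param d Number of features (default 48).
#' @param max_dropout Upper bound of the per-feature dropout probability.
#' @param seed Optional integer seed.
#' @return Numeric matrix with non-negative entries.
#' @export
make_expression_matrix <- function(n = 2000L, d = 48L, max_dropout = 0.5,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- exp(stats::rnorm(d, 0, 0.6))
  drop_p <- stats::runif(d, 0, max_dropout)
  X <- matrix(stats::rlnorm(n * d, meanlog = rep(log(base), each = n),
                            sdlog = 0.4), n, d)
  mask <- matrix(stats::runif(n * d) < rep(drop_p, each = n), n, d)
  X[mask] <- 0
  X
}

#' Simulate an overexpression perturbation
#'
#' Emulates a fold-change upregulation experiment: among features expressed
#' (value > 0) in at least `expr_frac` of cells, `n_genes` are chosen at
#' random; the cells are split into two disjoint halves at random, and in the
#' second half (the "perturbed" subset) the chosen features are multiplied by
#' `fold`. The unperturbed and perturbed subsets serve as source and target
#' for training a predictor, and the returned gene indices are the ground
#' truth for log fold-change evaluation (for expression-positive cells a
#' 2-fold upregulation gives a log2 fold change of exactly 1).
#'
#' @param X Non-negative `n x d` feature matrix (e.g.
#'   [make_expression_matrix()]).
#' @param n_genes Number of features to upregulate.
#' @param fold Multiplicative fold change.
#' @param expr_frac Minimum fraction of cells in which an eligible feature
#'   must be expressed.
#' @param seed Optional integer seed.
#' @return List with `source` (unperturbed rows), `target` (perturbed rows),
#'   and `genes` (indices of the upregulated features).
#' @export
simulate_overexpression <- function(X, n_genes = 5L, fold = 2, expr_frac = 0.6,
                                    seed = NULL) {
  X <- .as_points(X)
  if (!is.null(seed)) set.seed(seed)
  eligible <- which(colMeans(X > 0) >= expr_frac)
  if (length(eligible) < n_genes) {
    stop("only ", length(eligible), " feature(s) are expressed in at least ",
         round(100 * expr_frac), "% of cells; need ", n_genes)
  }
  genes <- sort(sample(eligible, n_genes))
  idx <- sample.int(nrow(X))
  half <- nrow(X) %/% 2L
  src <- X[idx[seq_len(half)], , drop = FALSE]
  tgt <- X[idx[(half + 1L):nrow(X)], , drop = FALSE]
  tgt[, genes] <- tgt[, genes] * fold
  list(source = src, target = tgt, genes = genes)
}
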