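#' Multi-scale RBF maximum mean discrepancy
#'
#' Biased (V-statistic) estimator of the squared maximum mean discrepancy
#' under the Gaussian kernel \eqn{k(x, y) = \exp(-\gamma \lVert x-y\rVert^2)},
#' \deqn{\widehat{MMD}^2 = \overline{K_{XX}} + \overline{K_{YY}} - 2\overline{K_{XY}},}
#' averaged over a list of kernel scales \eqn{\gamma}. By default the scales
#' are derived from the median-pairwise-distance heuristic: with `med` the
#' median Euclidean distance on the pooled sample,
#' \eqn{\gamma_s = 1 / (2 (s \cdot med)^2)} for the length-scale multipliers
#' `s` in `scale_multipliers`. The result is symmetric in `X` and `Y`,
#' non-negative, and exactly 0 when the two inputs are identical multisets.
#' The scales actually used are attached as attribute `"scales"`.
#'
#' @param X,Y Numeric matrices with equal column counts and at least one row
#'   each (two rows each for the default scale heuristic to be meaningful).
#' @param scales Optional numeric vector of kernel precisions \eqn{\gamma};
#'   overrides the heuristic.
#' @param scale_multipliers Length-scale multipliers for the median heuristic.
#' @param max_heuristic_n Cap on the number of pooled rows used for the median
#'   heuristic (rows are subset deterministically, evenly spaced).
#' @return Scalar averaged squared MMD with attribute `scales`.
#' @export
mmd_rbf <- function(X, Y, scales = NULL,
                    scale_multipliers = c(2, 1, 0.5, 0.1, 0.01, 0.005),
                    max_heuristic_n = 1000L) {
  X <- .as_points(X)
  Y <- .as_points(Y)
  if (nrow(X) < 1L || nrow(Y) < 1L) stop("empty input")
  if (ncol(X) != ncol(Y)) stop("X and Y must have the same number of columns")
  if (is.null(scales)) {
    P <- rbind(X, Y)
    if (nrow(P) > max_heuristic_n) {
      P <- P[round(seq(1L, nrow(P), length.out = max_heuristic_n)), , drop = FALSE]
    }
    med <- stats::median(stats::dist(P))
    if (!is.finite(med) || med <= 0) med <- 1
    scales <- 1 / (2 * (scale_multipliers * med)^2)
  }
  Dxx <- .sqdist(X, X)
  Dyy <- .sqdist(Y, Y)
  Dxy <- .sqdist(X, Y)
  vals <- vapply(scales, function(g) {
    mean(exp(-g * Dxx)) + mean(exp(-g * Dyy)) - 2 * mean(exp(-g * Dxy))
  }, numeric(1))
  structure(mean(vals), scales = scales)
}

# Pairwise squared Euclidean distances, n x m.
.sqdist <- function(X, Y) {
  nx <- rowSums(X * X)
  ny <- rowSums(Y * Y)
  D <- outer(nx, ny, "+") - 2 * tcrossprod(X, Y)
  D[D < 0] <- 0
  D
}

#' Squared Pearson correlation of feature means
#'
#' Computes the Pearson correlation between the two d-vectors of column
#' (feature) means and returns its square, the convention used for reporting
#' the similarity of predicted and observed perturbation profiles. Note that
#' squaring makes perfectly anti-correlated mean vectors score 1; the signed
#' correlation is attached as attribute `"pearson"`. If either mean vector
#' has zero variance the correlation is undefined and `NA` is returned.
#'
#' @param X,Y Numeric matrices with equal column counts.
#' @return Scalar in \[0, 1\] (or `NA`), with attribute `pearson`.
#' @export
r2_means <- function(X, Y) {
  mx <- colMeans(.as_points(X))
  my <- colMeans(.as_points(Y))
  if (stats::sd(mx) == 0 || stats::sd(my) == 0) {
    return(structure(NA_real_, pearson = NA_real_))
  }
  r <- stats::cor(mx, my)
  structure(r^2, pearson = r)
}

#' Euclidean distance between feature-mean vectors
#'
#' @param X,Y Numeric matrices with equal column counts.
#' @return Non-negative scalar.
#' @export
l2_means <- function(X, Y) {
  mx <- colMeans(.as_points(X))
  my <- colMeans(.as_points(Y))
  if (length(mx) != length(my)) stop("column counts differ")
  sqrt(sum((mx - my)^2))
}

#' Monotonicity-violation rate of a transport map
#'
#' A map is order-preserving (monotone) when for any two points the unit
#' vectors of \eqn{x_1 - x_2} and \eqn{T(x_1) - T(x_2)} do not cancel:
#' \deqn{\frac{x_1-x_2}{\lVert x_1-x_2\rVert} + \frac{T(x_1)-T(x_2)}{\lVert T(x_1)-T(x_2)\rVert} \neq 0.}
#' This diagnostic samples (or accepts) index pairs and reports the fraction
#' whose unit-difference vectors sum to numerically zero
#' (\eqn{\lVert u+v\rVert <} `tol`), i.e. whose relative order was inverted.
#' Pairs with coincident points (in either cloud) are skipped.
#'
#' @param X Source points, `n x d`.
#' @param TX Transported points, same shape, rows corresponding to `X`.
#' @param pairs Optional 2-column integer matrix of row-index pairs; if
#'   `NULL`, `n_pairs` pairs are sampled uniformly.
#' @param n_pairs Number of sampled pairs when `pairs` is `NULL`.
#' @param tol Numerical threshold on \eqn{\lVert u+v\rVert}.
#' @param seed Optional seed for pair sampling.
#' @return Fraction in \[0, 1\].
#' @export
monotonicity_violation_rate <- function(X, TX, pairs = NULL, n_pairs = 10000L,
                                        tol = 1e-3, seed = NULL) {
  X <- .as_points(X)
  TX <- .as_points(TX)
  stopifnot(nrow(X) == nrow(TX), ncol(X) == ncol(TX))
  n <- nrow(X)
  if (is.null(pairs)) {
    if (!is.null(seed)) set.seed(seed)
    pairs <- cbind(sample.int(n, n_pairs, replace = TRUE),
                   sample.int(n, n_pairs, replace = TRUE))
  }
  dx <- X[pairs[, 1], , drop = FALSE] - X[pairs[, 2], , drop = FALSE]
  dt <- TX[pairs[, 1], , drop = FALSE] - TX[pairs[, 2], , drop = FALSE]
  nx <- sqrt(rowSums(dx * dx))
  nt <- sqrt(rowSums(dt * dt))
  keep <- nx > 1e-12 & nt > 1e-12
  if (!any(keep)) {
    return(0)
  }
  u <- dx[keep, , drop = FALSE] / nx[keep]
  v <- dt[keep, , drop = FALSE] / nt[keep]
  s <- sqrt(rowSums((u + v)^2))
  mean(s < tol)
}

#' Rank features by two-sample differential expression
#'
#' Per-feature Wilcoxon rank-sum (Mann-Whitney) comparison between a control
#' and a perturbed matrix: each feature's pooled values are ranked, the
#' rank-sum statistic is standardized under the null (with tie correction),
#' and features are ordered by decreasing absolute z-score. Ties in the score
#' are broken deterministically by feature index, so
#' `rank_de_genes(X, X, k)` returns `1:k`.
#'
#' @param control,perturbed Numeric matrices with the same `d` columns.
#' @param k Number of top features to return (`k <= d`).
#' @return Integer vector of `k` unique feature indices.
#' @export
rank_de_genes <- function(control, perturbed, k = 50L) {
  control <- .as_points(control)
  perturbed <- .as_points(perturbed)
  d <- ncol(control)
  if (ncol(perturbed) != d) stop("column counts differ")
  if (k > d) stop("k = ", k, " exceeds the number of features (", d, ")")
  n1 <- nrow(control)
  n2 <- nrow(perturbed)
  n <- n1 + n2
  z <- vapply(seq_len(d), function(j) {
    v <- c(control[, j], perturbed[, j])
    r <- rank(v)
    w <- sum(r[seq_len(n1)]) # rank sum of the control group
    mu_w <- n1 * (n + 1) / 2
    ties <- table(v)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    var_w <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (var_w <= 0) {
      return(0)
    }
    (w - mu_w) / sqrt(var_w)
  }, numeric(1))
  order(-abs(z), seq_len(d))[seq_len(k)]
}

#' Mean absolute error of log2 fold changes on selected features
#'
#' For each feature index in `gene_idx`, computes the log2 of the
#' (pseudocounted) feature mean in `predicted` and in `observed` and reports
#' the mean absolute difference. When both matrices share the same control
#' baseline this equals the mean absolute error between predicted and actual
#' log2 fold changes of the perturbed features.
#'
#' @param predicted,observed Numeric matrices with equal column counts (row
#'   counts may differ; only feature means enter).
#' @param gene_idx Integer indices of the features to evaluate.
#' @param pseudocount Added to the means before taking logs.
#' @return Non-negative scalar.
#' @export
logfc_mae <- function(predicted, observed, gene_idx, pseudocount = 1e-8) {
  mp <- colMeans(.as_points(predicted))[gene_idx]
  mo <- colMeans(.as_points(observed))[gene_idx]
  mean(abs(log2(mp + pseudocount) - log2(mo + pseudocount)))
}

#' Assemble a metrics report for one evaluation
#'
#' Computes the standard metric panel comparing a predicted cell population
#' with the observed target population: squared Pearson correlation and
#' Euclidean distance of feature means, and multi-scale RBF MMD; optionally a
#' monotonicity-violation rate (when the source and its transported image are
#' supplied) and a log fold-change error (when perturbed gene indices are
#' supplied).
#'
#' @param predicted,observed Numeric matrices (rows = cells).
#' @param source Optional source matrix whose rows correspond to `predicted`
#'   rows, enabling the monotonicity diagnostic.
#' @param gene_idx Optional perturbed-feature indices for [logfc_mae()].
#' @param mmd_scales Optional explicit MMD scales (see [mmd_rbf()]).
#' @param metadata Optional named list copied into the report.
#' @return An object of class `metrics_report` (a named list).
#' @export
metrics_report <- function(predicted, observed, source = NULL,
                           gene_idx = NULL, mmd_scales = NULL,
                           metadata = list()) {
  mmd <- mmd_rbf(predicted, observed, scales = mmd_scales)
  rep <- list(
    r2_means = as.numeric(r2_means(predicted, observed)),
    l2_means = l2_means(predicted, observed),
    mmd = as.numeric(mmd),
    mmd_scales = as.numeric(attr(mmd, "scales")),
    metadata = metadata
  )
  if (!is.null(source)) {
    rep$monotonicity_violation_rate <-
      monotonicity_violation_rate(source, predicted, seed = 1L)
  }
  if (!is.null(gene_idx)) {
    rep$logfc_mae <- logfc_mae(predicted, observed, gene_idx)
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat("  r2 of feature means: ", signif(x$r2_means, 4), "\n", sep = "")
  cat("  l2 of feature means: ", signif(x$l2_means, 4), "\n", sep = "")
  cat("  MMD (multi-scale):   ", signif(x$mmd, 4), "\n", sep = "")
  if (!is.null(x$monotonicity_violation_rate)) {
    cat("  monotonicity violations: ",
        signif(x$monotonicity_violation_rate, 4), "\n", sep = "")
  }
  if (!is.null(x$logfc_mae)) {
    cat("  logFC MAE: ", signif(x$logfc_mae, 4), "\n", sep = "")
  }
  invisible(x)
}
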