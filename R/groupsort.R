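#' GroupSort activation
#'
#' Splits a feature vector into contiguous groups of `group_size` entries and
#' sorts each group in ascending order. The Jacobian of this operation is a
#' permutation matrix, so GroupSort preserves every vector norm and, unlike
#' ReLU-style activations, does not shrink gradient norms as they
#' backpropagate — the property that lets an orthonormal-weight network
#' represent functions whose gradient norm is 1 almost everywhere.
#'
#' @param v Numeric vector whose length is divisible by `group_size`, or a
#'   matrix whose rows are treated as feature vectors.
#' @param group_size Positive integer group width.
#' @return An object of the same shape with each contiguous group sorted
#'   ascending.
#' @export
#' @examples
#' groupsort(c(3, 1, 2, 0), 2) # 1 3 0 2
#' groupsort(c(3, 1, 2, 0), 4) # 0 1 2 3
groupsort <- function(v, group_size) {
  group_size <- as.integer(group_size)
  if (group_size < 1L) stop("`group_size` must be a positive integer")
  if (is.matrix(v)) {
    if (ncol(v) %% group_size != 0L) {
      stop("width ", ncol(v), " is not divisible by group size ", group_size)
    }
    return(.groupsort_rows(v, group_size)$values)
  }
  if (length(v) %% group_size != 0L) {
    stop("length ", length(v), " is not divisible by group size ", group_size)
  }
  drop(.groupsort_rows(matrix(v, nrow = 1L), group_size)$values)
}

# Batched row-wise GroupSort. H is n x w. Returns the sorted matrix plus the
# permutation `perm` (an index vector into the g x (w/g * n) column-major
# reshape of t(H)) used to route gradients in the backward pass. `order()` is
# stable, so ties keep their original position: the subgradient convention at
# sort ties is deterministic.
.groupsort_rows <- function(H, g) {
  n <- nrow(H)
  w <- ncol(H)
  if (g == 1L || g == 0L) {
    return(list(values = H, perm = NULL))
  }
  M <- matrix(t(H), nrow = g) # column j = one group; groups vary fastest within a row
  perm <- order(rep(seq_len(ncol(M)), each = g), M)
  values <- t(matrix(M[perm], nrow = w))
  list(values = values, perm = perm)
}

# Backward: scatter dL/d(sorted) back through the permutation.
.groupsort_backward <- function(G, perm, g) {
  if (is.null(perm)) {
    return(G)
  }
  w <- ncol(G)
  Mg <- matrix(t(G), nrow = g)
  out <- numeric(length(Mg))
  out[perm] <- Mg
  t(matrix(out, nrow = w))
}
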