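## Internal helpers: argument checks, rotations, assignment, small numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

.check_seed <- function(seed) {
  .assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
          "seed must be a single finite number")
  as.integer(seed %% .Machine$integer.max)
}

## log(cosh(x)) without overflow for large |x|.
.logcosh <- function(x) {
  ax <- abs(x)
  ax + log1p(exp(-2 * ax)) - log(2)
}

#' Sample a uniform 3-D rotation matrix
#'
#' Draws from the Haar measure on SO(3) by QR-decomposing a Gaussian matrix,
#' fixing the sign convention of the R factor, and correcting the determinant
#' to +1. Uses the current RNG state; seed with [set.seed()].
#'
#' @return A 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Minimum-cost assignment between two point sets
#'
#' Solves the linear assignment problem on a square cost matrix with the
#' Hungarian method (shortest augmenting paths, O(n^3)).
#'
#' @param cost Square numeric cost matrix; entry `[i, j]` is the cost of
#'   assigning row item `i` to column item `j`.
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`;
#'   a permutation of `seq_len(nrow(cost))`.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  .assert(nrow(cost) == ncol(cost), "cost matrix must be square")
  .assert(all(is.finite(cost)), "cost matrix must be finite")
  solve_assignment_cpp(cost)
}

## Assignment-based relabelling for one centroid set under rotation Q:
## returns pi such that a null map takes value[pi[j]] at slot j.
.rotation_perm <- function(centroids, Q) {
  rotated <- centroids %*% t(Q)
  d2 <- outer(rowSums(rotated^2), rowSums(centroids^2), "+") -
    2 * tcrossprod(rotated, centroids)
  d2[d2 < 0] <- 0
  a <- solve_assignment(sqrt(d2))   # rotated i -> original slot a[i]
  pi_ <- integer(length(a))
  pi_[a] <- seq_along(a)            # slot j receives region pi_[j]
  pi_
}

#' Spatial rotation permutations of a bilateral parcellation
#'
#' Generates region relabellings that preserve spatial autocorrelation: each
#' draw applies a uniformly random rotation to the left-hemisphere spherical
#' centroids and the mirrored rotation (x negated) to the right hemisphere,
#' then maps rotated centroids back onto original region slots by
#' minimum-total-distance assignment within hemisphere.
#'
#' @param parcellation Parcellation table from [generate_parcellation()].
#' @param n_perm Number of rotation draws.
#' @param seed Integer seed.
#' @param rotations Optional list of 3 x 3 rotation matrices to use instead of
#'   random draws (e.g. `list(diag(3))` for the identity; used for testing).
#' @return Integer matrix of dimension `n_perm x n_regions`; row `p` is a
#'   permutation `pi` such that the p-th null map takes the observed value of
#'   region `pi[j]` at region `j`. Within-hemisphere bijectivity is guaranteed.
#' @export
region_rotation_perms <- function(parcellation, n_perm, seed = 1,
                                  rotations = NULL) {
  .validate_parcellation(parcellation)
  n <- nrow(parcellation)
  left <- which(parcellation$hemisphere == "L")
  right <- which(parcellation$hemisphere == "R")
  cl <- as.matrix(parcellation[left, c("cx", "cy", "cz")])
  cr <- as.matrix(parcellation[right, c("cx", "cy", "cz")])
  M <- diag(c(-1, 1, 1))
  if (!is.null(rotations)) {
    n_perm <- length(rotations)
  } else {
    set.seed(.check_seed(seed))
  }
  out <- matrix(NA_integer_, n_perm, n)
  for (p in seq_len(n_perm)) {
    Q <- if (is.null(rotations)) random_rotation() else rotations[[p]]
    out[p, left] <- left[.rotation_perm(cl, Q)]
    out[p, right] <- right[.rotation_perm(cr, M %*% Q %*% M)]
  }
  out
}

## Empirical p-value with the +1 correction.
.perm_p <- function(null_geq_obs, n_perm) (1 + null_geq_obs) / (n_perm + 1)

## Cohen's d with the severity orientation: less severe minus more severe,
## divided by the pooled standard deviation.
.cohens_d <- function(x_less, x_more) {
  n1 <- length(x_less); n2 <- length(x_more)
  sp2 <- ((n1 - 1) * var(x_less) + (n2 - 1) * var(x_more)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) return(NA_real_)
  (mean(x_less) - mean(x_more)) / sqrt(sp2)
}
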