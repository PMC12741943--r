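## Spatial decoding: correlation of group-average deviation maps with
## regional reference maps (e.g. receptor density), with spin-permutation
## significance that respects spatial autocorrelation. The rotated object
## is always the deviation map; the reference map is held fixed.

#' Bilaterally average a regional map
#'
#' Pairs each left-hemisphere region with its right-hemisphere homologue
#' and averages their values, yielding one value per bilateral region pair.
#'
#' @param x Named numeric vector of per-region values in parcellation order
#'   (names are region ids) or an unnamed vector of length `n_regions`.
#' @param parcellation Parcellation with homologue pairing.
#' @return Numeric vector of length `n_regions / 2`, named by the left
#'   region id of each pair.
#' @export
bilateral_average <- function(x, parcellation) {
  .validate_parcellation(parcellation)
  n <- nrow(parcellation)
  .assert(length(x) == n, "x must have one value per region")
  ids <- if (is.null(names(x))) parcellation$region_id else
    as.integer(names(x))
  .assert(all(sort(ids) == seq_len(n)), "region ids do not match parcellation")
  v <- x[match(seq_len(n), ids)]
  left <- parcellation$region_id[parcellation$hemisphere == "L"]
  hom <- parcellation$homologue_id[match(left, parcellation$region_id)]
  .assert(all(parcellation$hemisphere[match(hom, parcellation$region_id)] ==
                "R"), "unpaired or mis-paired region(s)")
  out <- (v[left] + v[hom]) / 2
  names(out) <- left
  out
}

## Rotation-assignment permutations for a single (bilateral) centroid set.
.bilateral_spin_perms <- function(centroids, n_perm, seed, rotations = NULL) {
  if (!is.null(rotations)) n_perm <- length(rotations) else
    set.seed(.check_seed(seed))
  out <- matrix(NA_integer_, n_perm, nrow(centroids))
  for (p in seq_len(n_perm)) {
    Q <- if (is.null(rotations)) random_rotation() else rotations[[p]]
    out[p, ] <- .rotation_perm(centroids, Q)
  }
  out
}

#' Spin-permutation correlation between two bilateral maps
#'
#' Pearson correlation between a (bilaterally averaged) deviation map and a
#' reference map, with a two-tailed empirical p-value from rotation nulls:
#' each draw rotates the bilateral centroids, relabels the deviation map by
#' Hungarian assignment, and recomputes the correlation against the fixed
#' reference map.
#'
#' @param map_a Deviation map: numeric vector, one value per bilateral
#'   region (this is the map that gets rotated).
#' @param map_b Reference map, same regions and order.
#' @param centroids Matrix (`length(map_a)` x 3) of unit-sphere centroids
#'   for the bilateral regions (conventionally the left-hemisphere centroid
#'   of each pair).
#' @param n_perm Number of spins (default 5000).
#' @param seed Integer seed.
#' @param rotations Optional fixed rotation list (testing).
#' @return List of class `spin_test`: `r`, `p`, `n_perm`, `null_r`.
#' @export
spin_correlation <- function(map_a, map_b, centroids, n_perm = 5000,
                             seed = 1, rotations = NULL) {
  .assert(length(map_a) == length(map_b),
          "maps must cover the same regions")
  .assert(is.matrix(centroids) && nrow(centroids) == length(map_a) &&
            ncol(centroids) == 3, "centroids must be an n x 3 matrix")
  .assert(all(is.finite(map_a)) && all(is.finite(map_b)),
          "maps must be finite")
  .assert(sd(map_a) > 0 && sd(map_b) > 0,
          "zero-variance map supplied")
  r_obs <- cor(map_a, map_b)
  perms <- .bilateral_spin_perms(centroids, n_perm, seed, rotations)
  n_perm <- nrow(perms)
  null_r <- vapply(seq_len(n_perm),
                   function(p) cor(map_a[perms[p, ]], map_b), numeric(1))
  p <- .perm_p(sum(abs(null_r) >= abs(r_obs)), n_perm)
  structure(list(r = r_obs, p = p, n_perm = n_perm, null_r = null_r),
            class = "spin_test")
}

#' @export
print.spin_test <- function(x, ...) {
  cat(sprintf("Spin test: r = %.3f, p = %.4f (%d rotations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}

#' Generate smooth synthetic reference maps
#'
#' Draws bilateral regional reference maps (synthetic stand-ins for, e.g.,
#' receptor-density maps) from a Gaussian process on the left-hemisphere
#' centroids with exponentially distance-decaying covariance, so their
#' spatial autocorrelation is tunable.
#'
#' @param parcellation Parcellation table.
#' @param n_maps Number of maps (default 4).
#' @param length_scale Correlation length on the unit sphere (chord
#'   distance; default 0.8).
#' @param seed Integer seed.
#' @return Matrix (`n_regions / 2` x `n_maps`), rownames the left region
#'   ids, colnames `synthmap_1`, `synthmap_2`, ...
#' @export
generate_reference_maps <- function(parcellation, n_maps = 4,
                                    length_scale = 0.8, seed = 1) {
  .validate_parcellation(parcellation)
  .assert(length_scale > 0, "length_scale must be positive")
  set.seed(.check_seed(seed))
  left <- parcellation[parcellation$hemisphere == "L", ]
  C <- as.matrix(left[, c("cx", "cy", "cz")])
  d2 <- outer(rowSums(C^2), rowSums(C^2), "+") - 2 * tcrossprod(C)
  d2[d2 < 0] <- 0
  K <- exp(-sqrt(d2) / length_scale) + diag(1e-8, nrow(C))
  L <- chol(K)
  maps <- crossprod(L, matrix(rnorm(nrow(C) * n_maps), nrow(C), n_maps))
  dimnames(maps) <- list(left$region_id,
                         paste0("synthmap_", seq_len(n_maps)))
  maps
}
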