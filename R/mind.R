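## MIND network construction: per-subject region-by-region similarity
## matrices from vertex-level morphometric features. Similarity between two
## regions is 1 / (1 + KL), with KL the symmetric Kullback-Leibler
## divergence between their multivariate vertex-feature distributions,
## estimated with a k-nearest-neighbour density-ratio estimator in the
## standardised 5-D feature space.

## Canonical ordering of two matrices (by size, then first differing value);
## TRUE when `a` should be treated first.
.arg_first <- function(a, b) {
  if (nrow(a) != nrow(b)) return(nrow(a) < nrow(b))
  d <- which(as.vector(a) != as.vector(b))
  if (length(d) == 0) return(TRUE)
  a[d[1]] < b[d[1]]
}

.validate_subject_features <- function(features, min_vertices = NULL) {
  .assert(is.list(features) && length(features) >= 2,
          "features must be a list of per-region matrices (>= 2 regions)")
  ok <- vapply(features, function(m)
    is.matrix(m) && is.numeric(m) && ncol(m) == 5, logical(1))
  .assert(all(ok), "every region must be a numeric matrix with 5 feature columns")
  .assert(all(vapply(features, function(m) all(is.finite(m)), logical(1))),
          "non-finite feature values present")
  if (!is.null(min_vertices)) {
    nv <- vapply(features, nrow, integer(1))
    if (any(nv < min_vertices))
      stop("regions below the minimum vertex count (", min_vertices, "): ",
           paste(names(features)[nv < min_vertices], collapse = ", "),
           call. = FALSE)
  }
  invisible(features)
}

#' Standardise a subject's vertex features
#'
#' Z-scores each of the five morphometric features across all cortical
#' vertices of the subject (pooled over regions, per subject), putting the
#' features on a common scale before divergence estimation.
#'
#' @param features List of vertices x 5 matrices, one per region, for one
#'   subject.
#' @return The same structure with each feature column having pooled mean 0
#'   and standard deviation 1.
#' @export
zscore_features <- function(features) {
  .validate_subject_features(features)
  pooled <- do.call(rbind, features)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, sd)
  if (any(sdv == 0))
    stop("zero-variance feature(s): ",
         paste(colnames(pooled)[sdv == 0], collapse = ", "), call. = FALSE)
  lapply(features, function(m) sweep(sweep(m, 2, mu), 2, sdv, "/"))
}

#' k-nearest-neighbour symmetric Kullback-Leibler divergence
#'
#' Estimates KL(a||b) + KL(b||a) between the multivariate distributions
#' underlying two vertex samples with the k-NN density-ratio estimator: for
#' each point the ratio of its k-th nearest-neighbour distance within its
#' own sample to that in the other sample enters a log average, with the
#' `log(m / (n - 1))` sample-size correction. Coincident points are
#' protected by a seeded Gaussian jitter of magnitude 1e-10, and negative
#' raw estimates are clipped at zero so the divergence-to-similarity
#' transform stays within its bounds. The estimate is exactly symmetric in
#' its arguments.
#'
#' @param x_a,x_b Numeric matrices (vertices x features) with the same
#'   number of columns and at least `k + 1` rows each.
#' @param k Neighbour index (default 3).
#' @param seed Seed for the anti-duplicate jitter.
#' @return A single non-negative divergence estimate.
#' @export
knn_symmetric_kl <- function(x_a, x_b, k = 3, seed = 1) {
  .assert(is.matrix(x_a) && is.matrix(x_b) && ncol(x_a) == ncol(x_b),
          "x_a and x_b must be matrices with equal column counts")
  .assert(all(is.finite(x_a)) && all(is.finite(x_b)),
          "non-finite values in input samples")
  .assert(k >= 1 && nrow(x_a) >= k + 1 && nrow(x_b) >= k + 1,
          "both samples need at least k + 1 rows")
  ## Evaluate in a canonical argument order so the estimate (and the jitter
  ## draws) are exactly symmetric under swapping x_a and x_b: floating-point
  ## matrix products are not bitwise transpose-symmetric.
  set.seed(.check_seed(seed))
  if (!.arg_first(x_a, x_b)) {
    tmp <- x_a; x_a <- x_b; x_b <- tmp
  }
  x_a <- x_a + rnorm(length(x_a)) * 1e-10
  x_b <- x_b + rnorm(length(x_b)) * 1e-10
  knn_sym_kl_cpp(x_a, x_b, as.integer(k))
}

#' Divergence-to-similarity transform
#'
#' Maps a non-negative divergence to the similarity `1 / (1 + kl)`, bounded
#' in (0, 1] and strictly decreasing in the divergence.
#'
#' @param kl Non-negative finite divergence value(s).
#' @return Similarity value(s) in (0, 1].
#' @export
mind_similarity <- function(kl) {
  .assert(is.numeric(kl) && all(is.finite(kl)) && all(kl >= 0),
          "kl must be finite and non-negative")
  1 / (1 + kl)
}

#' Build a subject's MIND similarity matrix
#'
#' Standardises the subject's features, then computes the symmetric k-NN KL
#' divergence for every unordered region pair once and transforms it to
#' similarity. The result is exactly symmetric with unit diagonal.
#'
#' @param features List of vertices x 5 matrices, one per region.
#' @param k Neighbour index (default 3).
#' @param seed Seed for the anti-duplicate jitter.
#' @param min_vertices Minimum vertices required per region (default 20).
#' @param standardise Set to `FALSE` if `features` are already pooled
#'   Z-scores.
#' @return A region x region similarity matrix, entries in (0, 1], diagonal
#'   1, dimnames taken from `names(features)`.
#' @export
build_mind_matrix <- function(features, k = 3, seed = 1, min_vertices = 20,
                              standardise = TRUE) {
  .validate_subject_features(features, min_vertices = min_vertices)
  .assert(all(vapply(features, nrow, integer(1)) >= k + 1),
          "every region needs at least k + 1 vertices")
  if (standardise) features <- zscore_features(features)
  set.seed(.check_seed(seed))
  features <- lapply(features, function(m) m + rnorm(length(m)) * 1e-10)
  S <- mind_matrix_cpp(features, as.integer(k))
  dimnames(S) <- list(names(features), names(features))
  S
}

#' Weighted degree of a MIND matrix
#'
#' The weighted degree of a region is the mean of its similarities to all
#' other regions; the (constant) self-similarity diagonal is excluded.
#'
#' @param matrix Square symmetric MIND similarity matrix.
#' @return Named numeric vector of per-region degrees in (0, 1].
#' @export
weighted_degree <- function(matrix) {
  .assert(is.matrix(matrix) && nrow(matrix) == ncol(matrix),
          "matrix must be square")
  .assert(all(is.finite(matrix)), "matrix must be finite")
  n <- nrow(matrix)
  .assert(n >= 2, "need at least two regions")
  (rowSums(matrix) - diag(matrix)) / (n - 1)
}

#' Degree table for a cohort
#'
#' Runs [build_mind_matrix()] and [weighted_degree()] for every subject of a
#' generated cohort.
#'
#' @param cohort A `mind_cohort` from [generate_cohort()] or a named list of
#'   per-subject feature lists.
#' @param k,min_vertices Passed to [build_mind_matrix()].
#' @param seed Base seed; subject `i` uses `seed + i` for its jitter.
#' @return Subject x region matrix of weighted degrees.
#' @export
cohort_degrees <- function(cohort, k = 3, seed = 1, min_vertices = 20) {
  features <- if (inherits(cohort, "mind_cohort")) cohort$features else cohort
  .assert(is.list(features) && length(features) > 0,
          "no subject features supplied")
  seed <- .check_seed(seed)
  out <- t(vapply(seq_along(features), function(i) {
    S <- build_mind_matrix(features[[i]], k = k,
                           seed = (seed + i) %% .Machine$integer.max,
                           min_vertices = min_vertices)
    weighted_degree(S)
  }, numeric(length(features[[1]]))))
  rownames(out) <- names(features)
  colnames(out) <- names(features[[1]])
  out
}

#' Regional mean of one morphometric feature
#'
#' Collapses vertex-level features to a subject x region table of regional
#' means for a single feature (e.g. cortical thickness), so the same
#' normative machinery can be run on a univariate metric instead of MIND
#' degree.
#'
#' @param cohort A `mind_cohort` or named list of per-subject feature lists.
#' @param feature One of `"thickness"`, `"curvature"`, `"sulcal_depth"`,
#'   `"area"`, `"volume"`.
#' @return Subject x region matrix of regional feature means.
#' @export
regional_feature_means <- function(cohort, feature = "thickness") {
  features <- if (inherits(cohort, "mind_cohort")) cohort$features else cohort
  .assert(feature %in% .feature_names, "unknown feature: ", feature)
  out <- t(vapply(features, function(subj)
    vapply(subj, function(m) mean(m[, feature]), numeric(1)),
    numeric(length(features[[1]]))))
  rownames(out) <- names(features)
  out
}
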