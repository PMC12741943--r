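## Shared small fixtures, built in code.

## Gaussian vertex sample: n x 5, N(mu, sd^2 I).
gauss_vertices <- function(n, mu = 0, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * 5, mu, sd), n, 5,
         dimnames = list(NULL, c("thickness", "curvature", "sulcal_depth",
                                 "area", "volume")))
}

## A tiny subject: regions drawn from N(shift_r, I).
tiny_subject <- function(n_regions = 4, n_vertices = 40, shifts = NULL,
                         seed = 1) {
  set.seed(seed)
  shifts <- shifts %||% rep(0, n_regions)
  out <- lapply(seq_len(n_regions), function(r)
    gauss_vertices(n_vertices, mu = shifts[r]))
  names(out) <- seq_len(n_regions)
  out
}

## Manifest + degree matrix drawn from a plain Gaussian null (no signal),
## for permutation-machinery tests.
null_bin_fixture <- function(n_per_group = 50, n_regions = 40,
                             groups = c("NC_test", "AD"), seed = 1) {
  set.seed(seed)
  n <- n_per_group * length(groups)
  z <- matrix(rnorm(n * n_regions), n, n_regions,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              seq_len(n_regions)))
  manifest <- data.frame(subject_id = rownames(z),
                         diagnosis = rep(groups, each = n_per_group),
                         stringsAsFactors = FALSE)
  list(bin = threshold_deviations(z), z = z, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Brute-force minimum-cost assignment by enumeration (oracle for the
## Hungarian solver), n <= 7.
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL
  best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cst <- sum(cost[cbind(seq_len(n), p)])
    if (cst < best_cost) {
      best_cost <- cst
      best <- p
    }
  }
  list(assignment = best, cost = best_cost)
}
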