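## Deviation mapping: quality-control filters, head-size residualization,
## extreme-deviation thresholding and counting, group overlap / difference
## maps with permutation inference, Cohen's d maps, and within-group
## heterogeneity.

#' Exclude poor surface reconstructions by Euler index
#'
#' Excludes subjects whose Euler index is worse (more negative, i.e. more
#' topological defects) than the cohort median by more than `n_mad` median
#' absolute deviations.
#'
#' @param manifest Manifest with an `euler_index` column.
#' @param n_mad MAD multiplier (default 2).
#' @return List with `manifest` (retained rows) and `exclusions`
#'   (subject_id, euler_index, threshold).
#' @export
euler_mad_filter <- function(manifest, n_mad = 2) {
  .assert("euler_index" %in% names(manifest) &&
            !anyNA(manifest$euler_index),
          "euler_index must be present for all subjects")
  med <- median(manifest$euler_index)
  m <- mad(manifest$euler_index)
  if (m == 0) {
    warning("MAD of the Euler index is zero; no exclusions applied")
    thr <- -Inf
  } else {
    thr <- med - n_mad * m
  }
  drop_ <- manifest$euler_index < thr
  list(manifest = manifest[!drop_, , drop = FALSE],
       exclusions = data.frame(subject_id = manifest$subject_id[drop_],
                               euler_index = manifest$euler_index[drop_],
                               threshold = rep(thr, sum(drop_)),
                               stringsAsFactors = FALSE))
}

#' Exclude head-size outliers within diagnosis-by-sex cells
#'
#' Within each diagnosis x sex cell, excludes subjects whose estimated
#' total intracranial volume falls outside
#' `[Q1 - f * IQR, Q3 + f * IQR]`. The default fence multiplier 1.5 gives
#' classical Tukey fences; `fence_multiplier = 0` reproduces the literal
#' "outside the interquartile range" rule, which removes about half of a
#' continuous sample.
#'
#' @param manifest Manifest with `eTIV`, `sex`, `diagnosis`.
#' @param fence_multiplier IQR fence multiplier `f` (default 1.5).
#' @return List with `manifest` (retained) and `exclusions`.
#' @export
etiv_iqr_filter <- function(manifest, fence_multiplier = 1.5) {
  .assert(all(c("eTIV", "sex", "diagnosis") %in% names(manifest)),
          "manifest needs eTIV, sex and diagnosis")
  .assert(fence_multiplier >= 0, "fence_multiplier must be >= 0")
  cell <- interaction(manifest$diagnosis, manifest$sex, drop = TRUE)
  drop_ <- logical(nrow(manifest))
  lo <- hi <- rep(NA_real_, nrow(manifest))
  for (cl in levels(cell)) {
    idx <- which(cell == cl)
    if (length(idx) < 4) {
      warning("cell ", cl, " has fewer than 4 subjects; eTIV filter skipped")
      next
    }
    q <- quantile(manifest$eTIV[idx], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    lo[idx] <- q[1] - fence_multiplier * iqr
    hi[idx] <- q[2] + fence_multiplier * iqr
    drop_[idx] <- manifest$eTIV[idx] < lo[idx] | manifest$eTIV[idx] > hi[idx]
  }
  list(manifest = manifest[!drop_, , drop = FALSE],
       exclusions = data.frame(subject_id = manifest$subject_id[drop_],
                               eTIV = manifest$eTIV[drop_],
                               lower = lo[drop_], upper = hi[drop_],
                               stringsAsFactors = FALSE))
}

#' Residualize deviation Z-scores against head size
#'
#' Within each sex x diagnosis cell and per region, removes the straight-
#' line dependence of Z on eTIV while preserving the cell mean (the slope
#' component around the cell's mean eTIV is subtracted; the intercept is
#' retained). Cells with fewer than 3 subjects are skipped with a warning.
#'
#' @param z Subject x region deviation matrix.
#' @param manifest Matching manifest with `eTIV`, `sex`, `diagnosis`.
#' @return Residualized deviation matrix (attributes preserved).
#' @export
residualize_etiv <- function(z, manifest) {
  .assert(is.matrix(z) && nrow(z) == nrow(manifest),
          "z rows must match the manifest")
  .assert(all(c("eTIV", "sex", "diagnosis") %in% names(manifest)),
          "manifest needs eTIV, sex and diagnosis")
  out <- z
  cell <- interaction(manifest$diagnosis, manifest$sex, drop = TRUE)
  for (cl in levels(cell)) {
    idx <- which(cell == cl)
    if (length(idx) < 3) {
      warning("cell ", cl, " has fewer than 3 subjects; residualization skipped")
      next
    }
    e <- manifest$eTIV[idx] - mean(manifest$eTIV[idx])
    denom <- sum(e^2)
    if (denom == 0) next
    slope <- crossprod(e, z[idx, , drop = FALSE]) / denom
    out[idx, ] <- z[idx, , drop = FALSE] - e %*% slope
  }
  attributes(out) <- attributes(z)
  out
}

#' Binarize extreme deviations
#'
#' Flags regions whose deviation Z exceeds the threshold, strictly, in each
#' direction separately (the default 1.96 corresponds to the top and bottom
#' 2.5% of the normative distribution).
#'
#' @param z Subject x region deviation matrix (finite).
#' @param threshold Two-sided threshold (default 1.96).
#' @return Object of class `binary_deviation_map`: list with logical
#'   matrices `pos` (`z > threshold`) and `neg` (`z < -threshold`) and the
#'   `threshold`.
#' @export
threshold_deviations <- function(z, threshold = 1.96) {
  .assert(is.matrix(z) && all(is.finite(z)), "z must be a finite matrix")
  .assert(threshold > 0, "threshold must be positive")
  structure(list(pos = z > threshold, neg = z < -threshold,
                 threshold = threshold),
            class = "binary_deviation_map")
}

#' Per-subject extreme-deviation counts
#'
#' @param bin A `binary_deviation_map`.
#' @return Data.frame with `subject_id`, `positive_count`, `negative_count`.
#' @export
count_deviations <- function(bin) {
  .assert(inherits(bin, "binary_deviation_map"),
          "bin must come from threshold_deviations()")
  data.frame(subject_id = rownames(bin$pos) %||%
               sprintf("S%04d", seq_len(nrow(bin$pos))),
             positive_count = unname(rowSums(bin$pos)),
             negative_count = unname(rowSums(bin$neg)),
             stringsAsFactors = FALSE)
}

.overlap_groups <- function(manifest, control_group, groups) {
  .assert("diagnosis" %in% names(manifest), "manifest needs diagnosis")
  present <- unique(manifest$diagnosis)
  .assert(control_group %in% present,
          "control group ", control_group, " absent from manifest")
  groups <- groups %||% setdiff(present, c(control_group, "NC_train"))
  .assert(length(groups) > 0, "no clinical groups to compare")
  groups
}

#' Regional overlap and difference maps
#'
#' For each clinical group, region and deviation direction, the proportion
#' of the group's subjects flagged, and the difference versus the held-out
#' control group.
#'
#' @param bin A `binary_deviation_map`.
#' @param manifest Matching manifest with `diagnosis`.
#' @param control_group Held-out control label (default `"NC_test"`).
#' @param groups Clinical groups (default: all non-control, non-training
#'   groups present).
#' @return Long data.frame: `group`, `direction` ("positive"/"negative"),
#'   `region`, `prop`, `prop_control`, `delta`.
#' @export
group_overlap_and_difference <- function(bin, manifest,
                                         control_group = "NC_test",
                                         groups = NULL) {
  .assert(inherits(bin, "binary_deviation_map"), "bin must be a binary map")
  .assert(nrow(bin$pos) == nrow(manifest), "bin rows must match the manifest")
  groups <- .overlap_groups(manifest, control_group, groups)
  regions <- colnames(bin$pos) %||% as.character(seq_len(ncol(bin$pos)))
  ctrl <- manifest$diagnosis == control_group
  out <- list()
  for (dir_ in c("positive", "negative")) {
    B <- if (dir_ == "positive") bin$pos else bin$neg
    pc <- colMeans(B[ctrl, , drop = FALSE])
    for (g in groups) {
      pg <- colMeans(B[manifest$diagnosis == g, , drop = FALSE])
      out[[length(out) + 1]] <- data.frame(
        group = g, direction = dir_, region = regions,
        prop = unname(pg), prop_control = unname(pc),
        delta = unname(pg - pc), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## Null deltas of group-minus-control proportions under label shuffling for
## an indicator matrix B (subjects x items). Returns n_perm x items.
.null_deltas <- function(B, is_group, n_perm) {
  n <- nrow(B)
  ng <- sum(is_group)
  vapply(seq_len(n_perm), function(p) {
    pick <- sample.int(n, ng)
    gsum <- colSums(B[pick, , drop = FALSE])
    (gsum / ng) - ((colSums(B) - gsum) / (n - ng))
  }, numeric(ncol(B))) |> t()
}

#' Permutation test of regional overlap differences
#'
#' Assesses, per region and deviation direction, whether a clinical group's
#' overlap exceeds (or falls short of) the held-out control group's, by
#' shuffling diagnostic labels between the two groups while preserving
#' group sizes. Directional empirical p-values use the +1 correction
#' `p = (1 + #(null >= observed)) / (n_perm + 1)`; Benjamini-Hochberg FDR
#' is applied across regions within each group x direction x tail family.
#'
#' @inheritParams group_overlap_and_difference
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @return The [group_overlap_and_difference()] table with `p_greater`,
#'   `p_less`, `q_greater`, `q_less` columns appended.
#' @export
permutation_overlap_test <- function(bin, manifest,
                                     control_group = "NC_test",
                                     groups = NULL, n_perm = 10000,
                                     seed = 1) {
  if (n_perm < 100) warning("n_perm < 100 gives very coarse p-values")
  obs <- group_overlap_and_difference(bin, manifest, control_group, groups)
  groups <- unique(obs$group)
  set.seed(.check_seed(seed))
  obs$p_greater <- obs$p_less <- NA_real_
  for (g in groups) {
    both <- manifest$diagnosis %in% c(g, control_group)
    is_group <- manifest$diagnosis[both] == g
    .assert(sum(is_group) >= 2 && sum(!is_group) >= 2,
            "need >= 2 subjects per group for ", g)
    for (dir_ in c("positive", "negative")) {
      B <- (if (dir_ == "positive") bin$pos else bin$neg)[both, , drop = FALSE]
      nd <- .null_deltas(B, is_group, n_perm)
      rows <- which(obs$group == g & obs$direction == dir_)
      d <- obs$delta[rows]
      obs$p_greater[rows] <- .perm_p(colSums(nd >= rep(d, each = n_perm)),
                                     n_perm)
      obs$p_less[rows] <- .perm_p(colSums(nd <= rep(d, each = n_perm)),
                                  n_perm)
    }
  }
  obs$q_greater <- obs$q_less <- NA_real_
  for (g in groups) for (dir_ in c("positive", "negative")) {
    rows <- which(obs$group == g & obs$direction == dir_)
    obs$q_greater[rows] <- p.adjust(obs$p_greater[rows], method = "BH")
    obs$q_less[rows] <- p.adjust(obs$p_less[rows], method = "BH")
  }
  obs
}

#' Regional Cohen's d map between two diagnostic groups
#'
#' Computes, per region, Cohen's d on signed deviation Z-scores oriented so
#' that the more severe diagnostic group (severity order NC < MCI_stable <
#' MCI_progressive < AD) is subtracted from the less severe one, with
#' two-tailed label-permutation p-values and BH FDR across regions.
#'
#' @param z Subject x region deviation matrix.
#' @param manifest Matching manifest with `diagnosis`.
#' @param group_pair Character vector of two diagnostic groups.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return Data.frame per region: `d`, `p`, `q`, `flagged` (TRUE where the
#'   pooled variance was zero and d is undefined).
#' @export
cohens_d_map <- function(z, manifest, group_pair, n_perm = 10000, seed = 1) {
  .assert(is.matrix(z) && nrow(z) == nrow(manifest),
          "z rows must match the manifest")
  .assert(length(group_pair) == 2, "group_pair must name two groups")
  sev <- .severity_rank(group_pair)
  less <- group_pair[which.min(sev)]
  more <- group_pair[which.max(sev)]
  a <- which(manifest$diagnosis == less)
  b <- which(manifest$diagnosis == more)
  .assert(length(a) >= 2 && length(b) >= 2,
          "both groups need at least 2 subjects")
  regions <- colnames(z) %||% as.character(seq_len(ncol(z)))
  d_obs <- vapply(seq_len(ncol(z)),
                  function(j) .cohens_d(z[a, j], z[b, j]), numeric(1))
  set.seed(.check_seed(seed))
  idx <- c(a, b)
  na <- length(a)
  exceed <- numeric(ncol(z))
  for (p in seq_len(n_perm)) {
    pick <- sample(idx)
    pa <- pick[seq_len(na)]
    pb <- pick[-seq_len(na)]
    d_null <- vapply(seq_len(ncol(z)),
                     function(j) .cohens_d(z[pa, j], z[pb, j]), numeric(1))
    exceed <- exceed + (abs(d_null) >= abs(d_obs))
  }
  p_ <- .perm_p(exceed, n_perm)
  p_[is.na(d_obs)] <- NA_real_
  data.frame(region = regions, less_severe = less, more_severe = more,
             d = d_obs, p = p_,
             q = p.adjust(p_, method = "BH"),
             flagged = is.na(d_obs), stringsAsFactors = FALSE)
}

#' Within-group heterogeneity of binary deviation maps
#'
#' Pairwise Hamming distances (number of disagreeing regions) between all
#' unordered subject pairs within each diagnostic group, per deviation
#' direction, summarized by median and interquartile range.
#'
#' @param bin A `binary_deviation_map`.
#' @param manifest Matching manifest with `diagnosis`.
#' @param groups Groups to summarize (default: all with >= 2 subjects).
#' @return Data.frame: `group`, `direction`, `n_pairs`, `median`, `iqr`.
#' @export
hamming_heterogeneity <- function(bin, manifest, groups = NULL) {
  .assert(inherits(bin, "binary_deviation_map"), "bin must be a binary map")
  .assert(nrow(bin$pos) == nrow(manifest), "bin rows must match the manifest")
  tab <- table(manifest$diagnosis)
  groups <- groups %||% names(tab)[tab >= 2]
  out <- list()
  for (g in groups) {
    idx <- which(manifest$diagnosis == g)
    .assert(length(idx) >= 2, "group ", g, " needs >= 2 subjects")
    for (dir_ in c("positive", "negative")) {
      M <- (if (dir_ == "positive") bin$pos else bin$neg)[idx, , drop = FALSE]
      M <- M * 1
      H <- tcrossprod(M, 1 - M)
      H <- H + t(H)
      d <- H[lower.tri(H)]
      q <- quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
      out[[length(out) + 1]] <- data.frame(
        group = g, direction = dir_, n_pairs = length(d),
        median = q[2], iqr = q[3] - q[1], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
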