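## Functional-network enrichment of extreme deviations, tested against two
## complementary null families computed on the identical observed
## statistic: group-label permutation (exchangeability of diagnosis) and
## spatially constrained rotation of the parcellation (preservation of
## spatial structure while randomizing location).

## Subject x network indicator: does the subject have >= 1 flagged region
## in the network? `region_net` maps bin columns to network labels.
.network_indicator <- function(B, region_net) {
  nets <- sort(unique(region_net))
  out <- vapply(nets, function(k)
    rowSums(B[, region_net == k, drop = FALSE]) > 0, logical(nrow(B)))
  colnames(out) <- paste0("net", nets)
  out * 1
}

.net_region_map <- function(bin, parcellation) {
  .validate_parcellation(parcellation)
  .assert(ncol(bin$pos) == nrow(parcellation),
          "binary map columns must match the parcellation")
  regions <- colnames(bin$pos) %||% as.character(parcellation$region_id)
  net <- parcellation$network_label[
    match(as.integer(regions), parcellation$region_id)]
  .assert(!anyNA(net), "binary map columns not found in the parcellation")
  counts <- table(factor(net, levels = sort(unique(parcellation$network_label))))
  if (any(counts == 0))
    stop("network(s) with zero regions: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  net
}

#' Network-wise deviation overlap profiles
#'
#' For each diagnostic group, functional network and deviation direction:
#' the proportion of the group's subjects with at least one extreme
#' deviation in the network, and its difference versus the held-out
#' control group.
#'
#' @param bin A `binary_deviation_map`.
#' @param parcellation Parcellation supplying `network_label` per region.
#' @param manifest Matching manifest with `diagnosis`.
#' @param control_group Held-out control label (default `"NC_test"`).
#' @param groups Clinical groups (default: non-control groups present).
#' @return Long data.frame: `group`, `direction`, `network`, `prop`,
#'   `prop_control`, `delta`.
#' @export
network_overlap_profile <- function(bin, parcellation, manifest,
                                    control_group = "NC_test",
                                    groups = NULL) {
  .assert(inherits(bin, "binary_deviation_map"), "bin must be a binary map")
  .assert(nrow(bin$pos) == nrow(manifest), "bin rows must match the manifest")
  net <- .net_region_map(bin, parcellation)
  groups <- .overlap_groups(manifest, control_group, groups)
  ctrl <- manifest$diagnosis == control_group
  nets <- sort(unique(net))
  out <- list()
  for (dir_ in c("positive", "negative")) {
    I <- .network_indicator(if (dir_ == "positive") bin$pos else bin$neg, net)
    pc <- colMeans(I[ctrl, , drop = FALSE])
    for (g in groups) {
      pg <- colMeans(I[manifest$diagnosis == g, , drop = FALSE])
      out[[length(out) + 1]] <- data.frame(
        group = g, direction = dir_, network = nets,
        prop = unname(pg), prop_control = unname(pc),
        delta = unname(pg - pc), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

.enrichment_pq <- function(obs, null_fun, groups, n_perm) {
  obs$p_greater <- obs$p_less <- NA_real_
  obs$q_greater <- obs$q_less <- NA_real_
  for (g in groups) for (dir_ in c("positive", "negative")) {
    rows <- which(obs$group == g & obs$direction == dir_)
    nd <- null_fun(g, dir_)
    d <- obs$delta[rows]
    obs$p_greater[rows] <- .perm_p(colSums(nd >= rep(d, each = n_perm)),
                                   n_perm)
    obs$p_less[rows] <- .perm_p(colSums(nd <= rep(d, each = n_perm)), n_perm)
  }
  for (g in groups) for (dir_ in c("positive", "negative")) {
    rows <- which(obs$group == g & obs$direction == dir_)
    obs$q_greater[rows] <- p.adjust(obs$p_greater[rows], method = "BH")
    obs$q_less[rows] <- p.adjust(obs$p_less[rows], method = "BH")
  }
  obs
}

#' Group-label permutation null for network enrichment
#'
#' Shuffles diagnostic labels between each clinical group and the held-out
#' controls (preserving group sizes) and recomputes the network overlap
#' difference, giving +1-corrected directional empirical p-values and BH
#' FDR across networks.
#'
#' @inheritParams network_overlap_profile
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return The profile table with `p_greater`, `p_less`, `q_greater`,
#'   `q_less` columns.
#' @export
group_label_null <- function(bin, parcellation, manifest,
                             control_group = "NC_test", groups = NULL,
                             n_perm = 10000, seed = 1) {
  obs <- network_overlap_profile(bin, parcellation, manifest,
                                 control_group, groups)
  net <- .net_region_map(bin, parcellation)
  groups <- unique(obs$group)
  set.seed(.check_seed(seed))
  null_fun <- function(g, dir_) {
    both <- manifest$diagnosis %in% c(g, control_group)
    I <- .network_indicator(
      (if (dir_ == "positive") bin$pos else bin$neg)[both, , drop = FALSE],
      net)
    .null_deltas(I, manifest$diagnosis[both] == g, n_perm)
  }
  .enrichment_pq(obs, null_fun, groups, n_perm)
}

#' Spatial rotation null for network enrichment
#'
#' Tests the same observed network overlap differences against spatially
#' constrained null maps: each draw rigidly rotates the parcellation
#' centroids (mirrored across hemispheres), relabels regions by
#' minimum-distance Hungarian assignment, and recomputes the statistic.
#' This preserves each subject's total flag count and the spatial
#' autocorrelation of the maps while randomizing location.
#'
#' @inheritParams group_label_null
#' @param rotations Optional list of fixed rotation matrices (testing).
#' @return The profile table with `p_greater`, `p_less`, `q_greater`,
#'   `q_less` columns.
#' @export
spatial_rotation_null <- function(bin, parcellation, manifest,
                                  control_group = "NC_test", groups = NULL,
                                  n_perm = 10000, seed = 1,
                                  rotations = NULL) {
  obs <- network_overlap_profile(bin, parcellation, manifest,
                                 control_group, groups)
  net <- .net_region_map(bin, parcellation)
  groups <- unique(obs$group)
  perms <- region_rotation_perms(parcellation, n_perm, seed, rotations)
  n_perm <- nrow(perms)
  ctrl <- manifest$diagnosis == control_group
  nets <- sort(unique(net))
  null_fun <- function(g, dir_) {
    B <- if (dir_ == "positive") bin$pos else bin$neg
    gi <- manifest$diagnosis == g
    nd <- matrix(NA_real_, n_perm, length(nets))
    for (p in seq_len(n_perm)) {
      I <- .network_indicator(B[, perms[p, ], drop = FALSE], net)
      nd[p, ] <- colMeans(I[gi, , drop = FALSE]) -
        colMeans(I[ctrl, , drop = FALSE])
    }
    nd
  }
  .enrichment_pq(obs, null_fun, groups, n_perm)
}
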