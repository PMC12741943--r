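#' Generate a bilateral spherical parcellation with functional networks
#'
#' Builds the region metadata the pipeline needs: an even number of cortical
#' regions split equally between hemispheres, left-right homologue pairing,
#' a partition into functional networks (default seven, mirroring the
#' canonical seven-network cortical scheme), and unit-norm spherical centroid
#' coordinates used by the rotation null models. Centroids are laid out on a
#' Fibonacci lattice over one hemisphere of the sphere (x < 0 for the left
#' hemisphere) so they are approximately evenly spread; each right-hemisphere
#' homologue gets the mirrored centroid (x negated). Networks are spatially
#' contiguous clusters of left-hemisphere centroids (k-means), shared across
#' homologues.
#'
#' @param n_regions Even total number of regions (the full-scale cortical
#'   atlas has 360; the desk-scale default elsewhere is 60).
#' @param n_networks Number of functional networks (default 7).
#' @param seed Integer seed controlling the random lattice orientation and
#'   network clustering.
#' @return A data.frame with one row per region and columns `region_id`,
#'   `region_name`, `hemisphere` ("L"/"R"), `homologue_id`, `network_label`
#'   (integer in `1:n_networks`), and unit-norm centroid coordinates
#'   `cx`, `cy`, `cz`. Left-hemisphere regions come first.
#' @export
generate_parcellation <- function(n_regions, n_networks = 7, seed = 1) {
  .assert(is.numeric(n_regions) && length(n_regions) == 1 &&
            n_regions == round(n_regions) && n_regions >= 2,
          "n_regions must be a positive integer >= 2")
  .assert(n_regions %% 2 == 0, "n_regions must be even (bilateral atlas)")
  .assert(n_networks >= 1 && n_regions >= 2 * n_networks,
          "n_regions must be at least 2 * n_networks")
  set.seed(.check_seed(seed))

  nh <- n_regions / 2
  ## Each hemisphere's surface maps to its own full sphere (as in standard
  ## surface reconstructions), so the left-hemisphere centroids tile a
  ## complete Fibonacci lattice; a random rotation about the x axis makes
  ## layouts seed-dependent. Right-hemisphere homologues get the mirrored
  ## coordinates (x negated) on their own sphere.
  i <- seq_len(nh) - 0.5
  x <- 1 - 2 * i / nh                  # in (-1, 1): full sphere
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - x^2))
  theta0 <- runif(1, 0, 2 * pi)
  y <- r * cos(phi + theta0)
  z <- r * sin(phi + theta0)
  cl <- cbind(cx = x, cy = y, cz = z)
  cl <- cl / sqrt(rowSums(cl^2))

  net <- if (n_networks == 1) rep(1L, nh) else {
    km <- kmeans(cl, centers = n_networks, nstart = 5, iter.max = 50)
    ## Relabel clusters deterministically by first occurrence.
    as.integer(factor(km$cluster, levels = unique(km$cluster)))
  }

  left <- data.frame(
    region_id = seq_len(nh),
    region_name = sprintf("L_%03d", seq_len(nh)),
    hemisphere = "L",
    homologue_id = as.integer(seq_len(nh) + nh),
    network_label = net,
    cx = cl[, 1], cy = cl[, 2], cz = cl[, 3],
    stringsAsFactors = FALSE
  )
  right <- data.frame(
    region_id = as.integer(seq_len(nh) + nh),
    region_name = sprintf("R_%03d", seq_len(nh)),
    hemisphere = "R",
    homologue_id = seq_len(nh),
    network_label = net,
    cx = -cl[, 1], cy = cl[, 2], cz = cl[, 3],
    stringsAsFactors = FALSE
  )
  out <- rbind(left, right)
  rownames(out) <- NULL
  out
}

.validate_parcellation <- function(parcellation) {
  .assert(is.data.frame(parcellation), "parcellation must be a data.frame")
  need <- c("region_id", "region_name", "hemisphere", "homologue_id",
            "network_label", "cx", "cy", "cz")
  .assert(all(need %in% names(parcellation)),
          "parcellation is missing columns: ",
          paste(setdiff(need, names(parcellation)), collapse = ", "))
  n <- nrow(parcellation)
  .assert(n %% 2 == 0, "parcellation must have an even region count")
  .assert(all(sort(parcellation$region_id) == seq_len(n)),
          "region_id must be 1..n_regions")
  hom <- parcellation$homologue_id[match(seq_len(n), parcellation$region_id)]
  .assert(all(hom[hom] == seq_len(n)), "homologue pairing must be an involution")
  invisible(parcellation)
}

#' Write / read parcellation metadata as tab-separated text
#'
#' @param parcellation Parcellation data.frame.
#' @param path File path.
#' @return `read_parcellation` returns the parcellation data.frame;
#'   `write_parcellation` returns `path` invisibly.
#' @export
write_parcellation <- function(parcellation, path) {
  .validate_parcellation(parcellation)
  write.table(parcellation, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  .validate_parcellation(out)
  out
}
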