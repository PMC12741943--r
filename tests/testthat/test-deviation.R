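make_manifest <- function(euler = NULL, etiv = NULL, diagnosis = "NC",
                          sex = "F") {
  n <- max(length(euler), length(etiv), length(diagnosis), length(sex))
  data.frame(subject_id = sprintf("s%02d", seq_len(n)),
             euler_index = rep_len(euler %||% -40L, n),
             eTIV = rep_len(etiv %||% 1.4e6, n),
             diagnosis = rep_len(diagnosis, n), sex = rep_len(sex, n),
             stringsAsFactors = FALSE)
}

test_that("Euler MAD filter excludes only gross outliers", {
  m <- make_manifest(euler = c(-40, -42, -41, -43, -400))
  out <- euler_mad_filter(m, n_mad = 2)
  expect_identical(out$exclusions$subject_id, "s05")
  expect_equal(nrow(out$manifest), 4)
  ## all identical: MAD zero, warn, keep everyone
  m2 <- make_manifest(euler = rep(-40, 6))
  expect_warning(out2 <- euler_mad_filter(m2), "zero")
  expect_equal(nrow(out2$manifest), 6)
  ## infinite fence excludes nobody
  out3 <- euler_mad_filter(m, n_mad = Inf)
  expect_equal(nrow(out3$manifest), 5)
})

test_that("eTIV filter applies Tukey fences within diagnosis-by-sex cells", {
  set.seed(1)
  vals <- rnorm(40, 1.4e6, 5e4)
  q <- quantile(vals, c(0.25, 0.75))
  vals[1] <- q[2] + 10 * (q[2] - q[1])
  m <- make_manifest(etiv = vals)
  out <- etiv_iqr_filter(m)
  expect_true("s01" %in% out$exclusions$subject_id)
  expect_false("s02" %in% out$exclusions$subject_id)
  ## all equal: IQR zero, nobody leaves
  m2 <- make_manifest(etiv = rep(1.4e6, 10))
  expect_equal(nrow(etiv_iqr_filter(m2)$manifest), 10)
  ## literal zero-fence reading drops about half of continuous data
  out0 <- etiv_iqr_filter(m, fence_multiplier = 0)
  expect_gt(nrow(out0$exclusions), 0.3 * nrow(m))
  ## tiny cells are skipped with a warning
  m3 <- make_manifest(etiv = rnorm(3, 1.4e6, 5e4))
  expect_warning(etiv_iqr_filter(m3), "fewer than 4")
})

test_that("eTIV residualization removes constructed slopes per cell", {
  set.seed(2)
  n <- 500
  man <- data.frame(subject_id = sprintf("s%03d", 1:n),
                    eTIV = rnorm(n, 1.4e6, 1e5),
                    diagnosis = rep(c("NC", "AD"), each = n / 2),
                    sex = "F", stringsAsFactors = FALSE)
  ## opposite slopes in the two cells
  slope <- ifelse(man$diagnosis == "NC", 1e-6, -1e-6)
  z <- matrix(slope * (man$eTIV - 1.4e6) + rnorm(n, 0, 0.5), n, 3)
  out <- residualize_etiv(z, man)
  for (g in c("NC", "AD")) {
    idx <- man$diagnosis == g
    expect_lt(abs(cor(out[idx, 1], man$eTIV[idx])), 0.05)
    ## cell means preserved
    expect_equal(mean(out[idx, 1]), mean(z[idx, 1]), tolerance = 1e-8)
  }
  ## independent z: no material change. The removable component has
  ## magnitude |slope_hat| * max|eTIV deviation| with slope_hat ~
  ## N(0, 1 / (sd_e * sqrt(n_cell))); bound it at 4 standard errors.
  z0 <- matrix(rnorm(n * 2), n, 2)
  out0 <- residualize_etiv(z0, man)
  for (g in c("NC", "AD")) {
    idx <- man$diagnosis == g
    e <- man$eTIV[idx] - mean(man$eTIV[idx])
    bound <- 4 * max(abs(e)) / sqrt(sum(e^2))
    expect_lt(max(abs(out0[idx, ] - z0[idx, ])), bound)
  }
})

test_that("thresholding is strict and direction-separated", {
  z <- rbind(a = c(-2.5, 0, 2.5),
             b = c(1.96, -1.96, 3))
  bin <- threshold_deviations(z)
  expect_identical(unname(bin$neg),
                   rbind(c(TRUE, FALSE, FALSE), c(FALSE, FALSE, FALSE)))
  expect_identical(unname(bin$pos),
                   rbind(c(FALSE, FALSE, TRUE), c(FALSE, FALSE, TRUE)))
  expect_false(any(bin$pos & bin$neg))
  ## exact threshold values are not flagged
  expect_false(any(threshold_deviations(matrix(c(1.96, -1.96), 1))$pos))
  cnt <- count_deviations(bin)
  expect_equal(cnt$positive_count, c(1, 1))
  expect_equal(cnt$negative_count, c(1, 0))
  ## counts invariant to region order
  bin2 <- threshold_deviations(z[, c(3, 1, 2)])
  expect_equal(count_deviations(bin2)[, -1], cnt[, -1])
  ## all-quiet map
  expect_equal(sum(count_deviations(
    threshold_deviations(matrix(0.5, 3, 4)))[, -1]), 0)
})

test_that("overlap and difference maps do the arithmetic", {
  bin <- structure(list(
    pos = rbind(matrix(FALSE, 10, 1), matrix(FALSE, 100, 1)),
    neg = rbind(matrix(rep(c(TRUE, FALSE), c(4, 6))),
                matrix(rep(c(TRUE, FALSE), c(10, 90)))),
    threshold = 1.96), class = "binary_deviation_map")
  man <- data.frame(subject_id = sprintf("s%03d", 1:110),
                    diagnosis = rep(c("AD", "NC_test"), c(10, 100)),
                    stringsAsFactors = FALSE)
  ov <- group_overlap_and_difference(bin, man)
  neg <- ov[ov$direction == "negative", ]
  expect_equal(neg$prop, 0.4)
  expect_equal(neg$prop_control, 0.1)
  expect_equal(neg$delta, 0.3)
  ## a group compared against itself has zero difference
  man2 <- man
  man2$diagnosis <- rep(c("AD", "NC_test"), 55)
  set.seed(3)
  binr <- threshold_deviations(matrix(rnorm(110 * 5), 110, 5))
  ov2 <- group_overlap_and_difference(binr, man2)
  expect_true(all(abs(ov2$delta) < 0.2))  # same distribution, small deltas
})

test_that("permutation overlap p-values hit the +1 floor for extreme deltas", {
  fix <- null_bin_fixture(n_per_group = 30, n_regions = 5, seed = 4)
  ## plant a deterministic extreme effect in region 1
  fix$bin$neg[, 1] <- fix$manifest$diagnosis == "AD"
  res <- suppressWarnings(
    permutation_overlap_test(fix$bin, fix$manifest, n_perm = 500, seed = 9))
  r1 <- res[res$direction == "negative" & res$region == "1", ]
  expect_equal(r1$p_greater, 1 / 501)
  expect_warning(permutation_overlap_test(fix$bin, fix$manifest,
                                          n_perm = 50, seed = 9), "coarse")
})

test_that("null permutation p-values are super-uniform and seeded", {
  ps <- unlist(lapply(1:10, function(s) {
    fix <- null_bin_fixture(n_per_group = 40, n_regions = 30,
                            seed = 100 + s)
    res <- permutation_overlap_test(fix$bin, fix$manifest, n_perm = 500,
                                    seed = s)
    res$p_greater[res$direction == "negative"]
  }))
  grid <- seq(0.05, 0.95, by = 0.05)
  ecdf_ <- vapply(grid, function(g) mean(ps <= g), numeric(1))
  expect_true(all(ecdf_ <= grid + 0.05))
  ## determinism under a fixed seed
  fix <- null_bin_fixture(seed = 5)
  a <- permutation_overlap_test(fix$bin, fix$manifest, n_perm = 200,
                                seed = 42)
  b <- permutation_overlap_test(fix$bin, fix$manifest, n_perm = 200,
                                seed = 42)
  expect_identical(a, b)
})

test_that("Cohen's d maps carry the severity orientation", {
  set.seed(6)
  n <- 60
  z <- rbind(matrix(rnorm(n * 3, 0), n, 3),
             matrix(rnorm(n * 3, -1), n, 3))
  man <- data.frame(subject_id = sprintf("s%03d", 1:(2 * n)),
                    diagnosis = rep(c("MCI_stable", "AD"), each = n),
                    stringsAsFactors = FALSE)
  res <- cohens_d_map(z, man, c("AD", "MCI_stable"), n_perm = 300,
                      seed = 1)
  ## less severe minus more severe: means 0 - (-1) = +1 at unit sd
  expect_equal(res$less_severe[1], "MCI_stable")
  expect_true(all(res$d > 0.5))
  expect_true(all(res$q < 0.05))
  ## identical groups: d near zero, p large
  z2 <- matrix(rnorm(2 * n * 3), 2 * n, 3)
  res2 <- cohens_d_map(z2, man, c("MCI_stable", "AD"), n_perm = 300,
                       seed = 2)
  expect_true(all(abs(res2$d) < 0.5))
  expect_true(all(res2$p > 0.01))
})

test_that("Hamming heterogeneity counts disagreements", {
  bin <- structure(list(
    pos = rbind(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                c(TRUE, FALSE, FALSE)),
    neg = matrix(FALSE, 3, 3), threshold = 1.96),
    class = "binary_deviation_map")
  man <- data.frame(subject_id = c("a", "b", "c"),
                    diagnosis = rep("AD", 3), stringsAsFactors = FALSE)
  h <- hamming_heterogeneity(bin, man)
  pos <- h[h$direction == "positive", ]
  ## pairs: (a,b)=2, (a,c)=0, (b,c)=2
  expect_equal(pos$n_pairs, 3)
  expect_equal(pos$median, 2)
  neg <- h[h$direction == "negative", ]
  expect_equal(neg$median, 0)
  expect_equal(neg$iqr, 0)
})
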