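test_that("parcellation satisfies its structural invariants", {
  p <- generate_parcellation(360, 7, seed = 1)
  expect_equal(nrow(p), 360)
  expect_equal(sum(p$hemisphere == "L"), 180)
  expect_equal(sum(p$hemisphere == "R"), 180)
  ## homologue pairing is an involution crossing hemispheres
  hom <- p$homologue_id[match(seq_len(360), p$region_id)]
  expect_identical(hom[hom], seq_len(360L))
  expect_true(all(p$hemisphere[match(hom, p$region_id)] !=
                    p$hemisphere))
  ## unit-norm centroids, mirrored across the midline
  norms <- sqrt(p$cx^2 + p$cy^2 + p$cz^2)
  expect_equal(norms, rep(1, 360), tolerance = 1e-12)
  expect_equal(p$cx[1:180], -p$cx[181:360])
  expect_equal(p$cy[1:180], p$cy[181:360])
  ## every region has exactly one of 7 networks; homologues share it
  expect_setequal(unique(p$network_label), 1:7)
  expect_identical(p$network_label,
                   p$network_label[match(hom, p$region_id)])
})

test_that("parcellation generation is seeded and validates arguments", {
  expect_identical(generate_parcellation(60, 7, seed = 5),
                   generate_parcellation(60, 7, seed = 5))
  expect_error(generate_parcellation(61, 7), "even")
  expect_error(generate_parcellation(10, 7), "2 \\* n_networks")
  p2 <- generate_parcellation(2, 1, seed = 0)
  expect_equal(nrow(p2), 2)
  expect_identical(p2$network_label, c(1L, 1L))
})

test_that("parcellation round-trips through its TSV format", {
  p <- generate_parcellation(20, 4, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_parcellation(p, path)
  expect_equal(read_parcellation(path), p)
})

tiny_spec <- function(...) {
  cohort_spec(n_nc_train = 14, n_nc_test = 6, n_mci_stable = 5,
              n_mci_progressive = 5, n_ad = 8, n_regions = 16,
              n_networks = 4, vertices_per_region = 25,
              targeted_networks = 4, n_sites = 2, ...)
}

test_that("cohorts are reproducible and structurally complete", {
  p <- generate_parcellation(16, 4, seed = 2)
  co1 <- generate_cohort(tiny_spec(seed = 7), p)
  co2 <- generate_cohort(tiny_spec(seed = 7), p)
  expect_identical(co1, co2)
  m <- co1$manifest
  expect_equal(nrow(m), 38)
  expect_equal(as.vector(table(m$diagnosis)[c("NC_train", "NC_test",
                                              "AD")]),
               c(14L, 6L, 8L))
  expect_true(all(m$survival_years >= 0))
  expect_true(all(m$abc_score %in% c(0:3, NA)))
  expect_true(all(is.na(m$abc_score[!m$death_observed])))
  expect_true(all(m$euler_index <= 0))
  expect_true(all(m$sex %in% c("F", "M")))
  expect_length(co1$features, 38)
  expect_length(co1$features[[1]], 16)
  expect_equal(dim(co1$features[[1]][[1]]), c(25, 5))
})

test_that("zero group sizes warn and emit empty groups", {
  p <- generate_parcellation(16, 4, seed = 2)
  spec <- cohort_spec(n_nc_train = 10, n_nc_test = 4, n_mci_stable = 0,
                      n_mci_progressive = 0, n_ad = 5, n_regions = 16,
                      n_networks = 4, vertices_per_region = 25, seed = 1)
  expect_warning(co <- generate_cohort(spec, p), "empty group")
  expect_false("MCI_stable" %in% co$manifest$diagnosis)
})

test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(n_ad = -1), "non-negative")
  expect_error(cohort_spec(perturbation = c(NC = 0, MCI_stable = -0.1,
                                            MCI_progressive = 1, AD = 2)),
               ">= 0")
  expect_error(cohort_spec(apoe_freq = c(e3_homozygote = 0.5,
                                         e2_carrier = 0.4)),
               "sum to 1")
})

test_that("no-perturbation cohorts show no degree effect and dose response is monotone", {
  p <- generate_parcellation(16, 4, seed = 9)
  tdiff <- function(ad_mag, seed) {
    spec <- cohort_spec(n_nc_train = 10, n_nc_test = 0, n_mci_stable = 0,
                        n_mci_progressive = 0, n_ad = 8, n_regions = 16,
                        n_networks = 4, vertices_per_region = 30,
                        targeted_networks = 4,
                        perturbation = c(NC = 0, MCI_stable = 0,
                                         MCI_progressive = 0, AD = ad_mag),
                        seed = seed)
    co <- suppressWarnings(generate_cohort(spec, p))
    deg <- cohort_degrees(co, seed = seed)
    tr <- co$truth$targeted_regions
    ad <- co$manifest$diagnosis == "AD"
    mean(deg[ad, tr]) - mean(deg[!ad, tr])
  }
  seeds <- 1:10
  null_diff <- vapply(seeds, function(s) tdiff(0, s), numeric(1))
  mid_diff <- vapply(seeds, function(s) tdiff(1, s), numeric(1))
  high_diff <- vapply(seeds, function(s) tdiff(2, s), numeric(1))
  ## zero perturbation: mean difference within Monte-Carlo noise of zero
  expect_lt(abs(mean(null_diff)),
            3 * sd(null_diff) / sqrt(length(seeds)) + 1e-3)
  ## monotone dose-response: stronger perturbation, lower targeted degree
  expect_lt(mean(high_diff), mean(mid_diff))
  expect_lt(mean(mid_diff), mean(null_diff))
})

test_that("control features are exchangeable after removing generator effects", {
  ## two-sample rank test on residualised regional means, nominal level
  rejections <- vapply(1:20, function(s) {
    p <- generate_parcellation(8, 2, seed = s)
    spec <- cohort_spec(n_nc_train = 24, n_nc_test = 0, n_mci_stable = 0,
                        n_mci_progressive = 0, n_ad = 0, n_regions = 8,
                        n_networks = 2, vertices_per_region = 25,
                        targeted_networks = 1, n_sites = 2, seed = s)
    co <- suppressWarnings(generate_cohort(spec, p))
    y <- vapply(co$features, function(f) mean(f[[1]][, "thickness"]),
                numeric(1))
    m <- co$manifest
    res <- resid(lm(y ~ poly(age, 2) + sex + site, data = m))
    set.seed(1000 + s)
    half <- sample(length(res), length(res) / 2)
    suppressWarnings(
      wilcox.test(res[half], res[-half])$p.value) < 0.01
  }, logical(1))
  expect_lte(sum(rejections), 3)  # nominal 1% level across 20 seeds
})

test_that("survival and ABC couplings respond to their generator dials", {
  ## null hazard for burden: high- and low-burden AD subjects die alike
  df0 <- simulate_clinical_cohort(n = 2000, lhr_count = 0, seed = 3)
  df1 <- simulate_clinical_cohort(n = 2000, lhr_count = 0.05, seed = 3)
  cor0 <- cor(df0$negative_count, df0$death_observed)
  cor1 <- cor(df1$negative_count, df1$death_observed)
  expect_lt(abs(cor0), 0.06)
  expect_gt(cor1, 0.1)
  ## ABC latent scale rises with the count coupling
  dfb <- simulate_clinical_cohort(n = 1500, abc_beta = 0.1,
                                  baseline_hazard = 0.3, seed = 4)
  dead <- !is.na(dfb$abc_score)
  expect_gt(cor(dfb$negative_count[dead], dfb$abc_score[dead]), 0.3)
})

test_that("manifests and vertex features round-trip through text formats", {
  p <- generate_parcellation(16, 4, seed = 2)
  co <- generate_cohort(tiny_spec(seed = 5), p)
  mpath <- withr::local_tempfile(fileext = ".csv")
  write_manifest(co$manifest, mpath)
  m2 <- read_manifest(mpath)
  expect_equal(m2$subject_id, co$manifest$subject_id)
  expect_equal(m2$abc_score, co$manifest$abc_score)
  expect_equal(m2$survival_years, co$manifest$survival_years,
               tolerance = 1e-8)
  fpath <- withr::local_tempfile(fileext = ".tsv")
  write_vertex_features(co$features[[1]], fpath)
  f2 <- read_vertex_features(fpath)
  expect_equal(length(f2), 16)
  expect_equal(unname(f2[["3"]]), unname(co$features[[1]][["3"]]),
               tolerance = 1e-6)
})
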