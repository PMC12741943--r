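## Degrees simulated from the model family with known coefficients are the
## oracle for every fitting check here.

test_that("Gaussian generator coefficients are recovered within 3 SE", {
  sim <- simulate_degree_cohort(2000, 0, n_regions = 3, n_sites = 2,
                                seed = 21)
  m <- fit_normative(sim$train$degrees, sim$train$manifest,
                     normative_config(family = "gaussian"))
  man <- sim$train$manifest
  for (j in 1:3) {
    ## refit on the generator's own parameterisation for a comparable frame
    agec_t <- (man$age - 70) / 10
    truth_mu <- sim$truth$b0[j] + sim$truth$b_age[j] * agec_t +
      sim$truth$b_age2[j] * agec_t^2 +
      sim$truth$b_sex[j] * (man$sex == "M") +
      sim$truth$u[as.integer(sub("site", "", man$site)), j]
    fit <- m$fits[[j]]
    agec_m <- (man$age - m$age_center) / m$age_scale
    est_mu <- fit$beta["intercept"] + fit$beta["age"] * agec_m +
      fit$beta["age2"] * agec_m^2 + fit$beta["sexM"] * (man$sex == "M") +
      fit$u[man$site]
    ## location surface recovered: RMS error small vs residual scale
    resid_sd <- exp(fit$g0)
    expect_lt(sqrt(mean((est_mu - truth_mu)^2)),
              3 * resid_sd / sqrt(nrow(man) / 10))
  }
})

test_that("single-site homoscedastic Gaussian fit equals OLS to 1e-6", {
  set.seed(22)
  n <- 300
  man <- data.frame(subject_id = sprintf("s%03d", 1:n),
                    age = runif(n, 50, 90),
                    sex = sample(c("F", "M"), n, TRUE), site = "site1",
                    stringsAsFactors = FALSE)
  agec <- (man$age - mean(man$age)) / sd(man$age)
  y <- 0.3 - 0.02 * agec - 0.004 * agec^2 + 0.01 * (man$sex == "M") +
    rnorm(n, 0, 0.03)
  deg <- matrix(y, ncol = 1, dimnames = list(man$subject_id, "1"))
  m <- suppressWarnings(fit_normative(
    deg, man, normative_config(family = "gaussian", scale_age = FALSE,
                               min_site_n = 5)))
  ols <- lm(y ~ agec + I(agec^2) + I(as.numeric(man$sex == "M")))
  expect_equal(unname(m$fits[[1]]$beta), unname(coef(ols)),
               tolerance = 1e-6)
  expect_lt(abs(m$fits[[1]]$u[1]), 1e-6)
})

test_that("an injected site offset is recovered within 0.01", {
  sim <- simulate_degree_cohort(2000, 0, n_regions = 2, n_sites = 4,
                                site_shift = c(site3 = 0.05), seed = 23)
  m <- fit_normative(sim$train$degrees, sim$train$manifest,
                     normative_config(family = "gaussian"))
  for (j in 1:2) {
    u <- m$fits[[j]]$u
    tu <- sim$truth$u[, j]
    ## offsets are identified relative to the across-site mean
    err <- (u - tu) - mean(u - tu)
    expect_lt(abs(err["site3"]), 0.01)
  }
})

test_that("self-adaptation leaves offsets near zero; empty sites error", {
  sim <- simulate_degree_cohort(800, 400, n_regions = 3, n_sites = 2,
                                seed = 24)
  m <- fit_normative(sim$train$degrees, sim$train$manifest,
                     normative_config(family = "gaussian"))
  m2 <- adapt_sites(m, sim$test$degrees, sim$test$manifest)
  for (j in 1:3) {
    shift <- m2$fits[[j]]$u[c("site1", "site2")] -
      m$fits[[j]]$u[c("site1", "site2")]
    expect_lt(max(abs(shift)), 0.01)
  }
  expect_error(adapt_sites(m, sim$test$degrees, sim$test$manifest,
                           sites = "site99"), "empty adaptation")
})

test_that("unadapted test sites are refused", {
  sim <- simulate_degree_cohort(600, 100, n_regions = 2, n_sites = 2,
                                seed = 25)
  m <- fit_normative(sim$train$degrees, sim$train$manifest,
                     normative_config(family = "gaussian"))
  man <- sim$test$manifest
  man$site <- "siteX"
  expect_error(compute_deviation_z(m, sim$test$degrees, man),
               "not represented")
})

test_that("Gaussian regions reduce exactly to standardized residuals", {
  sim <- simulate_degree_cohort(600, 0, n_regions = 2, n_sites = 2,
                                seed = 26)
  m <- fit_normative(sim$train$degrees, sim$train$manifest,
                     normative_config(family = "gaussian"))
  fit <- m$fits[[1]]
  man1 <- sim$train$manifest[1, , drop = FALSE]
  agec <- (man1$age - m$age_center) / m$age_scale
  mu <- unname(fit$beta["intercept"] + fit$beta["age"] * agec +
                 fit$beta["age2"] * agec^2 +
                 fit$beta["sexM"] * (man1$sex == "M") + fit$u[man1$site])
  sig <- unname(exp(fit$g0 + fit$g_age * agec + fit$v[man1$site]))
  y <- mu + 1.96 * sig
  deg <- matrix(c(y, 0.3), 1, 2, dimnames = list("x", NULL))
  z <- suppressWarnings(compute_deviation_z(m, deg, man1))
  expect_equal(unname(z[1, 1]), 1.96, tolerance = 1e-6)
})

test_that("deviation Z is strictly increasing in observed degree", {
  sim <- simulate_degree_cohort(600, 0, n_regions = 1, n_sites = 2,
                                family = "shash", seed = 27)
  m <- fit_normative(sim$train$degrees, sim$train$manifest,
                     normative_config(family = "shash"))
  man1 <- sim$train$manifest[1, , drop = FALSE]
  ys <- seq(0.1, 0.6, length.out = 30)
  zs <- vapply(ys, function(y)
    suppressWarnings(compute_deviation_z(
      m, matrix(y, 1, 1), man1))[1, 1], numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("ages outside the training range are flagged, not refused", {
  sim <- simulate_degree_cohort(400, 0, n_regions = 1, n_sites = 2,
                                age_range = c(55, 75), seed = 28)
  m <- fit_normative(sim$train$degrees, sim$train$manifest,
                     normative_config(family = "gaussian"))
  man <- sim$train$manifest[1:2, , drop = FALSE]
  man$age <- c(90, 60)
  expect_warning(z <- compute_deviation_z(
    m, sim$train$degrees[1:2, , drop = FALSE], man), "extrapolat")
  expect_identical(attr(z, "extrapolated"), c(TRUE, FALSE))
  expect_true(all(is.finite(z)))
})

test_that("held-out null Z-scores are standard normal (KS, 20 seeds)", {
  ok <- vapply(1:20, function(s) {
    sim <- simulate_degree_cohort(1500, 200, n_regions = 1, n_sites = 2,
                                  seed = 3000 + s)
    m <- fit_normative(sim$train$degrees, sim$train$manifest,
                       normative_config(family = "gaussian"))
    z <- suppressWarnings(compute_deviation_z(m, sim$test$degrees,
                                              sim$test$manifest))
    suppressWarnings(ks.test(z[, 1], "pnorm"))$p.value > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("SHASH shapes are recovered where the data are skewed", {
  sim <- simulate_degree_cohort(2000, 1000, n_regions = 2, n_sites = 2,
                                family = "shash", seed = 31)
  m <- fit_normative(sim$train$degrees, sim$train$manifest,
                     normative_config(family = "shash"))
  z <- suppressWarnings(compute_deviation_z(m, sim$test$degrees,
                                            sim$test$manifest))
  ## calibrated scoring despite non-Gaussian shapes
  expect_lt(abs(mean(z)), 0.1)
  expect_lt(abs(sd(z) - 1), 0.1)
  ## Z-scores from the Gaussian-only fit are visibly worse calibrated
  mg <- fit_normative(sim$train$degrees, sim$train$manifest,
                      normative_config(family = "gaussian"))
  zg <- suppressWarnings(compute_deviation_z(mg, sim$test$degrees,
                                             sim$test$manifest))
  skew <- function(x) mean(((x - mean(x)) / sd(x))^3)
  expect_lt(abs(skew(as.vector(z))), abs(skew(as.vector(zg))))
})

test_that("model evaluation separates null from strong age signal", {
  sim <- simulate_degree_cohort(800, 0, n_regions = 3, n_sites = 2,
                                seed = 32)
  ## strip the age signal from region 1; amplify it in region 2
  man <- sim$train$manifest
  deg <- sim$train$degrees
  set.seed(33)
  deg[, 1] <- 0.3 + rnorm(nrow(deg), 0, 0.03)
  deg[, 2] <- 0.3 - 0.03 * (man$age - 70) + rnorm(nrow(deg), 0, 0.03)
  m <- fit_normative(deg, man, normative_config(family = "gaussian"))
  ev <- evaluate_model(m, deg, man)
  expect_true(all(ev$explained_var >= 0))       # in-sample bound
  expect_lt(abs(ev$explained_var[1]), 0.02)     # pure noise
  expect_gt(ev$explained_var[2], 0.5)           # strong signal
  expect_true(all(c("z_mean", "z_sd", "pos_rate", "neg_rate") %in%
                    names(ev)))
})
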