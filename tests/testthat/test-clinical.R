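test_that("ANOVA of counts recovers a constructed group effect", {
  set.seed(1)
  man <- data.frame(
    subject_id = sprintf("s%03d", 1:150),
    diagnosis = rep(c("NC_test", "MCI_stable", "AD"), each = 50),
    negative_count = round(c(rnorm(50, 10), rnorm(50, 10), rnorm(50, 15))),
    positive_count = round(rnorm(150, 8)), stringsAsFactors = FALSE)
  res <- anova_counts(counts = NULL, manifest = man)
  expect_lt(res$negative$p, 1e-6)
  expect_gt(res$negative$eta_sq, 0.5)
  tk <- res$negative$tukey
  ad_rows <- grepl("AD", tk$contrast)
  expect_true(all(tk$`p adj`[ad_rows] < 0.01))
  expect_gt(tk$`p adj`[!ad_rows], 0.05)
  ## positive counts: no group structure
  expect_gt(res$positive$p, 0.001)
  expect_lt(res$positive$eta_sq, 0.1)
})

test_that("ANOVA p-values are calibrated under the null", {
  rej <- vapply(1:60, function(s) {
    set.seed(s)
    man <- data.frame(subject_id = sprintf("s%03d", 1:90),
                      diagnosis = rep(c("NC_test", "MCI_stable", "AD"),
                                      each = 30),
                      negative_count = round(rnorm(90, 10, 3)),
                      positive_count = round(rnorm(90, 10, 3)),
                      stringsAsFactors = FALSE)
    anova_counts(NULL, man)$negative$p < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.15)
})

test_that("APOE models recover a pure additive genotype effect", {
  df <- simulate_clinical_cohort(n = 1300,
                                 apoe_effect = c(e2_carrier = 0,
                                                 e4_heterozygote = 2,
                                                 e4_homozygote = 6),
                                 seed = 5)
  res <- apoe_nested_models(NULL, df)
  neg <- res$negative
  cs <- neg$models$base
  est <- coef(cs)["apoee4_homozygote"]
  se <- summary(cs)$coefficients["apoee4_homozygote", 2]
  expect_lt(abs(est - 6), 3 * se)
  ## e2/e4 and missing genotypes were excluded
  expect_false(any(c("e2e4", "missing") %in%
                     neg$models$base$model$apoe))
  expect_s3_class(neg$tukey, "data.frame")
  expect_equal(nrow(neg$tukey), 6)  # 4 genotype groups, all pairs
})

test_that("null APOE effects give coefficients within 3 SE of zero", {
  df <- simulate_clinical_cohort(n = 1300, apoe_effect = c(
    e2_carrier = 0, e4_heterozygote = 0, e4_homozygote = 0), seed = 6)
  res <- apoe_nested_models(NULL, df)
  cs <- summary(res$negative$models$base)$coefficients
  apoe_rows <- grepl("^apoe", rownames(cs))
  expect_true(all(abs(cs[apoe_rows, 1]) < 3 * cs[apoe_rows, 2]))
})

test_that("a seeded genotype-by-sex interaction is detected by the LRT", {
  df <- simulate_clinical_cohort(
    n = 1300, apoe_effect = c(e2_carrier = 0, e4_heterozygote = 2,
                              e4_homozygote = 8),
    apoe_sex_interaction = c(e2_carrier = 0, e4_heterozygote = 0,
                             e4_homozygote = -8), seed = 7)
  res <- apoe_nested_models(NULL, df)
  lrt <- res$negative$lrt
  expect_lt(lrt$p[lrt$model == "sex_interaction"], 0.05)
})

test_that("Cox mortality models recover generator hazards and handle PH violations", {
  df <- simulate_clinical_cohort(n = 1500, lhr_count = 0.02, seed = 8)
  res <- suppressWarnings(cox_mortality(NULL, df))
  ct <- res$full[res$full$term == "count", ]
  se <- (log(ct$ci_upper) - log(ct$ci_lower)) / (2 * 1.96)
  expect_lt(abs(log(ct$hr) - 0.02), 3 * se)
  expect_true(all(res$full$hr > 0))
  expect_equal(sort(names(res$per_group)),
               sort(c("MCI_stable", "MCI_progressive", "AD")))
  expect_true(all(vapply(res$km, function(k)
    k$logrank_p >= 0 && k$logrank_p <= 1, logical(1))))
  ## zero-event group: skipped with a warning
  df2 <- df
  df2$death_observed[df2$diagnosis == "MCI_stable"] <- FALSE
  ## the all-censored group also makes coxph warn about an infinite
  ## diagnosis coefficient; collect everything and check for the skip
  w <- capture_warnings(res2 <- cox_mortality(NULL, df2))
  expect_true(any(grepl("zero events", w)))
  expect_false("MCI_stable" %in% names(res2$per_group))
})

test_that("median splits assign ties to the low-burden group", {
  set.seed(9)
  df <- simulate_clinical_cohort(n = 300, seed = 9)
  df$negative_count <- rep(c(5L, 5L, 9L), 100)  # median 5, heavy ties
  res <- suppressWarnings(cox_mortality(NULL, df))
  for (k in res$km) {
    n_high <- sum(k$fit$n[2])
    expect_lt(n_high, sum(k$fit$n) / 2)  # ties went low
  }
})

test_that("ordinal ABC models recover the latent odds ratio", {
  df <- simulate_clinical_cohort(n = 260, abc_beta = log(2) / 10,
                                 baseline_hazard = 0.4, seed = 10)
  res <- abc_ordinal_models(NULL, df)
  ors <- res$negative$odds_ratios
  ct <- ors[ors$term == "count", ]
  se <- (log(ct$ci_upper) - log(ct$ci_lower)) / (2 * 1.96)
  expect_lt(abs(log(ct$or) - log(2) / 10), 3 * se)
  expect_true(all(c("base", "age_interaction", "ttd_interaction") %in%
                    names(res$negative$aic)))
})

test_that("null ABC coupling keeps the count OR near one", {
  df <- simulate_clinical_cohort(n = 260, abc_beta = 0,
                                 baseline_hazard = 0.4, seed = 11)
  res <- abc_ordinal_models(NULL, df, directions = "negative")
  ors <- res$negative$odds_ratios
  ct <- ors[ors$term == "count", ]
  expect_true(ct$ci_lower < 1 && ct$ci_upper > 1)
})
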