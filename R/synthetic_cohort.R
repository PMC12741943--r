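## Synthetic multi-site cohort generator.
##
## Emulates the statistical structure the downstream analysis assumes:
## vertex-level morphometric features with smooth age/sex trends and
## site-specific location/scale effects in controls, plus network-targeted
## perturbations in disease groups (mean shift away from the cortical
## profile and variance inflation, ordered NC < MCI_stable <
## MCI_progressive < AD) so that MIND degree in targeted regions falls
## below normative expectation. Clinical outcomes (survival, ABC
## neuropathology) are coupled to the injected burden.

## Feature-scale constants (units: mm, 1/mm, mm, mm^2 (log scale-ish), mm^3).
.feat_mean <- c(thickness = 2.5, curvature = 0.12, sulcal_depth = 1.5,
                area = 0.65, volume = 2.1)
.feat_between_sd <- c(thickness = 0.35, curvature = 0.04, sulcal_depth = 0.55,
                      area = 0.18, volume = 0.55)
.feat_vertex_sd <- c(thickness = 0.45, curvature = 0.05, sulcal_depth = 0.70,
                     area = 0.25, volume = 0.70)

#' Specify a synthetic cohort
#'
#' Collects every tunable of the synthetic cohort generator with desk-scale
#' defaults: 60 regions, 100 vertices per region, 4 sites, and roughly 600
#' subjects split across reference controls, held-out controls, stable and
#' progressive MCI, and AD. Disease perturbation magnitudes are expressed in
#' within-region vertex standard deviations and are strictly ordered across
#' groups; targeted networks default to the two association-like networks
#' (labels 6 and 7) in keeping with the predominance of default-mode and
#' frontoparietal involvement in dementia.
#'
#' @param n_nc_train,n_nc_test,n_mci_stable,n_mci_progressive,n_ad Group sizes.
#' @param n_regions,vertices_per_region,n_sites,n_networks Cohort geometry.
#' @param age_range Age span in years subjects are drawn from.
#' @param targeted_networks Integer network labels receiving the disease
#'   perturbation.
#' @param perturbation Named per-group mean-shift magnitudes (vertex-sd units).
#' @param variance_inflation Vertex-sd multiplier slope per unit perturbation.
#' @param target_fraction Probability that each targeted region is actually
#'   perturbed in a given disease subject. Values below 1 reproduce the
#'   characteristic inter-individual heterogeneity of neurodegeneration:
#'   subjects deviate within the same networks but in different regions.
#' @param severity_sdlog Log-sd of the subject-level severity multiplier.
#' @param apoe_freq APOE genotype category frequencies (must sum to 1).
#' @param apoe_severity_boost Multiplicative severity boosts by genotype and
#'   sex (list with `female` and `male` named vectors), expressing the
#'   sex-specific e4 risk gradient.
#' @param survival Exponential proportional-hazards generator parameters:
#'   `baseline_hazard` (events/year), `horizon` (administrative censoring,
#'   years), log-hazard ratios `lhr_age` (per decade), `lhr_male`,
#'   `lhr_burden` (per unit injected burden), per-group `lhr_dx`, and
#'   `dx_decay` (log-hazard decay of the group effect after `dx_break` years,
#'   which induces the proportional-hazards violation for diagnosis seen in
#'   clinical cohorts).
#' @param abc Ordinal neuropathology generator: latent scale
#'   `coef_burden` and `coef_age` plus `thresholds` cutting the latent
#'   logistic variable into ABC scores 0-3; scored only for deceased subjects.
#' @param etiv,euler Head-size and surface-reconstruction quality generators;
#'   `euler$bad_rate` is the fraction of heavy-tailed "bad reconstruction"
#'   subjects the MAD filter should catch.
#' @param min_vertices Minimum vertices per region (validated downstream).
#' @param seed Integer seed; identical spec + seed gives identical cohorts.
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_nc_train = 240, n_nc_test = 60, n_mci_stable = 120,
                        n_mci_progressive = 90, n_ad = 90,
                        n_regions = 60, vertices_per_region = 100,
                        n_sites = 4, n_networks = 7,
                        age_range = c(55, 90),
                        targeted_networks = c(6, 7),
                        perturbation = c(NC = 0, MCI_stable = 0.5,
                                         MCI_progressive = 1.0, AD = 2.0),
                        variance_inflation = 0.1,
                        target_fraction = 0.6,
                        severity_sdlog = 0.3,
                        apoe_freq = c(e3_homozygote = 0.41, e2_carrier = 0.07,
                                      e4_heterozygote = 0.38,
                                      e4_homozygote = 0.10,
                                      e2e4 = 0.02, missing = 0.02),
                        apoe_severity_boost = list(
                          female = c(e3_homozygote = 0, e2_carrier = -0.1,
                                     e4_heterozygote = 0.15,
                                     e4_homozygote = 0.5, e2e4 = 0,
                                     missing = 0),
                          male = c(e3_homozygote = 0, e2_carrier = -0.05,
                                   e4_heterozygote = 0.1,
                                   e4_homozygote = 0.1, e2e4 = 0,
                                   missing = 0)),
                        survival = list(baseline_hazard = 0.04, horizon = 12,
                                        lhr_age = 0.5, lhr_male = 0.3,
                                        lhr_burden = 0,
                                        lhr_dx = c(NC = 0, MCI_stable = 0.3,
                                                   MCI_progressive = 0.8,
                                                   AD = 1.2),
                                        dx_break = 3, dx_decay = 0.5),
                        abc = list(coef_burden = 1.2, coef_age = 0.3,
                                   thresholds = c(-0.8, 0.8, 2.2)),
                        etiv = list(mean = 1.45e6, sex_diff = 1.2e5,
                                    sd = 1.0e5, outlier_rate = 0.005,
                                    outlier_factor = 1.35),
                        euler = list(shape = 2, scale = 15, bad_rate = 0.03,
                                     bad_shape = 3, bad_scale = 80),
                        min_vertices = 20, seed = 1) {
  spec <- list(n_nc_train = n_nc_train, n_nc_test = n_nc_test,
               n_mci_stable = n_mci_stable,
               n_mci_progressive = n_mci_progressive, n_ad = n_ad,
               n_regions = n_regions,
               vertices_per_region = vertices_per_region,
               n_sites = n_sites, n_networks = n_networks,
               age_range = age_range, targeted_networks = targeted_networks,
               perturbation = perturbation,
               variance_inflation = variance_inflation,
               target_fraction = target_fraction,
               severity_sdlog = severity_sdlog,
               apoe_freq = apoe_freq,
               apoe_severity_boost = apoe_severity_boost,
               survival = survival, abc = abc, etiv = etiv, euler = euler,
               min_vertices = min_vertices, seed = .check_seed(seed))
  sizes <- unlist(spec[c("n_nc_train", "n_nc_test", "n_mci_stable",
                         "n_mci_progressive", "n_ad")])
  .assert(all(sizes >= 0) && all(sizes == round(sizes)),
          "group sizes must be non-negative integers")
  .assert(all(perturbation >= 0), "perturbation magnitudes must be >= 0")
  .assert(all(c("NC", "MCI_stable", "MCI_progressive", "AD") %in%
                names(perturbation)),
          "perturbation must be named for NC, MCI_stable, MCI_progressive, AD")
  .assert(abs(sum(apoe_freq) - 1) < 1e-8, "apoe_freq must sum to 1")
  .assert(target_fraction > 0 && target_fraction <= 1,
          "target_fraction must be in (0, 1]")
  .assert(vertices_per_region >= min_vertices,
          "vertices_per_region must be at least min_vertices")
  .assert(n_sites >= 1, "n_sites must be >= 1")
  class(spec) <- "cohort_spec"
  spec
}

## Diagnosis labels in generation order.
.cohort_groups <- function(spec) {
  rep(c("NC_train", "NC_test", "MCI_stable", "MCI_progressive", "AD"),
      times = c(spec$n_nc_train, spec$n_nc_test, spec$n_mci_stable,
                spec$n_mci_progressive, spec$n_ad))
}

## Survival draw under a piecewise-constant hazard where the diagnosis
## log-hazard drops by dx_decay after dx_break years (PH violation).
.draw_survival <- function(rate_early, rate_late, brk, horizon) {
  t1 <- rexp(1, rate_early)
  t <- if (t1 <= brk) t1 else brk + rexp(1, rate_late)
  if (t <= horizon) c(t, 1) else c(horizon, 0)
}

#' Generate a synthetic multi-site cohort
#'
#' Draws a subject manifest and per-subject vertex-level morphometric
#' features under the generative model described in [cohort_spec()].
#' Control features follow region-specific baselines with linear-plus-
#' quadratic age trends, additive sex effects, per-site location offsets and
#' scale multipliers (all region-specific, so they survive the per-subject
#' feature standardisation), and subject-level noise. Disease subjects
#' additionally receive a mean shift along a fixed random direction in
#' feature space plus variance inflation, confined to regions of the
#' targeted networks, scaled by a subject-level severity multiplier that is
#' also modulated by APOE genotype and sex. eTIV, Euler index, APOE group,
#' survival time (exponential proportional hazards with administrative
#' censoring), and ABC neuropathology score (latent-logistic ordinal model,
#' deceased subjects only) are emitted per subject; survival and ABC depend
#' on the injected burden through `spec$survival$lhr_burden` and
#' `spec$abc$coef_burden`.
#'
#' @param spec A [cohort_spec()].
#' @param parcellation Parcellation from [generate_parcellation()] with
#'   `spec$n_regions` rows.
#' @return A list of class `mind_cohort` with elements `manifest` (one row
#'   per subject), `features` (named list: subject -> list of
#'   vertices x 5 feature matrices per region), and `truth` (generator
#'   parameters, including `targeted_regions` and per-subject
#'   `injected_burden`).
#' @export
generate_cohort <- function(spec, parcellation) {
  .assert(inherits(spec, "cohort_spec"), "spec must come from cohort_spec()")
  .validate_parcellation(parcellation)
  .assert(nrow(parcellation) == spec$n_regions,
          "parcellation has ", nrow(parcellation),
          " regions but spec$n_regions is ", spec$n_regions)
  set.seed(spec$seed)

  R <- spec$n_regions
  V <- spec$vertices_per_region
  P <- length(.feature_names)
  groups <- .cohort_groups(spec)
  n <- length(groups)
  sizes <- table(factor(groups, levels = c("NC_train", "NC_test",
                                           "MCI_stable", "MCI_progressive",
                                           "AD")))
  if (any(sizes == 0))
    warning("empty group(s) emitted: ",
            paste(names(sizes)[sizes == 0], collapse = ", "))

  ## ---- generator truth -------------------------------------------------
  bsd <- .feat_between_sd
  vsd <- .feat_vertex_sd
  mu0 <- matrix(rnorm(R * P, rep(.feat_mean, each = R),
                      rep(bsd, each = R)), R, P)
  age_slope <- matrix(rnorm(R * P, rep(-0.05 * bsd, each = R),
                            rep(0.04 * bsd, each = R)), R, P)
  age_quad <- matrix(rnorm(R * P, 0, rep(0.015 * bsd, each = R)), R, P)
  sex_eff <- matrix(rnorm(R * P, 0, rep(0.04 * bsd, each = R)), R, P)
  site_off <- array(rnorm(spec$n_sites * R * P, 0,
                          rep(0.05 * bsd, each = spec$n_sites * R)),
                    c(spec$n_sites, R, P))
  site_scale <- matrix(exp(rnorm(spec$n_sites * P, 0, 0.05)),
                       spec$n_sites, P)
  dir_r <- matrix(rnorm(R * P), R, P)
  dir_r <- dir_r / sqrt(rowSums(dir_r^2))
  targeted <- parcellation$region_id[
    parcellation$network_label %in% spec$targeted_networks]

  ## ---- manifest --------------------------------------------------------
  age_mu <- c(NC_train = 66, NC_test = 66, MCI_stable = 71.5,
              MCI_progressive = 74.5, AD = 73.5)
  age <- pmin(pmax(rnorm(n, age_mu[groups], 8),
                   spec$age_range[1]), spec$age_range[2])
  p_female <- ifelse(groups %in% c("NC_train", "NC_test"), 0.70, 0.53)
  sex <- ifelse(runif(n) < p_female, "F", "M")
  site <- paste0("site", sample.int(spec$n_sites, n, replace = TRUE))
  apoe <- sample(names(spec$apoe_freq), n, replace = TRUE,
                 prob = spec$apoe_freq)

  etiv <- rnorm(n, spec$etiv$mean + spec$etiv$sex_diff * (sex == "M"),
                spec$etiv$sd)
  out_idx <- runif(n) < spec$etiv$outlier_rate
  etiv[out_idx] <- etiv[out_idx] * spec$etiv$outlier_factor

  euler <- -round(rgamma(n, spec$euler$shape, scale = spec$euler$scale))
  bad <- runif(n) < spec$euler$bad_rate
  euler[bad] <- euler[bad] -
    round(rgamma(sum(bad), spec$euler$bad_shape,
                 scale = spec$euler$bad_scale))

  dxg <- sub("NC_(train|test)", "NC", groups)
  boost <- ifelse(sex == "F",
                  spec$apoe_severity_boost$female[apoe],
                  spec$apoe_severity_boost$male[apoe])
  severity <- spec$perturbation[dxg] *
    rlnorm(n, 0, spec$severity_sdlog) * (1 + boost)
  burden <- severity * length(targeted) / max(1, R)

  sv <- spec$survival
  agec <- (age - 70) / 10
  lhr_base <- sv$lhr_age * agec + sv$lhr_male * (sex == "M") +
    sv$lhr_burden * burden
  surv <- t(vapply(seq_len(n), function(i) {
    early <- sv$baseline_hazard * exp(lhr_base[i] + sv$lhr_dx[dxg[i]])
    late <- sv$baseline_hazard *
      exp(lhr_base[i] + sv$lhr_dx[dxg[i]] - sv$dx_decay * (dxg[i] != "NC"))
    .draw_survival(early, late, sv$dx_break, sv$horizon)
  }, numeric(2)))
  survival_years <- surv[, 1]
  death_observed <- surv[, 2] == 1

  abc_lat <- spec$abc$coef_burden * burden + spec$abc$coef_age * agec +
    rlogis(n)
  abc_score <- findInterval(abc_lat, spec$abc$thresholds)
  abc_score[!death_observed] <- NA_integer_
  thal <- pmin(5L, pmax(0L, as.integer(round(abc_score * 5 / 3 +
                                               rnorm(n, 0, 0.5)))))
  braak <- pmin(6L, pmax(0L, as.integer(round(abc_score * 2 +
                                                rnorm(n, 0, 0.7)))))
  cerad <- pmin(3L, pmax(0L, as.integer(round(abc_score +
                                                rnorm(n, 0, 0.4)))))
  thal[is.na(abc_score)] <- NA_integer_
  braak[is.na(abc_score)] <- NA_integer_
  cerad[is.na(abc_score)] <- NA_integer_

  manifest <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = age, sex = sex, site = site, diagnosis = groups,
    eTIV = etiv, euler_index = euler, apoe_group = apoe,
    death_observed = death_observed, survival_years = survival_years,
    abc_score = abc_score, thal = thal, braak = braak, cerad = cerad,
    stringsAsFactors = FALSE
  )

  ## ---- vertex features -------------------------------------------------
  site_idx <- as.integer(sub("site", "", site))
  is_targeted <- parcellation$region_id %in% targeted
  features <- vector("list", n)
  names(features) <- manifest$subject_id
  for (i in seq_len(n)) {
    s <- site_idx[i]
    male <- as.numeric(sex[i] == "M")
    ## which targeted regions this subject actually expresses the disease
    ## effect in: a random subset, giving heterogeneous individual maps
    hit <- is_targeted & (runif(R) < spec$target_fraction)
    subj <- vector("list", R)
    for (r in seq_len(R)) {
      m <- mu0[r, ] + age_slope[r, ] * agec[i] + age_quad[r, ] * agec[i]^2 +
        sex_eff[r, ] * male + site_off[s, r, ] +
        rnorm(P, 0, 0.1 * vsd)
      sdv <- vsd * site_scale[s, ]
      if (hit[r] && severity[i] > 0) {
        m <- m + severity[i] * dir_r[r, ] * vsd
        sdv <- sdv * (1 + spec$variance_inflation * severity[i])
      }
      subj[[r]] <- matrix(rnorm(V * P), V, P) *
        rep(sdv, each = V) + rep(m, each = V)
      colnames(subj[[r]]) <- .feature_names
    }
    names(subj) <- parcellation$region_id
    features[[i]] <- subj
  }

  structure(list(manifest = manifest, features = features,
                 truth = list(mu0 = mu0, age_slope = age_slope,
                              age_quad = age_quad, sex_eff = sex_eff,
                              site_off = site_off, site_scale = site_scale,
                              direction = dir_r,
                              targeted_regions = targeted,
                              severity = severity,
                              injected_burden = burden)),
            class = "mind_cohort")
}

#' Simulate degree-level cohorts from a known normative process
#'
#' Draws subject-by-region weighted-degree tables directly from the
#' distributional regression family the normative model fits: per-region
#' location with linear-plus-quadratic age trends and an additive sex
#' effect, per-site location offsets, log-scale with a linear age term and
#' per-site offsets, and Gaussian or sinh-arcsinh residuals. Training and
#' held-out test subjects are drawn from the identical process, which makes
#' this the reference generator for normative-model recovery and
#' calibration checks.
#'
#' @param n_train,n_test Numbers of training and held-out subjects.
#' @param n_regions,n_sites Table geometry.
#' @param age_range Age span (years).
#' @param family "gaussian" or "shash" residuals.
#' @param site_shift Optional named numeric vector of extra location shifts
#'   applied to specific sites (e.g. `c(site3 = -0.03)`), used for
#'   site-adaptation recovery checks.
#' @param seed Integer seed.
#' @return List with `train` and `test` (each `list(degrees, manifest)`) and
#'   `truth` (all generator coefficients; age centred at 70 and scaled by
#'   10 years).
#' @export
simulate_degree_cohort <- function(n_train, n_test = 0, n_regions = 60,
                                   n_sites = 4, age_range = c(50, 90),
                                   family = c("gaussian", "shash"),
                                   site_shift = NULL, seed = 1) {
  family <- match.arg(family)
  set.seed(.check_seed(seed))
  R <- n_regions
  truth <- list(
    b0 = runif(R, 0.25, 0.45),
    b_age = rnorm(R, -0.02, 0.008),
    b_age2 = rnorm(R, -0.004, 0.002),
    b_sex = rnorm(R, 0, 0.005),
    u = matrix(rnorm(n_sites * R, 0, 0.01), n_sites, R),
    g0 = rep(log(0.03), R),
    g_age = rnorm(R, 0, 0.05),
    v = matrix(rnorm(n_sites * R, 0, 0.1), n_sites, R),
    eps = if (family == "shash") runif(R, -0.4, 0.4) else rep(0, R),
    logdelta = if (family == "shash") runif(R, -0.2, 0.25) else rep(0, R),
    family = family, age_center = 70, age_scale = 10
  )
  if (!is.null(site_shift)) {
    idx <- as.integer(sub("site", "", names(site_shift)))
    .assert(all(idx >= 1 & idx <= n_sites), "site_shift names unknown")
    for (j in seq_along(idx)) truth$u[idx[j], ] <- truth$u[idx[j], ] +
        site_shift[j]
  }

  draw <- function(n, prefix) {
    if (n == 0) return(NULL)
    age <- runif(n, age_range[1], age_range[2])
    sex <- sample(c("F", "M"), n, replace = TRUE)
    site <- paste0("site", sample.int(n_sites, n, replace = TRUE))
    s <- as.integer(sub("site", "", site))
    agec <- (age - truth$age_center) / truth$age_scale
    male <- as.numeric(sex == "M")
    mu <- outer(rep(1, n), truth$b0) + outer(agec, truth$b_age) +
      outer(agec^2, truth$b_age2) + outer(male, truth$b_sex) + truth$u[s, ]
    sig <- exp(outer(rep(1, n), truth$g0) + outer(agec, truth$g_age) +
                 truth$v[s, ])
    z <- matrix(rnorm(n * R), n, R)
    if (family == "shash") {
      eps <- rep(truth$eps, each = n)
      del <- rep(exp(truth$logdelta), each = n)
      z <- sinh((asinh(z) + eps) / del)
    }
    degrees <- mu + sig * z
    rownames(degrees) <- sprintf("%s%04d", prefix, seq_len(n))
    colnames(degrees) <- seq_len(R)
    manifest <- data.frame(subject_id = rownames(degrees), age = age,
                           sex = sex, site = site, stringsAsFactors = FALSE)
    list(degrees = degrees, manifest = manifest)
  }

  list(train = draw(n_train, "T"), test = draw(n_test, "H"), truth = truth)
}

#' Simulate a clinical outcomes cohort with known couplings
#'
#' Generates a subject manifest carrying deviation counts, APOE genotype,
#' survival, and ABC neuropathology whose couplings are fully specified, for
#' recovery checks of the clinical model stages. Negative deviation counts
#' follow a rounded Gaussian linear model in genotype, age, sex and an
#' optional genotype-by-sex interaction; survival follows an exponential
#' proportional-hazards model in the count; the ABC score follows a
#' proportional-odds latent-logistic model in the count.
#'
#' @param n Number of subjects.
#' @param base_count,count_sd Baseline mean and residual sd of the negative
#'   deviation count.
#' @param age_effect Count increase per decade of age.
#' @param apoe_effect Named additive genotype effects on the count
#'   (reference: e3 homozygotes).
#' @param apoe_sex_interaction Named genotype-by-male interaction effects.
#' @param apoe_freq Genotype frequencies (including `e2e4` and `missing`,
#'   which the APOE models exclude).
#' @param diagnosis_probs Group membership probabilities.
#' @param lhr_count Log hazard ratio per unit negative count.
#' @param lhr_age,lhr_male,baseline_hazard,horizon Survival nuisance
#'   parameters (per decade, indicator, events/year, censoring years).
#' @param abc_beta Latent log-odds per unit negative count.
#' @param abc_age,abc_ttd Latent log-odds per decade of age and per year of
#'   time to death.
#' @param abc_age_interaction Latent log-odds per (count x decade) if an
#'   age-dependent pathology coupling is wanted.
#' @param seed Integer seed.
#' @return A manifest-style data.frame with columns used by
#'   [anova_counts()], [apoe_nested_models()], [cox_mortality()] and
#'   [abc_ordinal_models()].
#' @export
simulate_clinical_cohort <- function(n = 1300,
                                     base_count = 18, count_sd = 10,
                                     age_effect = 2,
                                     apoe_effect = c(e2_carrier = 0,
                                                     e4_heterozygote = 2,
                                                     e4_homozygote = 5),
                                     apoe_sex_interaction = c(
                                       e2_carrier = 0, e4_heterozygote = 0,
                                       e4_homozygote = 0),
                                     apoe_freq = c(e3_homozygote = 0.41,
                                                   e2_carrier = 0.07,
                                                   e4_heterozygote = 0.38,
                                                   e4_homozygote = 0.10,
                                                   e2e4 = 0.02,
                                                   missing = 0.02),
                                     diagnosis_probs = c(MCI_stable = 0.4,
                                                         MCI_progressive = 0.2,
                                                         AD = 0.4),
                                     lhr_count = 0, lhr_age = 0.4,
                                     lhr_male = 0.3, baseline_hazard = 0.05,
                                     horizon = 12,
                                     abc_beta = 0, abc_age = 0.3,
                                     abc_ttd = 0,
                                     abc_age_interaction = 0,
                                     seed = 1) {
  set.seed(.check_seed(seed))
  age <- runif(n, 55, 90)
  agec <- (age - 70) / 10
  sex <- sample(c("F", "M"), n, replace = TRUE)
  male <- as.numeric(sex == "M")
  apoe <- sample(names(apoe_freq), n, replace = TRUE, prob = apoe_freq)
  diagnosis <- sample(names(diagnosis_probs), n, replace = TRUE,
                      prob = diagnosis_probs)

  eff <- c(e3_homozygote = 0, apoe_effect, e2e4 = 0, missing = 0)
  inter <- c(e3_homozygote = 0, apoe_sex_interaction, e2e4 = 0, missing = 0)
  neg <- base_count + eff[apoe] + inter[apoe] * male + age_effect * agec +
    rnorm(n, 0, count_sd)
  neg_count <- pmax(0L, as.integer(round(neg)))
  pos_count <- pmax(0L, as.integer(round(
    base_count * 0.6 + rnorm(n, 0, count_sd))))

  rate <- baseline_hazard * exp(lhr_count * neg_count + lhr_age * agec +
                                  lhr_male * male)
  t <- rexp(n, rate)
  death_observed <- t <= horizon
  survival_years <- pmin(t, horizon)

  ttd <- ifelse(death_observed, survival_years, NA_real_)
  lat <- abc_beta * neg_count + abc_age * agec +
    ifelse(is.na(ttd), 0, abc_ttd * ttd) +
    abc_age_interaction * neg_count * agec + rlogis(n)
  lat <- lat - median(lat)
  spread <- max(sd(lat), 1e-8)
  abc_score <- findInterval(lat, spread * c(-0.8, 0, 0.8))
  abc_score[!death_observed] <- NA_integer_

  data.frame(
    subject_id = sprintf("C%04d", seq_len(n)),
    age = age, sex = sex, diagnosis = diagnosis, apoe_group = apoe,
    negative_count = neg_count, positive_count = pos_count,
    death_observed = death_observed, survival_years = survival_years,
    abc_score = abc_score, stringsAsFactors = FALSE
  )
}

#' Write / read a subject manifest as comma-separated text
#'
#' Missing values are encoded as empty fields.
#'
#' @param manifest Manifest data.frame.
#' @param path File path.
#' @return `read_manifest` returns the manifest; `write_manifest` returns
#'   `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if ("death_observed" %in% names(out))
    out$death_observed <- as.logical(out$death_observed)
  out
}

#' Write / read one subject's vertex features as tab-separated text
#'
#' One row per vertex with columns `region_id` plus the five morphometric
#' features.
#'
#' @param subject_features List of vertices x 5 matrices keyed by region.
#' @param path File path.
#' @return `read_vertex_features` returns the per-region matrix list;
#'   `write_vertex_features` returns `path` invisibly.
#' @export
write_vertex_features <- function(subject_features, path) {
  tab <- do.call(rbind, lapply(names(subject_features), function(r) {
    cbind(region_id = as.integer(r),
          as.data.frame(subject_features[[r]]))
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vertex_features
#' @export
read_vertex_features <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  .assert(identical(names(tab), c("region_id", .feature_names)),
          "unexpected vertex feature columns in ", path)
  split_idx <- split(seq_len(nrow(tab)), tab$region_id)
  out <- lapply(split_idx, function(ix) as.matrix(tab[ix, -1]))
  names(out) <- names(split_idx)
  out[order(as.integer(names(out)))]
}
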