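## Clinical models of deviation burden: one-way ANOVA with Tukey HSD,
## nested APOE regressions with AIC/likelihood-ratio selection, Cox
## survival models with proportional-hazards diagnostics, and ordinal
## logistic models of neuropathological (ABC) severity. These are standard
## fits; the package's contract is the exact model set, covariate coding
## (reference levels: e3 homozygotes, female, least-severe diagnosis),
## exclusion rules and selection procedure.

.counts_merge <- function(counts, manifest) {
  if (!all(c("positive_count", "negative_count") %in% names(manifest))) {
    .assert(all(c("subject_id", "positive_count", "negative_count") %in%
                  names(counts)), "counts must come from count_deviations()")
    manifest <- merge(manifest, counts, by = "subject_id", sort = FALSE)
  }
  manifest
}

.count_col <- function(direction) {
  .assert(direction %in% c("positive", "negative"),
          "direction must be 'positive' or 'negative'")
  paste0(direction, "_count")
}

#' One-way ANOVA of deviation counts across diagnostic groups
#'
#' Separate one-way ANOVAs for positive and negative extreme-deviation
#' counts across diagnostic groups, with eta-squared effect sizes and
#' Tukey HSD post hoc pairwise comparisons.
#'
#' @param counts Output of [count_deviations()] (ignored if `manifest`
#'   already carries count columns).
#' @param manifest Manifest with `diagnosis` (and `subject_id` to merge).
#' @param groups Groups to compare (default: all present).
#' @return List with one element per direction, each containing `F`, `df`,
#'   `p`, `eta_sq` and the `tukey` table.
#' @export
anova_counts <- function(counts, manifest, groups = NULL) {
  dat <- .counts_merge(counts, manifest)
  groups <- groups %||% unique(dat$diagnosis)
  dat <- dat[dat$diagnosis %in% groups, , drop = FALSE]
  .assert(length(unique(dat$diagnosis)) >= 2,
          "need at least two groups")
  tab <- table(dat$diagnosis)
  .assert(all(tab >= 2), "every group needs >= 2 subjects")
  out <- list()
  for (dir_ in c("positive", "negative")) {
    y <- dat[[.count_col(dir_)]]
    g <- factor(dat$diagnosis)
    wv <- tapply(y, g, var)
    if (all(wv == 0))
      stop("zero within-group variance in ", dir_, " counts", call. = FALSE)
    fit <- aov(y ~ g)
    s <- summary(fit)[[1]]
    eta <- s[1, "Sum Sq"] / sum(s[, "Sum Sq"])
    tk <- as.data.frame(TukeyHSD(fit)$g)
    tk$contrast <- rownames(tk)
    rownames(tk) <- NULL
    out[[dir_]] <- list(F = s[1, "F value"], df = s[, "Df"],
                        p = s[1, "Pr(>F)"], eta_sq = eta,
                        tukey = tk[, c("contrast", "diff", "lwr", "upr",
                                       "p adj")])
  }
  out
}

.apoe_levels <- c("e3_homozygote", "e2_carrier", "e4_heterozygote",
                  "e4_homozygote")

#' Nested APOE regression models of deviation counts
#'
#' Fits, per deviation direction, the four-candidate nested OLS family with
#' APOE genotype group as a categorical predictor (e3 homozygotes as
#' reference) and age and sex as covariates: (1) additive base model,
#' (2) base + APOE x age, (3) base + APOE x sex, (4) full model with all
#' two- and three-way interactions. Candidates are compared by AIC and by
#' likelihood-ratio tests against the base model; e2/e4 genotypes and
#' missing APOE are excluded. Tukey pairwise genotype contrasts are
#' computed from the additive model.
#'
#' @inheritParams anova_counts
#' @return List per direction with `aic`, `lrt` (vs the base model),
#'   `selected` (model name), `coefficients` (estimate, SE, 95% CI, p for
#'   the selected model) and `tukey` genotype contrasts.
#' @export
apoe_nested_models <- function(counts, manifest) {
  dat <- .counts_merge(counts, manifest)
  .assert("apoe_group" %in% names(dat), "manifest needs apoe_group")
  dat <- dat[!is.na(dat$apoe_group) & dat$apoe_group %in% .apoe_levels, ,
             drop = FALSE]
  dat$apoe <- factor(dat$apoe_group, levels = .apoe_levels)
  dat$sex <- factor(dat$sex, levels = c("F", "M"))
  dat$agec <- (dat$age - 70) / 10
  empty <- setdiff(.apoe_levels, unique(as.character(dat$apoe)))
  if (length(empty) > 0) {
    warning("empty genotype cell(s), contrasts omitted: ",
            paste(empty, collapse = ", "))
    dat$apoe <- droplevels(dat$apoe)
  }
  out <- list()
  for (dir_ in c("positive", "negative")) {
    dat$y <- dat[[.count_col(dir_)]]
    m <- list(
      base = lm(y ~ apoe + agec + sex, data = dat),
      age_interaction = lm(y ~ apoe + agec + sex + apoe:agec, data = dat),
      sex_interaction = lm(y ~ apoe + agec + sex + apoe:sex, data = dat),
      full = lm(y ~ apoe * agec * sex, data = dat))
    aic <- vapply(m, AIC, numeric(1))
    lrt <- do.call(rbind, lapply(names(m)[-1], function(nm) {
      lt <- lmtest::lrtest(m$base, m[[nm]])
      data.frame(model = nm, chisq = lt$Chisq[2], df = lt$Df[2],
                 p = lt$`Pr(>Chisq)`[2], stringsAsFactors = FALSE)
    }))
    selected <- names(which.min(aic))
    cs <- summary(m[[selected]])$coefficients
    ## rank-deficient interaction fits drop aliased terms from summary()
    ci <- confint(m[[selected]])[rownames(cs), , drop = FALSE]
    coefs <- data.frame(term = rownames(cs), estimate = cs[, 1],
                        se = cs[, 2], ci_lower = ci[, 1], ci_upper = ci[, 2],
                        p = cs[, 4], row.names = NULL,
                        stringsAsFactors = FALSE)
    tk <- summary(multcomp::glht(m$base,
                                 linfct = multcomp::mcp(apoe = "Tukey")))
    tukey <- data.frame(contrast = names(tk$test$coefficients),
                        estimate = unname(tk$test$coefficients),
                        se = unname(tk$test$sigma),
                        p_adj = unname(tk$test$pvalues),
                        stringsAsFactors = FALSE)
    out[[dir_]] <- list(aic = aic, lrt = lrt, selected = selected,
                        coefficients = coefs, tukey = tukey,
                        models = m)
  }
  out
}

#' Cox models of mortality on negative deviation burden
#'
#' Negative extreme-deviation count (the direction that tracks clinical
#' progression) as a continuous predictor of mortality: (1) a full Cox
#' model with age, sex, count and diagnostic group; (2) scaled Schoenfeld
#' proportional-hazards diagnostics per covariate; (3) when any covariate
#' violates proportionality (diagnostic p < 0.05), a model stratified by
#' diagnostic group;
#' (4) Cox models fitted separately per diagnostic group; and (5) within-
#' group median splits of the count with Kaplan-Meier curves and log-rank
#' tests (ties at the median go to the low-burden group).
#'
#' @inheritParams anova_counts
#' @param groups Diagnostic groups for the per-group models (default: all
#'   non-control groups present).
#' @return List of class `cox_mortality_result` with `full`, `schoenfeld`,
#'   `stratified` (NULL when no violation), `per_group`, `km`.
#' @export
cox_mortality <- function(counts, manifest, groups = NULL) {
  dat <- .counts_merge(counts, manifest)
  .assert(all(c("survival_years", "death_observed") %in% names(dat)),
          "manifest needs survival_years and death_observed")
  .assert(all(dat$survival_years >= 0, na.rm = TRUE),
          "survival_years must be non-negative")
  dat <- dat[!is.na(dat$survival_years), , drop = FALSE]
  dat$sex <- factor(dat$sex, levels = c("F", "M"))
  dat$agec <- (dat$age - 70) / 10
  dat$count <- dat$negative_count
  dat$dx <- factor(dat$diagnosis,
                   levels = intersect(.severity_levels,
                                      unique(dat$diagnosis)))
  groups <- groups %||%
    setdiff(levels(dat$dx), c("NC", "NC_train", "NC_test"))

  tidy_cox <- function(fit) {
    s <- summary(fit)
    data.frame(term = rownames(s$coefficients),
               hr = s$coefficients[, "exp(coef)"],
               ci_lower = s$conf.int[, "lower .95"],
               ci_upper = s$conf.int[, "upper .95"],
               p = s$coefficients[, "Pr(>|z|)"], row.names = NULL,
               stringsAsFactors = FALSE)
  }

  full <- survival::coxph(
    survival::Surv(survival_years, death_observed) ~ agec + sex + count + dx,
    data = dat)
  zph <- survival::cox.zph(full)
  sch <- data.frame(term = rownames(zph$table), p = zph$table[, "p"],
                    row.names = NULL, stringsAsFactors = FALSE)
  violators <- sch$term[sch$p < 0.05 & sch$term != "GLOBAL"]

  stratified <- NULL
  if ("dx" %in% violators) {
    stratified <- survival::coxph(
      survival::Surv(survival_years, death_observed) ~ agec + sex + count +
        survival::strata(dx), data = dat)
  }

  per_group <- list()
  km <- list()
  for (g in groups) {
    sub <- dat[dat$diagnosis == g, , drop = FALSE]
    if (sum(sub$death_observed) == 0) {
      warning("group ", g, " has zero events; per-group model skipped")
      next
    }
    per_group[[g]] <- tidy_cox(survival::coxph(
      survival::Surv(survival_years, death_observed) ~ agec + sex + count,
      data = sub))
    med <- median(sub$count)
    sub$burden <- factor(ifelse(sub$count > med, "high", "low"),
                         levels = c("low", "high"))
    if (nlevels(droplevels(sub$burden)) == 2) {
      sd_ <- survival::survdiff(
        survival::Surv(survival_years, death_observed) ~ burden, data = sub)
      km[[g]] <- list(
        fit = survival::survfit(
          survival::Surv(survival_years, death_observed) ~ burden,
          data = sub),
        median_split = med, chisq = sd_$chisq,
        logrank_p = pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
    }
  }

  structure(list(full = tidy_cox(full), schoenfeld = sch,
                 ph_violations = violators,
                 stratified = if (!is.null(stratified)) tidy_cox(stratified),
                 per_group = per_group, km = km,
                 fits = list(full = full, stratified = stratified)),
            class = "cox_mortality_result")
}

#' Ordinal logistic models of ABC neuropathology on deviation counts
#'
#' Proportional-odds models of the composite ABC score (0 = no pathology to
#' 3 = high pathology) on the extreme-deviation count, per direction, in
#' the autopsy subset (valid ABC scores only). Three candidates are
#' compared by AIC: a base model with age, sex and time-to-death
#' covariates; a count x age interaction model; and a count x time-to-death
#' interaction model. Outcome levels with zero observations are collapsed
#' with their lower neighbour (with a warning).
#'
#' @inheritParams anova_counts
#' @param directions Deviation directions to model (default both).
#' @return List per direction: `aic`, `selected`, `odds_ratios` (OR, 95%
#'   CI, p per term), `n`.
#' @export
abc_ordinal_models <- function(counts, manifest,
                               directions = c("negative", "positive")) {
  dat <- .counts_merge(counts, manifest)
  .assert("abc_score" %in% names(dat), "manifest needs abc_score")
  dat <- dat[!is.na(dat$abc_score) & dat$abc_score %in% 0:3, , drop = FALSE]
  .assert(nrow(dat) >= 30, "too few subjects with valid ABC scores")
  dat$sex <- factor(dat$sex, levels = c("F", "M"))
  dat$agec <- (dat$age - 70) / 10
  dat$ttd <- dat$survival_years
  lv <- 0:3
  present <- lv %in% unique(dat$abc_score)
  if (!all(present)) {
    warning("ABC level(s) with zero observations collapsed with neighbour: ",
            paste(lv[!present], collapse = ", "))
  }
  dat$abc <- factor(dat$abc_score, levels = lv[present], ordered = TRUE)

  out <- list()
  for (dir_ in directions) {
    dat$count <- dat[[.count_col(dir_)]]
    forms <- list(
      base = abc ~ count + agec + sex + ttd,
      age_interaction = abc ~ count + agec + sex + ttd + count:agec,
      ttd_interaction = abc ~ count + agec + sex + ttd + count:ttd)
    fits <- lapply(forms, function(f)
      MASS::polr(f, data = dat, Hess = TRUE))
    aic <- vapply(fits, AIC, numeric(1))
    selected <- names(which.min(aic))
    s <- summary(fits[[selected]])
    ct <- s$coefficients
    beta <- ct[seq_len(length(coef(fits[[selected]]))), , drop = FALSE]
    pvals <- 2 * pnorm(-abs(beta[, "t value"]))
    ors <- data.frame(term = rownames(beta),
                      or = exp(beta[, "Value"]),
                      ci_lower = exp(beta[, "Value"] -
                                       1.96 * beta[, "Std. Error"]),
                      ci_upper = exp(beta[, "Value"] +
                                       1.96 * beta[, "Std. Error"]),
                      p = pvals, row.names = NULL, stringsAsFactors = FALSE)
    out[[dir_]] <- list(aic = aic, selected = selected, odds_ratios = ors,
                        n = nrow(dat), fits = fits)
  }
  out
}
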