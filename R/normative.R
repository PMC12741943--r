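## Per-region normative models of MIND weighted degree (or any regional
## brain measure): distributional regression with location depending on
## age, age^2 and sex, log-scale depending on age, per-site location and
## log-scale offsets shrunk toward zero by a quadratic (Gaussian-prior)
## penalty, and either Gaussian or sinh-arcsinh (SHASH) residuals. Fitting
## is penalized maximum likelihood; the Gaussian sub-model (skewness 0,
## tail weight 1) is an exactly testable special case, and per region the
## SHASH shape parameters are kept only when an information criterion
## supports them. Deviations are scored as Gaussianized quantile residuals.

#' Configuration for normative model fitting
#'
#' @param family `"auto"` (fit Gaussian; extend to SHASH when the residual
#'   normality pre-test rejects, then select by AIC), `"gaussian"`, or
#'   `"shash"` (always attempt the SHASH fit and select by AIC).
#' @param tau_site_loc,tau_site_scale Prior standard deviations of the
#'   per-site location and log-scale offsets (the pooling precision is
#'   their inverse square). Units of the response and log-scale.
#' @param scale_age Include the linear age term in the log-scale predictor.
#' @param eps_bounds,logdelta_bounds Box bounds for the SHASH skewness and
#'   log tail-weight parameters.
#' @param restarts Number of seeded SHASH starts (the likelihood is
#'   multi-modal).
#' @param shash_test_alpha Significance level of the residual-normality
#'   moment test that triggers the SHASH extension under `family = "auto"`.
#' @param min_site_n Minimum training subjects per site.
#' @param maxit Optimizer iteration cap.
#' @return A list of class `normative_config`.
#' @export
normative_config <- function(family = c("auto", "gaussian", "shash"),
                             tau_site_loc = 0.1, tau_site_scale = 0.5,
                             scale_age = TRUE,
                             eps_bounds = c(-2, 2),
                             logdelta_bounds = c(-1.5, 1.5),
                             restarts = 3, shash_test_alpha = 0.05,
                             min_site_n = 20, maxit = 300) {
  out <- list(family = match.arg(family), tau_site_loc = tau_site_loc,
              tau_site_scale = tau_site_scale, scale_age = scale_age,
              eps_bounds = eps_bounds, logdelta_bounds = logdelta_bounds,
              restarts = restarts, shash_test_alpha = shash_test_alpha,
              min_site_n = min_site_n, maxit = maxit)
  class(out) <- "normative_config"
  out
}

.norm_manifest_check <- function(manifest, n) {
  .assert(is.data.frame(manifest) &&
            all(c("age", "sex", "site") %in% names(manifest)),
          "manifest needs columns age, sex, site")
  .assert(nrow(manifest) == n,
          "manifest rows must match degree-table rows")
  .assert(all(manifest$sex %in% c("F", "M")), "sex must be F or M")
}

.norm_design <- function(manifest, age_center, age_scale) {
  agec <- (manifest$age - age_center) / age_scale
  cbind(intercept = 1, age = agec, age2 = agec^2,
        sexM = as.numeric(manifest$sex == "M"))
}

## SHASH log-density of y given location mu, scale sig, skewness eps and
## tail weight delta (y = mu + sig * sinh((asinh(Z) + eps) / delta)).
.shash_loglik <- function(y, mu, sig, eps, delta) {
  r <- (y - mu) / sig
  t_ <- delta * asinh(r) - eps
  z <- sinh(t_)
  -0.5 * z^2 - 0.5 * log(2 * pi) + log(delta) + .logcosh(t_) -
    0.5 * log1p(r^2) - log(sig)
}

## Parameter packing for one region:
## th = c(b[4], u[S], g0, g_age?, v[S], eps?, logdelta?)
.region_negpll <- function(th, y, X, site_idx, S, cfg, shash) {
  p <- ncol(X)
  b <- th[seq_len(p)]
  u <- th[p + seq_len(S)]
  g0 <- th[p + S + 1]
  off <- p + S + 1
  g_age <- if (cfg$scale_age) th[off + 1] else 0
  if (cfg$scale_age) off <- off + 1
  v <- th[off + seq_len(S)]
  off <- off + S
  eps <- if (shash) th[off + 1] else 0
  delta <- if (shash) exp(th[off + 2]) else 1
  mu <- drop(X %*% b) + u[site_idx]
  eta <- g0 + g_age * X[, "age"] + v[site_idx]
  sig <- exp(eta)
  ll <- if (shash) .shash_loglik(y, mu, sig, eps, delta) else
    dnorm(y, mu, sig, log = TRUE)
  -sum(ll) + sum(u^2) / (2 * cfg$tau_site_loc^2) +
    sum(v^2) / (2 * cfg$tau_site_scale^2)
}

## Closed-form penalized weighted LS for (b, u) given per-subject weights.
.loc_ridge <- function(y, X, site_mat, w, tau) {
  Z <- cbind(X, site_mat)
  P <- diag(c(rep(0, ncol(X)), rep(1 / tau^2, ncol(site_mat))),
            ncol(Z), ncol(Z))
  A <- crossprod(Z * w, Z) + P
  drop(solve(A, crossprod(Z * w, y)))
}

## Penalized Gaussian fit by blockwise iteration: exact weighted ridge for
## the location block, quasi-Newton for the scale block.
.fit_region_gaussian <- function(y, X, site_idx, site_mat, cfg) {
  S <- ncol(site_mat)
  agec <- X[, "age"]
  g <- c(log(max(sd(y), 1e-8)), if (cfg$scale_age) 0, rep(0, S))
  theta_loc <- rep(0, ncol(X) + S)
  scale_obj <- function(g, r) {
    g0 <- g[1]
    g_age <- if (cfg$scale_age) g[2] else 0
    v <- g[(if (cfg$scale_age) 2 else 1) + seq_len(S)]
    eta <- g0 + g_age * agec + v[site_idx]
    sum(eta + r^2 * exp(-2 * eta) / 2) + sum(v^2) / (2 * cfg$tau_site_scale^2)
  }
  scale_grad <- function(g, r) {
    g0 <- g[1]
    g_age <- if (cfg$scale_age) g[2] else 0
    v <- g[(if (cfg$scale_age) 2 else 1) + seq_len(S)]
    eta <- g0 + g_age * agec + v[site_idx]
    d <- 1 - r^2 * exp(-2 * eta)
    gv <- vapply(seq_len(S), function(s) sum(d[site_idx == s]),
                 numeric(1)) + v / cfg$tau_site_scale^2
    c(sum(d), if (cfg$scale_age) sum(d * agec), gv)
  }
  for (it in seq_len(25)) {
    g0 <- g[1]
    g_age <- if (cfg$scale_age) g[2] else 0
    v <- g[(if (cfg$scale_age) 2 else 1) + seq_len(S)]
    w <- exp(-2 * (g0 + g_age * agec + v[site_idx]))
    theta_new <- .loc_ridge(y, X, site_mat, w, cfg$tau_site_loc)
    r <- y - drop(cbind(X, site_mat) %*% theta_new)
    opt <- optim(g, scale_obj, scale_grad, r = r, method = "BFGS",
                 control = list(maxit = cfg$maxit))
    delta_par <- max(abs(theta_new - theta_loc), abs(opt$par - g))
    theta_loc <- theta_new
    g <- opt$par
    if (delta_par < 1e-10) break
  }
  b <- theta_loc[seq_len(ncol(X))]
  u <- theta_loc[ncol(X) + seq_len(S)]
  g0 <- g[1]
  g_age <- if (cfg$scale_age) g[2] else 0
  v <- g[(if (cfg$scale_age) 2 else 1) + seq_len(S)]
  mu <- drop(X %*% b) + u[site_idx]
  sig <- exp(g0 + g_age * agec + v[site_idx])
  loglik <- sum(dnorm(y, mu, sig, log = TRUE))
  npar <- ncol(X) + S + 1 + cfg$scale_age + S
  list(family = "gaussian", beta = setNames(b, colnames(X)),
       u = setNames(u, colnames(site_mat)),
       g0 = g0, g_age = g_age, v = setNames(v, colnames(site_mat)),
       eps = 0, logdelta = 0, loglik = loglik,
       aic = 2 * npar - 2 * loglik, npar = npar, converged = TRUE)
}

.fit_region_shash <- function(y, X, site_idx, site_mat, cfg, gauss_fit) {
  S <- ncol(site_mat)
  p <- ncol(X)
  base <- c(gauss_fit$beta, gauss_fit$u, gauss_fit$g0,
            if (cfg$scale_age) gauss_fit$g_age, gauss_fit$v)
  starts <- list(c(0, 0), c(0.5, -0.3), c(-0.5, 0.3), c(1, 0.3),
                 c(-1, 0.3))[seq_len(max(1, cfg$restarts))]
  lower <- c(rep(-Inf, length(base)), cfg$eps_bounds[1],
             cfg$logdelta_bounds[1])
  upper <- c(rep(Inf, length(base)), cfg$eps_bounds[2],
             cfg$logdelta_bounds[2])
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(c(base, st), .region_negpll, y = y, X = X, site_idx = site_idx,
            S = S, cfg = cfg, shash = TRUE, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = cfg$maxit)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) return(NULL)
  th <- best$par
  off <- p + S + 1 + cfg$scale_age + S
  u <- th[p + seq_len(S)]
  v <- th[(p + S + 1 + cfg$scale_age) + seq_len(S)]
  penalty <- sum(u^2) / (2 * cfg$tau_site_loc^2) +
    sum(v^2) / (2 * cfg$tau_site_scale^2)
  loglik <- -(best$value - penalty)
  npar <- off + 2
  list(family = "shash", beta = setNames(th[seq_len(p)], colnames(X)),
       u = setNames(u, colnames(site_mat)),
       g0 = th[p + S + 1],
       g_age = if (cfg$scale_age) th[p + S + 2] else 0,
       v = setNames(v, colnames(site_mat)),
       eps = th[off + 1], logdelta = th[off + 2], loglik = loglik,
       aic = 2 * npar - 2 * loglik, npar = npar,
       converged = best$convergence == 0)
}

## Moment-based (Jarque-Bera) normality check on standardized residuals.
.normality_p <- function(z) {
  n <- length(z)
  z <- (z - mean(z)) / sd(z)
  s <- mean(z^3)
  k <- mean(z^4)
  jb <- n / 6 * (s^2 + (k - 3)^2 / 4)
  pchisq(jb, df = 2, lower.tail = FALSE)
}

#' Fit per-region normative models on reference controls
#'
#' Fits an independent distributional regression per region of a
#' subject x region degree table: location on age, age squared and sex;
#' log-scale on age; per-site location and log-scale offsets shrunk by a
#' Gaussian-prior penalty (partial pooling); Gaussian or SHASH residuals
#' per [normative_config()]. Under `family = "auto"` each region gets the
#' Gaussian fit, extended to SHASH (with seeded multi-start) only when a
#' residual-normality moment test rejects, and the richer family is kept
#' only if it improves AIC. Regions whose SHASH optimisation fails fall
#' back to the Gaussian sub-model with a warning.
#'
#' @param degrees Subject x region numeric matrix (reference controls).
#' @param manifest Data.frame with `age`, `sex` ("F"/"M"), `site` aligned
#'   with the rows of `degrees`.
#' @param config A [normative_config()].
#' @return Object of class `normative_model`: per-region fits plus the
#'   covariate recipe (age centring/scaling, training age range) and config.
#' @export
fit_normative <- function(degrees, manifest, config = normative_config()) {
  degrees <- as.matrix(degrees)
  .norm_manifest_check(manifest, nrow(degrees))
  .assert(all(is.finite(degrees)), "degrees must be finite")
  site_f <- factor(manifest$site)
  if (nlevels(site_f) < 2)
    warning("reference data covers a single site; site effects are not identifiable beyond the penalty")
  site_n <- table(site_f)
  if (any(site_n < config$min_site_n))
    stop("sites below the minimum per-site n (", config$min_site_n, "): ",
         paste(names(site_n)[site_n < config$min_site_n], collapse = ", "),
         call. = FALSE)

  age_center <- mean(manifest$age)
  age_scale <- max(sd(manifest$age), 1e-8)
  X <- .norm_design(manifest, age_center, age_scale)
  site_idx <- as.integer(site_f)
  site_mat <- 1 * outer(site_idx, seq_len(nlevels(site_f)), "==")
  colnames(site_mat) <- levels(site_f)

  regions <- colnames(degrees) %||% as.character(seq_len(ncol(degrees)))
  fits <- vector("list", ncol(degrees))
  fallback <- character(0)
  for (j in seq_len(ncol(degrees))) {
    y <- degrees[, j]
    gf <- .fit_region_gaussian(y, X, site_idx, site_mat, config)
    fit <- gf
    try_shash <- switch(config$family,
      gaussian = FALSE,
      shash = TRUE,
      auto = {
        mu <- drop(X %*% gf$beta) + gf$u[site_idx]
        sig <- exp(gf$g0 + gf$g_age * X[, "age"] + gf$v[site_idx])
        .normality_p((y - mu) / sig) < config$shash_test_alpha
      })
    if (try_shash) {
      sf <- .fit_region_shash(y, X, site_idx, site_mat, config, gf)
      if (is.null(sf)) fallback <- c(fallback, regions[j])
      else if (sf$aic < gf$aic) fit <- sf
    }
    fits[[j]] <- fit
  }
  if (length(fallback) > 0)
    warning("SHASH optimisation failed; Gaussian fallback used for region(s): ",
            paste(fallback, collapse = ", "))
  names(fits) <- regions
  structure(list(fits = fits, regions = regions,
                 age_center = age_center, age_scale = age_scale,
                 age_range = range(manifest$age),
                 sites = levels(site_f), config = config),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  fam <- table(vapply(x$fits, `[[`, character(1), "family"))
  cat("Normative model:", length(x$fits), "regions |",
      paste(names(fam), fam, collapse = ", "), "\n")
  cat("Sites:", paste(x$sites, collapse = ", "),
      "| training ages", round(x$age_range[1], 1), "-",
      round(x$age_range[2], 1), "\n")
  invisible(x)
}

## Location/scale prediction for one region; site must be adapted.
.region_mu_sigma <- function(fit, X, site) {
  unknown <- setdiff(unique(site), names(fit$u))
  if (length(unknown) > 0)
    stop("site(s) not represented in the model/adaptation data: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  mu <- drop(X %*% fit$beta) + fit$u[site]
  sig <- exp(fit$g0 + fit$g_age * X[, "age"] + fit$v[site])
  list(mu = unname(mu), sigma = unname(sig))
}

#' Adapt a normative model to new sites
#'
#' Transfer calibration: population coefficients and shape parameters are
#' frozen; per-site location and log-scale offsets are re-estimated on
#' adaptation controls under the same Gaussian-prior penalty. Every site to
#' be scored later must appear in the adaptation data.
#'
#' @param model A fitted `normative_model`.
#' @param degrees Subject x region degree matrix of adaptation controls.
#' @param manifest Matching manifest (`age`, `sex`, `site`).
#' @param sites Sites to calibrate (default: all sites present in
#'   `manifest`). A declared site with no adaptation subjects is an error.
#' @return The model with the new sites' offsets in place (existing sites
#'   retained unless re-declared).
#' @export
adapt_sites <- function(model, degrees, manifest,
                        sites = unique(manifest$site)) {
  .assert(inherits(model, "normative_model"), "model must be a normative_model")
  degrees <- as.matrix(degrees)
  .norm_manifest_check(manifest, nrow(degrees))
  .assert(ncol(degrees) == length(model$fits),
          "degree table does not match the model's regions")
  cfg <- model$config
  X <- .norm_design(manifest, model$age_center, model$age_scale)
  for (s in sites) {
    idx <- which(manifest$site == s)
    if (length(idx) == 0)
      stop("empty adaptation set for declared site: ", s, call. = FALSE)
    Xs <- X[idx, , drop = FALSE]
    for (j in seq_along(model$fits)) {
      fit <- model$fits[[j]]
      y <- degrees[idx, j]
      mu0 <- drop(Xs %*% fit$beta)
      eta0 <- fit$g0 + fit$g_age * Xs[, "age"]
      delta <- exp(fit$logdelta)
      obj <- function(p) {
        sig <- exp(eta0 + p[2])
        ll <- if (fit$family == "shash")
          .shash_loglik(y, mu0 + p[1], sig, fit$eps, delta)
        else dnorm(y, mu0 + p[1], sig, log = TRUE)
        -sum(ll) + p[1]^2 / (2 * cfg$tau_site_loc^2) +
          p[2]^2 / (2 * cfg$tau_site_scale^2)
      }
      opt <- optim(c(0, 0), obj, method = "BFGS",
                   control = list(maxit = cfg$maxit))
      fit$u[s] <- opt$par[1]
      fit$v[s] <- opt$par[2]
      model$fits[[j]] <- fit
    }
  }
  model$sites <- union(model$sites, sites)
  model
}

#' Deviation Z-scores against a normative model
#'
#' Scores each subject x region observation as the Gaussianized quantile
#' residual of its normative distribution: `z = sinh(delta * asinh(r) -
#' eps)` with `r = (y - mu) / sigma`, which reduces exactly to the
#' classical standardized residual for Gaussian regions. Ages outside the
#' training range are scored but flagged (attribute `extrapolated`) with a
#' warning.
#'
#' @param model Adapted `normative_model` covering every site in `manifest`.
#' @param degrees Subject x region degree matrix of the test set.
#' @param manifest Matching manifest.
#' @return Subject x region matrix of deviation Z-scores with attribute
#'   `extrapolated` (logical per subject).
#' @export
compute_deviation_z <- function(model, degrees, manifest) {
  .assert(inherits(model, "normative_model"), "model must be a normative_model")
  degrees <- as.matrix(degrees)
  .norm_manifest_check(manifest, nrow(degrees))
  .assert(ncol(degrees) == length(model$fits),
          "degree table does not match the model's regions")
  X <- .norm_design(manifest, model$age_center, model$age_scale)
  z <- matrix(NA_real_, nrow(degrees), ncol(degrees),
              dimnames = list(manifest$subject_id %||% rownames(degrees),
                              model$regions))
  for (j in seq_along(model$fits)) {
    fit <- model$fits[[j]]
    ms <- .region_mu_sigma(fit, X, manifest$site)
    r <- (degrees[, j] - ms$mu) / ms$sigma
    z[, j] <- if (fit$family == "gaussian") r else
      sinh(exp(fit$logdelta) * asinh(r) - fit$eps)
  }
  extrap <- manifest$age < model$age_range[1] |
    manifest$age > model$age_range[2]
  if (any(extrap))
    warning(sum(extrap),
            " subject(s) outside the training age range; Z-scores are extrapolated")
  attr(z, "extrapolated") <- extrap
  attr(z, "threshold_suggested") <- 1.96
  z
}

#' Evaluate a normative model on held-out controls
#'
#' @param model Adapted `normative_model`.
#' @param degrees Subject x region degree matrix of held-out controls.
#' @param manifest Matching manifest.
#' @param threshold Two-sided extreme-deviation threshold for the tail-rate
#'   calibration columns (default 1.96).
#' @return Data.frame with one row per region: chosen family, explained
#'   variance of the location prediction, Z-score mean/sd/skewness, and
#'   per-tail exceedance rates.
#' @export
evaluate_model <- function(model, degrees, manifest, threshold = 1.96) {
  degrees <- as.matrix(degrees)
  .norm_manifest_check(manifest, nrow(degrees))
  X <- .norm_design(manifest, model$age_center, model$age_scale)
  z <- suppressWarnings(compute_deviation_z(model, degrees, manifest))
  out <- lapply(seq_along(model$fits), function(j) {
    fit <- model$fits[[j]]
    ms <- .region_mu_sigma(fit, X, manifest$site)
    y <- degrees[, j]
    ev <- 1 - var(y - ms$mu) / var(y)
    zj <- z[, j]
    data.frame(region = model$regions[j], family = fit$family,
               explained_var = ev, z_mean = mean(zj), z_sd = sd(zj),
               z_skew = mean(((zj - mean(zj)) / sd(zj))^3),
               pos_rate = mean(zj > threshold),
               neg_rate = mean(zj < -threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
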