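#' Fit a precision-weighted binomial mixed model of PFIF
#'
#' Fits the flight-path model: the inside-forest indicator (PFIF) as a
#' Bernoulli-logit response of the distance to the light, the light
#' spectrum, and their interaction, with Gaussian random intercepts on the
#' trajectory identifier (repeated positions of one pass are
#' pseudo-replicates) and on the date (night-to-night and site variation).
#' Each observation's log-likelihood contribution is multiplied by its
#' precision weight `1/I^2`, so imprecise positions count less. One model
#' can be fitted per species group and per spatial subset around the light
#' (all positions, above/under, back/front).
#'
#' Estimation uses the Laplace-approximated marginal likelihood (package
#' \pkg{glmmTMB}); with a 0/1 response the non-integer weights act exactly
#' as multiplicative factors on the per-observation Bernoulli
#' log-likelihood. Inference on coefficients is by Wald z-tests. A null
#' model (intercept plus the same random effects and weights) is fitted for
#' the AIC comparison, and variance explained is reported as marginal and
#' conditional R-squared (latent-scale variance decomposition with logistic
#' distribution variance `pi^2/3`).
#'
#' @param data labelled position table with columns `pfif` (0/1), `D` (m),
#'   `spectrum`, `trajectory_id`, `date`, `weight`, and — when `zone` or
#'   `species_group` filters are used — `zone_vertical`, `zone_horizontal`,
#'   `species_group`.
#' @param reference spectrum level used as intercept (the unlit-control and
#'   white-light parameterizations of the reported tables are
#'   `reference = "dark"` and `reference = "white"`).
#' @param zone spatial subset: `"all"`, `"above"`, `"under"`, `"back"` or
#'   `"front"`.
#' @param species_group optional species-group filter.
#' @param weighted multiply likelihood contributions by `weight`? (`TRUE`
#'   reproduces the published weighting.)
#' @param normalize_weights rescale the weights of the fitted subset to
#'   mean 1? Precision weights only carry relative information; without
#'   rescaling, weights of order `1/I^2` (hundreds when positions are
#'   centimetre-precise) act as artificial replication of each binary
#'   observation, which inflates the random-intercept variance and distorts
#'   the fixed effects. Rescaling leaves a fixed-effects-only fit exactly
#'   unchanged.
#' @param random_effects include the trajectory and date random
#'   intercepts? `FALSE` collapses the model to a weighted logistic
#'   regression (useful for oracle checks and large simulation studies).
#' @param null_model also fit the null model for the AIC comparison?
#' @return An object of class `pfif_glmm`: coefficient table with Wald SEs,
#'   z and p-values, fixed-effect covariance, random-intercept SDs,
#'   log-likelihood, `AIC`, `AIC_null`, marginal/conditional R-squared,
#'   convergence flag and bookkeeping needed by [compute_fpsd()],
#'   [prediction_curve()] and [relevel_contrasts()].
#' @seealso [relevel_contrasts()], [variance_explained()],
#'   [simulated_residual_check()], [compute_fpsd()]
#' @export
fit_pfif_glmm <- function(data, reference = "dark",
                          zone = c("all", "above", "under", "back", "front"),
                          species_group = NULL,
                          weighted = TRUE,
                          normalize_weights = TRUE,
                          random_effects = TRUE,
                          null_model = TRUE) {
  zone <- match.arg(zone)
  need <- c("pfif", "D", "spectrum", "trajectory_id", "date")
  if (weighted) need <- c(need, "weight")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("`data` lacks column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(data)
  if (!is.null(species_group))
    df <- df[df$species_group %in% species_group, , drop = FALSE]
  df <- switch(zone,
    all = df,
    above = df[df$zone_vertical == "above", , drop = FALSE],
    under = df[df$zone_vertical == "under", , drop = FALSE],
    back = df[df$zone_horizontal == "back", , drop = FALSE],
    front = df[df$zone_horizontal == "front", , drop = FALSE]
  )
  df <- df[complete.cases(df[, need]), , drop = FALSE]
  spectra <- unique(as.character(df$spectrum))
  if (length(spectra) < 2)
    stop("the subset must contain at least two spectra; found: ",
         paste(spectra, collapse = ", "))
  if (!reference %in% spectra)
    stop("`reference` ('", reference, "') is not among the spectra present")
  if (weighted && any(!is.finite(df$weight) | df$weight <= 0))
    stop("weights must be finite and positive")
  df$spectrum <- stats::relevel(factor(df$spectrum), ref = reference)
  df$trajectory_id <- factor(df$trajectory_id)
  df$date <- factor(df$date)
  w <- if (weighted) df$weight else rep(1, nrow(df))
  if (weighted && normalize_weights) w <- w / mean(w)
  df$.w <- w

  re_sd <- c(trajectory = 0, date = 0)
  if (random_effects) {
    m <- fit_tmb(pfif ~ D * spectrum + (1 | trajectory_id) + (1 | date), df)
    fe <- glmmTMB::fixef(m)$cond
    V <- as.matrix(vcov(m)$cond)
    vc <- glmmTMB::VarCorr(m)$cond
    re_sd <- c(trajectory = attr(vc$trajectory_id, "stddev")[[1]],
               date = attr(vc$date, "stddev")[[1]])
    converged <- isTRUE(m$fit$convergence == 0) && isTRUE(m$sdr$pdHess)
    ll <- as.numeric(logLik(m))
    npar <- attr(logLik(m), "df")
    aic <- AIC(m)
  } else {
    m <- fit_glm(pfif ~ D * spectrum, df)
    fe <- coef(m)
    V <- as.matrix(vcov(m))
    converged <- isTRUE(m$converged)
    ll <- bernoulli_loglik(df$pfif, stats::fitted(m), df$.w)
    npar <- length(fe)
    aic <- -2 * ll + 2 * npar
  }
  se <- sqrt(diag(V))
  zval <- fe / se
  separated <- isTRUE(any(abs(fe) > 30 | se > 100, na.rm = TRUE)) ||
    anyNA(se)
  if (separated)
    warning("extreme coefficient or SE: possible (quasi-)complete separation; ",
            "interpret this fit with caution")

  X <- stats::model.matrix(~ D * spectrum, df)
  lp_fixed <- drop(X %*% fe[colnames(X)])

  aic_null <- NA_real_
  if (null_model) {
    aic_null <- if (random_effects) {
      AIC(fit_tmb(pfif ~ 1 + (1 | trajectory_id) + (1 | date), df))
    } else {
      m0 <- fit_glm(pfif ~ 1, df)
      -2 * bernoulli_loglik(df$pfif, stats::fitted(m0), df$.w) + 2
    }
  }

  fit <- structure(list(
    coefficients = tibble::tibble(term = names(fe), estimate = unname(fe),
                                  se = unname(se), z = unname(zval),
                                  p = 2 * pnorm(-abs(unname(zval)))),
    beta = fe, vcov = V, re_sd = re_sd,
    logLik = ll, npar = npar,
    AIC = aic, AIC_null = aic_null,
    n_obs = nrow(df),
    converged = converged, separation_flag = separated,
    reference = reference, levels = levels(df$spectrum),
    zone = zone, species_group = species_group,
    weighted = weighted, random_effects = random_effects,
    lp_fixed = lp_fixed,
    frame = df[, c(need, ".w")],
    model = m
  ), class = "pfif_glmm")
  r2 <- variance_explained(fit)
  fit$r2_marginal <- r2[["r2_marginal"]]
  fit$r2_conditional <- r2[["r2_conditional"]]
  fit
}

# weighted Bernoulli log-likelihood (precision weights as multiplicative
# factors on per-observation contributions)
bernoulli_loglik <- function(y, mu, w) {
  mu <- pmin(pmax(mu, 1e-15), 1 - 1e-15)
  sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
}

fit_glm <- function(formula, df) {
  withCallingHandlers(
    # etastart = 0 (mu = 1/2): the default mustart is numerically fragile
    # under large prior weights on a binary response
    stats::glm(formula, data = df, family = stats::binomial(), weights = .w,
               etastart = rep(0, nrow(df)),
               control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("non-integer", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
}

# glmmTMB wrapper; the non-integer-successes warning is the expected
# consequence of precision weights on a 0/1 response
fit_tmb <- function(formula, df) {
  withCallingHandlers(
    glmmTMB::glmmTMB(formula, data = df, family = stats::binomial(),
                     weights = .w),
    warning = function(w) {
      if (grepl("non-integer", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
}

#' @export
print.pfif_glmm <- function(x, ...) {
  cat("Precision-weighted binomial mixed model of PFIF\n")
  cat(sprintf("  subset: %s%s | n = %d | reference spectrum: %s\n",
              x$zone,
              if (is.null(x$species_group)) ""
              else paste0(", ", paste(x$species_group, collapse = "+")),
              x$n_obs, x$reference))
  ct <- x$coefficients
  stars <- cut(ct$p, c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  out <- data.frame(estimate = sprintf("%8.4f", ct$estimate),
                    se = sprintf("%7.4f", ct$se),
                    z = sprintf("%7.2f", ct$z),
                    p = format.pval(ct$p, digits = 3),
                    " " = stars, check.names = FALSE)
  rownames(out) <- ct$term
  print(out)
  if (x$random_effects)
    cat(sprintf("  random-intercept SDs: trajectory %.3f, date %.3f (logit)\n",
                x$re_sd[["trajectory"]], x$re_sd[["date"]]))
  cat(sprintf("  logLik %.2f | AIC %.1f%s | R2 marginal %.3f, conditional %.3f\n",
              x$logLik, x$AIC,
              if (is.na(x$AIC_null)) "" else sprintf(" (null %.1f)", x$AIC_null),
              x$r2_marginal, x$r2_conditional))
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' Re-express a fitted model against another reference spectrum
#'
#' Exact reparameterization of a fitted PFIF model so that another spectrum
#' is the intercept level (the published coefficient tables report both the
#' unlit-control and the white-light parameterizations). Coefficients and
#' their covariance are transformed linearly; the likelihood, AIC,
#' random-effect estimates and every prediction are invariant.
#'
#' @param fit a [fit_pfif_glmm()] result.
#' @param new_reference spectrum level to use as the new intercept.
#' @return a `pfif_glmm` object in the new parameterization.
#' @export
relevel_contrasts <- function(fit, new_reference) {
  stopifnot(inherits(fit, "pfif_glmm"))
  if (!new_reference %in% fit$levels)
    stop("unknown spectrum level '", new_reference, "'")
  if (new_reference == fit$reference) return(fit)
  old_lv <- fit$levels
  new_lv <- c(new_reference, setdiff(old_lv, new_reference))
  nm_old <- names(fit$beta)
  # row r of L gives the new coefficient as a linear combination of old ones
  coef_vec <- function(level, slope = FALSE) {
    v <- setNames(numeric(length(nm_old)), nm_old)
    base <- if (slope) "D" else "(Intercept)"
    v[base] <- 1
    if (level != old_lv[1]) {
      nm <- paste0(if (slope) "D:spectrum" else "spectrum", level)
      v[nm] <- 1
    }
    v
  }
  rows <- list(`(Intercept)` = coef_vec(new_reference))
  for (l in new_lv[-1])
    rows[[paste0("spectrum", l)]] <- coef_vec(l) - coef_vec(new_reference)
  rows$D <- coef_vec(new_reference, slope = TRUE)
  for (l in new_lv[-1])
    rows[[paste0("D:spectrum", l)]] <-
      coef_vec(l, slope = TRUE) - coef_vec(new_reference, slope = TRUE)
  L <- do.call(rbind, rows)
  beta <- drop(L %*% fit$beta)
  V <- L %*% fit$vcov %*% t(L)
  dimnames(V) <- list(rownames(L), rownames(L))
  se <- sqrt(diag(V))
  zval <- beta / se
  out <- fit
  out$beta <- beta
  out$vcov <- V
  out$coefficients <- tibble::tibble(term = names(beta),
                                     estimate = unname(beta),
                                     se = unname(se), z = unname(zval),
                                     p = 2 * pnorm(-abs(unname(zval))))
  out$reference <- new_reference
  out$levels <- new_lv
  out
}

#' Variance explained by a fitted PFIF model
#'
#' Latent-scale variance decomposition for the Bernoulli-logit mixed model:
#' marginal R-squared is the share of latent variance due to the fixed
#' effects, conditional R-squared the share due to fixed plus random
#' effects, with the logistic distribution variance `pi^2/3` completing the
#' denominator.
#'
#' @param fit a [fit_pfif_glmm()] result.
#' @return named numeric: `r2_marginal`, `r2_conditional`.
#' @export
variance_explained <- function(fit) {
  stopifnot(inherits(fit, "pfif_glmm"))
  var_f <- if (length(fit$lp_fixed) > 1) var(fit$lp_fixed) else 0
  var_re <- sum(fit$re_sd^2)
  denom <- var_f + var_re + pi^2 / 3
  c(r2_marginal = var_f / denom,
    r2_conditional = (var_f + var_re) / denom)
}

#' Simulation-based residual uniformity check
#'
#' Lightweight goodness-of-fit diagnostic in the spirit of simulated
#' (randomized-quantile) residual checks: responses are simulated `n_sim`
#' times from the fitted model (fresh random-intercept draws each time),
#' each observation's scaled residual is its randomized quantile within the
#' simulated distribution, and the set of residuals is compared to the
#' standard uniform with a Kolmogorov–Smirnov test. Under a correctly
#' specified model the residuals are approximately U(0, 1).
#'
#' @param fit a [fit_pfif_glmm()] result.
#' @param n_sim number of simulations (must be >= 1).
#' @param seed optional seed for the simulation stream.
#' @return list with `statistic` (KS distance), `p_value`, and the
#'   per-observation `residuals`.
#' @export
simulated_residual_check <- function(fit, n_sim = 250, seed = NULL) {
  stopifnot(inherits(fit, "pfif_glmm"))
  if (!is.numeric(n_sim) || n_sim < 1) stop("`n_sim` must be >= 1")
  n_sim <- as.integer(n_sim)
  if (!is.null(seed)) set.seed(seed)
  df <- fit$frame
  n <- nrow(df)
  y <- df$pfif
  traj <- factor(df$trajectory_id)
  date <- factor(df$date)
  sim_lt <- integer(n)   # count of simulated y below the observed y
  sim_eq <- integer(n)
  for (s in seq_len(n_sim)) {
    u <- fit$lp_fixed
    if (fit$random_effects) {
      u <- u + rnorm(nlevels(traj), 0, fit$re_sd[["trajectory"]])[traj] +
        rnorm(nlevels(date), 0, fit$re_sd[["date"]])[date]
    }
    ysim <- rbinom(n, 1, plogis(u))
    sim_eq <- sim_eq + (ysim == y)
    sim_lt <- sim_lt + (ysim < y)
  }
  # randomized quantile: P(sim < y) + V * P(sim = y)
  resid <- (sim_lt + runif(n) * (sim_eq + 1)) / (n_sim + 1)
  ks <- suppressWarnings(ks.test(resid, "punif"))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       residuals = resid)
}

#' Tidy coefficient table of one or more fitted PFIF models
#'
#' Stacks the coefficient tables of fitted models into the layout of the
#' published results tables: one row per term with estimate, SE and
#' p-value, tagged by spatial subset, species group and reference level.
#'
#' @param ... `pfif_glmm` fits.
#' @return a tibble with columns `term`, `subset`, `group`, `reference`,
#'   `estimate`, `se`, `p`.
#' @export
coef_table <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "pfif_glmm"))
    fits <- fits[[1]]
  do.call(rbind, lapply(fits, function(f) {
    stopifnot(inherits(f, "pfif_glmm"))
    tibble::tibble(
      term = f$coefficients$term,
      subset = f$zone,
      group = if (is.null(f$species_group)) "all"
              else paste(f$species_group, collapse = "+"),
      reference = f$reference,
      estimate = f$coefficients$estimate,
      se = f$coefficients$se,
      p = f$coefficients$p
    )
  }))
}
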