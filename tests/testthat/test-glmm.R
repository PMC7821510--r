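test_that("with zero random-effect variance the fit matches a weighted IRLS oracle", {
  set.seed(40)
  # moderate effects: well-conditioned likelihood, no separation
  d <- simulate_labeled(n = 1500, sigma_traj = 0, sigma_date = 0,
                        beta0 = c(dark = -1.5, red = 1.5, white = 2),
                        beta_d = c(dark = -0.05, red = -0.3, white = -0.3))
  X <- model.matrix(~ D * spectrum,
                    transform(d, spectrum = relevel(factor(spectrum), "dark")))
  # heterogeneous precision weights, zero-variance model: exact weighting check
  w <- d$weight / mean(d$weight)
  beta_oracle <- irls_logistic(X, d$pfif, w)
  fit_glm <- fit_pfif_glmm(d, random_effects = FALSE, null_model = FALSE)
  expect_lt(max(abs(fit_glm$beta[colnames(X)] - beta_oracle)), 1e-3)
  # homogeneous weights, estimated random effects: the mixed model sits near
  # the zero-variance boundary and close to the plain logistic fit (the
  # estimated SD fluctuates above 0 by sampling error on binary data)
  d1 <- d
  d1$weight <- 1
  beta_unw <- irls_logistic(X, d1$pfif)
  fit_mm <- fit_pfif_glmm(d1, null_model = FALSE)
  expect_lt(fit_mm$re_sd[["trajectory"]], 0.5)
  expect_lt(max(abs(fit_mm$beta[colnames(X)] - beta_unw)), 0.15)
})

test_that("precision weights carry only relative information", {
  set.seed(41)
  # mild effects keep the classes overlapping (no quasi-separation)
  d <- simulate_labeled(n = 800, sigma_traj = 0, sigma_date = 0,
                        beta0 = c(dark = -1, red = 1, white = 1.5),
                        beta_d = c(dark = -0.05, red = -0.2, white = -0.2))
  f1 <- fit_pfif_glmm(d, random_effects = FALSE, null_model = FALSE)
  d2 <- d
  d2$weight <- 2 * d$weight
  f2 <- fit_pfif_glmm(d2, random_effects = FALSE, null_model = FALSE)
  # doubling every weight changes nothing after mean-normalization
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)
  # without normalization the estimates still stand, the likelihood doubles
  f1r <- fit_pfif_glmm(d, random_effects = FALSE, null_model = FALSE,
                       normalize_weights = FALSE)
  f2r <- fit_pfif_glmm(d2, random_effects = FALSE, null_model = FALSE,
                       normalize_weights = FALSE)
  expect_equal(f1r$beta, f2r$beta, tolerance = 1e-4)
  expect_equal(f2r$logLik, 2 * f1r$logLik, tolerance = 1e-6)
})

test_that("the model recovers its generating parameters on a rich campaign", {
  set.seed(42)
  d <- simulate_labeled(n = 6000)
  # unweighted fit: clean recovery of the generating parameters
  fit_u <- fit_pfif_glmm(d, weighted = FALSE, null_model = FALSE)
  expect_true(fit_u$converged)
  expect_lt(abs(fit_u$beta[["(Intercept)"]] - (-2)), 1)
  expect_lt(abs(fit_u$beta[["spectrumwhite"]] - 6.5), 1.5)
  expect_lt(abs((fit_u$beta[["D"]] + fit_u$beta[["D:spectrumwhite"]]) - (-0.75)),
            0.2)
  expect_lt(abs(fit_u$re_sd[["trajectory"]] - 1), 0.5)
  # precision-weighted fit: same inference machinery, AIC beats the null
  fit <- fit_pfif_glmm(d)
  expect_true(fit$converged)
  expect_lt(fit$AIC, fit$AIC_null - 50)
  # AIC identity: -2 logLik + 2 (6 fixed effects + 2 variances)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * (6 + 2))
  # monotone predictions under negative slopes
  for (s in c("red", "white")) {
    crv <- prediction_curve(fit, s, seq(0, 20, 0.5))
    expect_true(all(diff(crv$pfif_pred) <= 1e-12))
  }
  # the weighted switch distances stay close to the unweighted ones
  for (s in c("red", "white")) {
    expect_lt(abs(compute_fpsd(fit, s)$fpsd - compute_fpsd(fit_u, s)$fpsd), 1)
  }
})

test_that("releveling the spectrum reference is an exact reparameterization", {
  set.seed(43)
  d <- simulate_labeled(n = 2500)
  fit <- fit_pfif_glmm(d, reference = "dark", null_model = FALSE)
  fit_w <- relevel_contrasts(fit, "white")
  # involution returns the original coefficients exactly
  back <- relevel_contrasts(fit_w, "dark")
  expect_equal(back$beta[names(fit$beta)], fit$beta, tolerance = 1e-12)
  expect_equal(back$vcov[names(fit$beta), names(fit$beta)], fit$vcov,
               tolerance = 1e-12)
  # likelihood-scale quantities are invariant
  expect_identical(fit_w$logLik, fit$logLik)
  expect_identical(fit_w$AIC, fit$AIC)
  # contrast algebra: (white vs red) = (dark vs red) - (dark vs white)
  ref_r <- relevel_contrasts(fit, "red")
  expect_equal(ref_r$beta[["spectrumwhite"]],
               fit$beta[["spectrumwhite"]] - fit$beta[["spectrumred"]],
               tolerance = 1e-12)
  # predictions identical under either parameterization
  for (s in c("dark", "red", "white")) {
    c1 <- prediction_curve(fit, s)
    c2 <- prediction_curve(fit_w, s)
    expect_lt(max(abs(c1$pfif_pred - c2$pfif_pred)), 1e-10)
    expect_lt(max(abs(c1$lo - c2$lo)), 1e-10)
  }
  expect_error(relevel_contrasts(fit, "green"), "unknown")
})

test_that("variance explained follows the latent-scale decomposition", {
  set.seed(44)
  d <- simulate_labeled(n = 1200, sigma_traj = 0, sigma_date = 0)
  fit <- fit_pfif_glmm(d, random_effects = FALSE, null_model = FALSE)
  r2 <- variance_explained(fit)
  # no random effects: marginal and conditional coincide
  expect_equal(r2[["r2_marginal"]], r2[["r2_conditional"]])
  expect_gt(r2[["r2_marginal"]], 0)
  expect_lt(r2[["r2_conditional"]], 1)
  # with no generating effects the fixed part explains almost nothing
  d0 <- simulate_labeled(n = 1500, beta0 = c(dark = 0, red = 0, white = 0),
                         beta_d = c(dark = 0, red = 0, white = 0),
                         sigma_traj = 0, sigma_date = 0)
  fit0 <- fit_pfif_glmm(d0, random_effects = FALSE, null_model = FALSE)
  expect_lt(variance_explained(fit0)[["r2_marginal"]], 0.05)
  # strong fixed effects can reach high marginal R2 without clipping
  full <- fit_pfif_glmm(simulate_labeled(n = 2000), null_model = FALSE)
  expect_true(full$r2_marginal >= 0 && full$r2_conditional <= 1)
  expect_gte(full$r2_conditional, full$r2_marginal)
})

test_that("simulated-residual diagnostics behave like uniform quantiles", {
  set.seed(45)
  d <- simulate_labeled(n = 1200)
  fit <- fit_pfif_glmm(d, null_model = FALSE)
  chk <- simulated_residual_check(fit, n_sim = 200, seed = 1)
  expect_true(all(chk$residuals >= 0 & chk$residuals <= 1))
  # a correctly specified model should not be flagrantly rejected
  expect_gt(chk$p_value, 1e-4)
  expect_error(simulated_residual_check(fit, n_sim = 0), "n_sim")
})

test_that("model fitting validates its inputs", {
  d <- simulate_labeled(n = 200)
  expect_error(fit_pfif_glmm(d[, setdiff(names(d), "weight")]), "weight")
  expect_error(fit_pfif_glmm(d[d$spectrum == "dark", ]), "two spectra")
  expect_error(fit_pfif_glmm(d, reference = "green"), "not among")
  d_bad <- d
  d_bad$weight[1] <- -1
  expect_error(fit_pfif_glmm(d_bad), "positive")
})

test_that("coefficient tables stack fits in the reporting layout", {
  set.seed(46)
  d <- simulate_labeled(n = 1500)
  d$zone_vertical <- ifelse(runif(nrow(d)) < 0.5, "under", "above")
  d$zone_horizontal <- "front"
  f1 <- fit_pfif_glmm(d, null_model = FALSE)
  f2 <- relevel_contrasts(f1, "white")
  tab <- coef_table(f1, f2)
  expect_identical(nrow(tab), 12L)
  expect_identical(unique(tab$reference), c("dark", "white"))
  expect_true(all(c("term", "subset", "group", "estimate", "se", "p")
                  %in% names(tab)))
})
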