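# population-level intercept and slope of one spectrum's logistic
# distance-response (random effects at zero)
spectrum_coef <- function(fit, spectrum) {
  stopifnot(inherits(fit, "pfif_glmm"))
  if (!spectrum %in% fit$levels)
    stop("unknown spectrum level '", spectrum, "'")
  b <- fit$beta
  b0 <- b[["(Intercept)"]]
  bd <- b[["D"]]
  if (spectrum != fit$reference) {
    b0 <- b0 + b[[paste0("spectrum", spectrum)]]
    bd <- bd + b[[paste0("D:spectrum", spectrum)]]
  }
  c(intercept = b0, slope = bd)
}

#' Flight-Path Switch Distance of one spectrum
#'
#' The distance to the light at which bats on average fly as much inside
#' the forest as outside it: the population-level solution of
#' `intercept + slope * d = 0`, i.e. predicted PFIF exactly 0.5, with the
#' random effects at zero. The switch distance is not estimable when the
#' combined slope is non-negative (PFIF does not decrease away from the
#' light) or when the root is negative (the predicted PFIF never reaches
#' 0.5 at a physical distance — insufficient PFIF near the light).
#'
#' @param fit a [fit_pfif_glmm()] result.
#' @param spectrum spectrum level.
#' @return list with `spectrum`, `fpsd` (m, `NA` when not estimable),
#'   `estimable` and `reason`.
#' @examples
#' # intercept 3, slope -0.5 (logit/m) puts the switch at 6 m: 3 - 0.5*6 = 0
#' @export
compute_fpsd <- function(fit, spectrum) {
  cf <- spectrum_coef(fit, spectrum)
  if (!is.finite(cf[["slope"]]) || cf[["slope"]] >= 0) {
    return(list(spectrum = spectrum, fpsd = NA_real_, estimable = FALSE,
                reason = "non-negative distance slope"))
  }
  d <- -cf[["intercept"]] / cf[["slope"]]
  if (d < 0) {
    return(list(spectrum = spectrum, fpsd = NA_real_, estimable = FALSE,
                reason = "insufficient PFIF (negative root)"))
  }
  list(spectrum = spectrum, fpsd = d, estimable = TRUE, reason = "ok")
}

#' Perturbation-onset distance of one spectrum
#'
#' The distance at which the predicted PFIF, walking inward from the far
#' field where it is close to zero, first exceeds a small threshold —
#' i.e. where the behavioural perturbation begins. Solved in closed form on
#' the logit scale: `d = (logit(threshold) - intercept) / slope`. Requires
#' a decreasing predicted curve; for thresholds below 0.5 the onset lies
#' beyond the switch distance.
#'
#' @inheritParams compute_fpsd
#' @param threshold PFIF threshold in (0, 1); default 0.05.
#' @return list with `spectrum`, `threshold`, `onset` (m, `NA` when not
#'   estimable), `estimable` and `reason`.
#' @export
compute_onset <- function(fit, spectrum, threshold = 0.05) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("`threshold` must be strictly inside (0, 1)")
  cf <- spectrum_coef(fit, spectrum)
  if (!is.finite(cf[["slope"]]) || cf[["slope"]] >= 0) {
    return(list(spectrum = spectrum, threshold = threshold, onset = NA_real_,
                estimable = FALSE, reason = "non-negative distance slope"))
  }
  d <- (qlogis(threshold) - cf[["intercept"]]) / cf[["slope"]]
  if (d < 0) {
    return(list(spectrum = spectrum, threshold = threshold, onset = NA_real_,
                estimable = FALSE,
                reason = "predicted PFIF below threshold everywhere"))
  }
  list(spectrum = spectrum, threshold = threshold, onset = d,
       estimable = TRUE, reason = "ok")
}

#' Predicted PFIF curve of one spectrum
#'
#' Population-level inverse-logit predictions over a distance grid with
#' delta-method pointwise confidence intervals (normal on the logit scale,
#' then back-transformed).
#'
#' @inheritParams compute_fpsd
#' @param d_grid distances to the light (m).
#' @param conf_level pointwise confidence level.
#' @return tibble with `spectrum`, `D`, `pfif_pred`, `lo`, `hi`.
#' @export
prediction_curve <- function(fit, spectrum, d_grid = seq(0, 25, by = 0.1),
                             conf_level = 0.95) {
  stopifnot(inherits(fit, "pfif_glmm"))
  if (!spectrum %in% fit$levels)
    stop("unknown spectrum level '", spectrum, "'")
  nm <- names(fit$beta)
  a <- matrix(0, length(d_grid), length(nm), dimnames = list(NULL, nm))
  a[, "(Intercept)"] <- 1
  a[, "D"] <- d_grid
  if (spectrum != fit$reference) {
    a[, paste0("spectrum", spectrum)] <- 1
    a[, paste0("D:spectrum", spectrum)] <- d_grid
  }
  eta <- drop(a %*% fit$beta)
  se <- sqrt(rowSums((a %*% fit$vcov) * a))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    spectrum = spectrum, D = d_grid,
    pfif_pred = plogis(eta),
    lo = plogis(eta - zq * se),
    hi = plogis(eta + zq * se)
  )
}

#' Switch and onset distances with prediction curves for every spectrum
#'
#' Convenience wrapper combining [compute_fpsd()], [compute_onset()] and
#' [prediction_curve()] across the spectra of a fitted model.
#'
#' @inheritParams compute_fpsd
#' @param spectra spectra to evaluate (default: all levels of the fit).
#' @param threshold onset threshold in (0, 1).
#' @param d_grid distance grid for the curves (m).
#' @return object of class `fpsd_result`: a list with `table` (tibble:
#'   `spectrum`, `fpsd`, `onset`, `estimable`, `reason`) and `curves`
#'   (stacked [prediction_curve()] output).
#' @export
fpsd_analysis <- function(fit, spectra = fit$levels, threshold = 0.05,
                          d_grid = seq(0, 25, by = 0.1)) {
  rows <- lapply(spectra, function(s) {
    f <- compute_fpsd(fit, s)
    o <- compute_onset(fit, s, threshold)
    tibble::tibble(spectrum = s, fpsd = f$fpsd, onset = o$onset,
                   estimable = f$estimable, reason = f$reason)
  })
  curves <- lapply(spectra, function(s) prediction_curve(fit, s, d_grid))
  structure(list(table = do.call(rbind, rows),
                 curves = do.call(rbind, curves),
                 threshold = threshold),
            class = "fpsd_result")
}

#' @export
print.fpsd_result <- function(x, ...) {
  cat("Flight-Path Switch Distances (predicted PFIF = 0.5) and onset",
      sprintf("distances (PFIF = %g):\n", x$threshold))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-6s fpsd = %s, onset = %s%s\n", tab$spectrum[i],
                if (is.na(tab$fpsd[i])) "not estimable"
                else sprintf("%.2f m", tab$fpsd[i]),
                if (is.na(tab$onset[i])) "not estimable"
                else sprintf("%.2f m", tab$onset[i]),
                if (tab$estimable[i]) "" else paste0(" (", tab$reason[i], ")")))
  }
  invisible(x)
}
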