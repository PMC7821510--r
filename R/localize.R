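#' Cumulated imprecision of a 3D position
#'
#' The Euclidean norm of the per-axis position standard deviations,
#' `I = sqrt(dx^2 + dy^2 + dz^2)` (m). This single-number imprecision is
#' what the one-metre quality filter and the model weights `1/I^2` use.
#'
#' @param dx,dy,dz per-axis standard deviations (m), vectorized.
#' @return numeric vector of imprecisions (m).
#' @examples
#' cumulated_imprecision(0.6, 0.8, 0)  # 1
#' @export
cumulated_imprecision <- function(dx, dy, dz) {
  if (any(c(dx, dy, dz) < 0, na.rm = TRUE))
    stop("per-axis standard deviations must be >= 0")
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Precision weight of a position
#'
#' The inverse squared cumulated imprecision, `1/I^2`, used as the
#' observation weight in the flight-path models so that precisely
#' localized positions count more.
#'
#' @param I cumulated imprecision (m), strictly positive, vectorized.
#' @return numeric vector of weights.
#' @examples
#' precision_weight(0.5)  # 4
#' @export
precision_weight <- function(I) {
  if (any(!is.finite(I) | I <= 0))
    stop("`I` must be strictly positive; the weight 1/I^2 is undefined otherwise")
  1 / I^2
}

#' Localize calls by time-difference-of-arrival multilateration
#'
#' Converts each call's arrival times at the microphone array into a 3D
#' position with per-axis standard deviations and the cumulated
#' imprecision. Arrival-time differences relative to the first microphone
#' are scaled by the speed of sound into range differences; the source is
#' the generalized-least-squares minimizer of the range-difference
#' residuals, found by a coarse grid search over the monitored volume
#' followed by damped Gauss–Newton refinement. Because every difference
#' shares the reference microphone's noise, the residuals are correlated
#' with correlation matrix `I + 11'` (up to `sigma^2`); the solver uses its
#' inverse as the GLS metric, which makes the estimate equivalent to the
#' maximum-likelihood source location under independent Gaussian
#' arrival-time errors, and makes the linearized covariance
#' `c^2 sigma_t^2 (J' (I + 11')^{-1} J)^{-1}` exactly calibrated under that
#' noise model. Per-axis SDs are the square roots of its diagonal.
#'
#' A microphone array that is (nearly) planar cannot distinguish a source
#' from its mirror image below the microphone plane; solutions below the
#' plane are rejected in favour of the above-plane solution (bats fly above
#' the microphones).
#'
#' @param calls data frame with arrival-time columns `toa_1` ... `toa_m`
#'   (s); a per-call timing-uncertainty column `toa_sigma` (s), when
#'   present, overrides `toa_noise_sd` call by call (detectors estimate it
#'   from call quality). Any other columns are carried through.
#' @param geometry a [scene_geometry()].
#' @param toa_noise_sd SD of the arrival-time noise (s) used for the
#'   covariance scale when `calls` has no `toa_sigma` column. With zero
#'   noise SD the reported imprecision is 0 and the weight is `NA`.
#' @param imprecision_floor systematic per-axis error floor (m), added in
#'   quadrature to the propagated per-axis SDs before computing `I`. The
#'   default 0 reports the pure arrival-time-noise covariance; field
#'   deployments carry additional waveform- and setup-dependent errors
#'   (cross-correlation bias, microphone placement, temperature gradients)
#'   and should set a floor of a few centimetres so reported precisions
#'   stay conservative. When `calls` carries a `call_quality` column (the
#'   detector's relative timing-quality estimate, median 1), the floor is
#'   scaled by it call by call, so reported imprecision is dominated by
#'   call quality rather than by array geometry — the regime field
#'   trajectography systems report.
#' @param grid_xy,grid_zmax,grid_step extent (m) of the initialization grid:
#'   x and y span `grid_xy`, z spans microphone-plane height to `grid_zmax`,
#'   at `grid_step` resolution.
#' @param max_iter,tol Gauss–Newton iteration cap and step-norm tolerance (m).
#' @param chunk_size number of calls scored against the grid at a time
#'   (memory/speed trade-off only).
#' @return A tibble with one row per call: `time` (arrival time at the
#'   reference microphone), `x`, `y`, `z`, `dx`, `dy`, `dz`, `I`, `weight`,
#'   `status` (`"ok"`, `"no_convergence"`, `"singular"` or `"below_plane"`),
#'   `trajectory_id` (`NA`, filled by [link_trajectories()]), and the
#'   carried-through columns.
#' @export
localize_calls <- function(calls, geometry = scene_geometry(),
                           toa_noise_sd = 5e-6,
                           imprecision_floor = 0,
                           grid_xy = c(-15, 15), grid_zmax = 15.5,
                           grid_step = 0.5,
                           max_iter = 100, tol = 1e-9,
                           chunk_size = 2000) {
  toa_cols <- grep("^toa_[0-9]+$", names(calls), value = TRUE)
  m <- nrow(geometry$mic_positions)
  if (length(toa_cols) != m)
    stop("`calls` must have arrival-time columns toa_1..toa_", m,
         " matching the ", m, "-microphone geometry")
  toa <- as.matrix(calls[, paste0("toa_", seq_len(m))])
  if (!all(is.finite(toa))) stop("arrival times must be finite")
  n <- nrow(toa)
  mics <- geometry$mic_positions
  cs <- geometry$speed_of_sound
  # observed range differences relative to microphone 1
  rho <- (toa[, -1, drop = FALSE] - toa[, 1]) * cs
  # GLS metric: inverse correlation of differences sharing the reference mic
  W0 <- diag(m - 1) - matrix(1 / m, m - 1, m - 1)
  plane_z <- mean(mics[, 3])

  ginit <- localization_grid(mics, grid_xy, plane_z, grid_zmax, grid_step, W0)
  starts <- matrix(NA_real_, n, 3)
  for (lo in seq(1, n, by = chunk_size)) {
    hi <- min(lo + chunk_size - 1, n)
    cross <- ginit$GW %*% t(rho[lo:hi, , drop = FALSE])
    best <- vapply(seq_len(hi - lo + 1),
                   function(j) which.min(ginit$q - 2 * cross[, j]), integer(1))
    starts[lo:hi, ] <- ginit$grid[best, , drop = FALSE]
  }

  res <- matrix(NA_real_, n, 7)
  status <- character(n)
  for (i in seq_len(n)) {
    fit <- gn_localize(rho[i, ], mics, W0, starts[i, ], plane_z, max_iter, tol)
    res[i, ] <- c(fit$s, fit$axis_var, fit$obj)
    status[i] <- fit$status
  }
  sigma <- if ("toa_sigma" %in% names(calls)) calls$toa_sigma
           else rep(toa_noise_sd, n)
  sds <- sqrt(pmax(res[, 4:6, drop = FALSE], 0)) * cs * sigma
  if (imprecision_floor > 0) {
    floor_i <- imprecision_floor *
      (if ("call_quality" %in% names(calls)) calls$call_quality else 1)
    sds <- sqrt(sds^2 + floor_i^2)
  }
  I <- sqrt(rowSums(sds^2))
  out <- tibble::tibble(
    time = toa[, 1],
    x = res[, 1], y = res[, 2], z = res[, 3],
    dx = sds[, 1], dy = sds[, 2], dz = sds[, 3],
    I = I,
    weight = ifelse(I > 0, 1 / I^2, NA_real_),
    status = status,
    trajectory_id = NA_character_
  )
  keep <- setdiff(names(calls), toa_cols)
  if (length(keep))
    out <- tibble::as_tibble(cbind(as.data.frame(calls[, keep, drop = FALSE]),
                                   as.data.frame(out)))
  out
}

# precompute the initialization grid and its GLS scoring pieces
localization_grid <- function(mics, grid_xy, plane_z, grid_zmax, grid_step, W0) {
  gx <- seq(grid_xy[1], grid_xy[2], by = grid_step)
  gz <- seq(plane_z + grid_step / 2, grid_zmax, by = grid_step)
  grid <- as.matrix(expand.grid(x = gx, y = gx, z = gz))
  d1 <- sqrt((grid[, 1] - mics[1, 1])^2 + (grid[, 2] - mics[1, 2])^2 +
               (grid[, 3] - mics[1, 3])^2)
  G <- matrix(NA_real_, nrow(grid), nrow(mics) - 1)
  for (k in 2:nrow(mics)) {
    dk <- sqrt((grid[, 1] - mics[k, 1])^2 + (grid[, 2] - mics[k, 2])^2 +
                 (grid[, 3] - mics[k, 3])^2)
    G[, k - 1] <- dk - d1
  }
  GW <- G %*% W0
  list(grid = grid, GW = GW, q = rowSums(GW * G))
}

# predicted range differences and Jacobian at source s
tdoa_model <- function(s, mics) {
  diff <- matrix(s, nrow(mics), 3, byrow = TRUE) - mics
  d <- sqrt(rowSums(diff^2))
  d <- pmax(d, 1e-12)
  u <- diff / d
  list(pred = d[-1] - d[1],
       J = u[-1, , drop = FALSE] -
         matrix(u[1, ], nrow(mics) - 1, 3, byrow = TRUE))
}

gn_objective <- function(s, rho, mics, W0) {
  r <- rho - tdoa_model(s, mics)$pred
  drop(crossprod(r, W0 %*% r))
}

gn_localize <- function(rho, mics, W0, s0, plane_z, max_iter, tol,
                        allow_mirror_restart = TRUE) {
  s <- s0
  obj <- gn_objective(s, rho, mics, W0)
  status <- "no_convergence"
  A <- diag(3)
  for (it in seq_len(max_iter)) {
    mod <- tdoa_model(s, mics)
    r <- rho - mod$pred
    JW <- crossprod(mod$J, W0)
    A <- JW %*% mod$J
    if (!all(is.finite(A)) || rcond(A) < 1e-14) {
      return(list(s = s, axis_var = rep(NA_real_, 3), obj = obj,
                  status = "singular"))
    }
    delta <- solve(A, JW %*% r)
    # step-halving keeps the iteration descending
    lambda <- 1
    repeat {
      s_new <- s + lambda * delta
      obj_new <- gn_objective(s_new, rho, mics, W0)
      if (obj_new <= obj + 1e-15 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    step <- sqrt(sum((lambda * delta)^2))
    s <- s_new
    obj <- obj_new
    if (step < tol) { status <- "ok"; break }
  }
  # a planar array cannot tell a source from its mirror image below the
  # microphone plane; prefer the physical (above-plane) solution
  if (allow_mirror_restart && s[3] < plane_z) {
    mirrored <- gn_localize(rho, mics, W0, c(s[1], s[2], 2 * plane_z - s[3]),
                            plane_z, max_iter, tol, allow_mirror_restart = FALSE)
    if (mirrored$s[3] >= plane_z && mirrored$obj <= obj + 1e-9)
      return(mirrored)
    status <- "below_plane"
  }
  axis_var <- tryCatch(diag(solve(A)), error = function(e) rep(NA_real_, 3))
  list(s = s, axis_var = axis_var, obj = obj, status = status)
}

#' Quality-filter localized positions
#'
#' Applies the two publication filters: positions with a cumulated
#' imprecision of more than `max_imprecision` (default one metre) are
#' discarded, as are positions not included in any bat trajectory (a
#' trajectory needs at least two linked positions). The threshold is
#' strict — a position with `I` exactly at the threshold is kept. Failed
#' localizations (`status` other than `"ok"`) are also discarded. Every
#' discarded record carries a reason code.
#'
#' @param positions position table with columns `I` and `trajectory_id`
#'   (run [link_trajectories()] first), optionally `status`.
#' @param max_imprecision imprecision threshold (m).
#' @return list with tibbles `kept` and `discarded` (the latter with a
#'   `reason` column) and a named integer `counts`.
#' @export
filter_positions <- function(positions, max_imprecision = 1.0) {
  stopifnot(all(c("I", "trajectory_id") %in% names(positions)))
  imprecise <- !is.na(positions$I) & positions$I > max_imprecision
  untracked <- is.na(positions$trajectory_id) | positions$trajectory_id == ""
  failed <- if ("status" %in% names(positions)) positions$status != "ok"
            else rep(FALSE, nrow(positions))
  reason <- rep("", nrow(positions))
  reason[failed] <- "localization_failed"
  reason[imprecise] <- paste0(reason[imprecise],
                              ifelse(reason[imprecise] == "", "", ";"),
                              "imprecision")
  reason[untracked] <- paste0(reason[untracked],
                              ifelse(reason[untracked] == "", "", ";"),
                              "no_trajectory")
  drop <- reason != ""
  discarded <- tibble::as_tibble(positions[drop, , drop = FALSE])
  discarded$reason <- reason[drop]
  list(
    kept = tibble::as_tibble(positions[!drop, , drop = FALSE]),
    discarded = discarded,
    counts = c(n_input = nrow(positions), n_kept = sum(!drop),
               n_discarded = sum(drop))
  )
}
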