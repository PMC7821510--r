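# Independent oracles used to cross-check the package's implementations.
# Everything here is written from first principles on purpose: these
# functions must not share code paths with the package.

# weighted logistic regression by iteratively reweighted least squares
irls_logistic <- function(X, y, w = rep(1, length(y)),
                          tol = 1e-12, max_iter = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    wirls <- w * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    beta_new <- drop(solve(crossprod(X, wirls * X), crossprod(X, wirls * z)))
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

# noiseless arrival times of a source at the array (forward model)
toas_for_source <- function(src, geometry, t_emit = 0) {
  d <- sqrt(colSums((t(geometry$mic_positions) - src)^2))
  t_emit + d / geometry$speed_of_sound
}

# build a call table for a set of sources (rows) with optional TOA noise
calls_for_sources <- function(srcs, geometry, noise = 0, t_emit = NULL) {
  srcs <- matrix(srcs, ncol = 3)
  if (is.null(t_emit)) t_emit <- seq_len(nrow(srcs)) * 2
  toa <- t(vapply(seq_len(nrow(srcs)), function(i) {
    toas_for_source(srcs[i, ], geometry, t_emit[i])
  }, numeric(nrow(geometry$mic_positions))))
  if (noise > 0) toa <- toa + rnorm(length(toa), 0, noise)
  colnames(toa) <- paste0("toa_", seq_len(ncol(toa)))
  tibble::as_tibble(as.data.frame(toa))
}

# exhaustive grid-search localization oracle: global coarse pass over the
# monitored volume, then nested local grids down to 1 cm around the best
# point; minimizes the GLS criterion from an independent implementation
oracle_score <- function(grid, rho, geometry) {
  mics <- geometry$mic_positions
  m <- nrow(mics)
  W0 <- diag(m - 1) - matrix(1 / m, m - 1, m - 1)
  d <- lapply(seq_len(m), function(k) {
    sqrt((grid[, 1] - mics[k, 1])^2 + (grid[, 2] - mics[k, 2])^2 +
           (grid[, 3] - mics[k, 3])^2)
  })
  R <- do.call(cbind, lapply(2:m, function(k) d[[k]] - d[[1]])) -
    matrix(rho, nrow(grid), m - 1, byrow = TRUE)
  rowSums((R %*% W0) * R)
}

# coarse-stage structure precomputed once and reused across many sources
oracle_coarse <- function(geometry, step = 0.5, xy = 16, zmax = 16) {
  g <- seq(-xy, xy, by = step)
  gz <- seq(mean(geometry$mic_positions[, 3]), zmax, by = step)
  grid <- as.matrix(expand.grid(x = g, y = g, z = gz))
  mics <- geometry$mic_positions
  m <- nrow(mics)
  W0 <- diag(m - 1) - matrix(1 / m, m - 1, m - 1)
  d <- lapply(seq_len(m), function(k) {
    sqrt((grid[, 1] - mics[k, 1])^2 + (grid[, 2] - mics[k, 2])^2 +
           (grid[, 3] - mics[k, 3])^2)
  })
  G <- do.call(cbind, lapply(2:m, function(k) d[[k]] - d[[1]]))
  GW <- G %*% W0
  list(grid = grid, GW = GW, q = rowSums(GW * G))
}

grid_localize_oracle <- function(toa, geometry, coarse) {
  rho <- (toa[-1] - toa[1]) * geometry$speed_of_sound
  best <- coarse$grid[which.min(coarse$q - 2 * drop(coarse$GW %*% rho)), ]
  zmin <- mean(geometry$mic_positions[, 3])
  # multi-scale lattice descent down to 1 cm: at each scale, move to the
  # best of the 27 lattice neighbours until the centre wins (the range-
  # difference objective has long flat valleys, so the search must be
  # allowed to travel, not just refine in place)
  off <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  for (h in c(0.25, 0.1, 0.05, 0.02, 0.01)) {
    for (it in 1:400) {
      cand <- sweep(off * h, 2, best, "+")
      cand[, 3] <- pmax(cand[, 3], zmin)
      sc <- oracle_score(cand, rho, geometry)
      k <- which.min(sc)
      if (all(off[k, ] == 0)) break
      best <- cand[k, ]
    }
  }
  best
}

# exact algebraic TDOA solution (spherical-interpolation method): writing
# the source as a linear function of the unknown reference range d1 and
# closing with |s - m1| = d1 gives a quadratic in d1; machine-precision
# exact for noiseless range differences, fully independent of the
# iterative solver
algebraic_localize <- function(toa, geometry) {
  mics <- geometry$mic_positions
  stopifnot(diff(range(mics[, 3])) < 1e-9)  # horizontal-planar array form
  zm <- mics[1, 3]
  m1 <- mics[1, 1:2]
  rho <- (toa[-1] - toa[1]) * geometry$speed_of_sound
  # unknowns (x, y, d1): 2 (mk - m1)_xy . s_xy + 2 rho_k d1 = |mk|^2 - |m1|^2 - rho_k^2
  M <- cbind(2 * sweep(mics[-1, 1:2, drop = FALSE], 2, m1), 2 * rho)
  u <- rowSums(mics[-1, 1:2, drop = FALSE]^2) - sum(m1^2) - rho^2
  sol <- tryCatch(solve(M, u), error = function(e) rep(NA_real_, 3))
  if (anyNA(sol) || sol[3] <= 0) return(rep(NA_real_, 3))
  h2 <- sol[3]^2 - sum((sol[1:2] - m1)^2)
  if (h2 < -1e-9) return(rep(NA_real_, 3))
  c(sol[1], sol[2], zm + sqrt(max(h2, 0)))  # above-plane image
}

# draw random sources within a given range of the array centre, above the
# microphone plane
random_sources <- function(n, rmax = 15, zplane = 0.9) {
  out <- matrix(NA_real_, n, 3)
  k <- 0
  while (k < n) {
    p <- c(runif(1, -rmax, rmax), runif(1, -rmax, rmax),
           runif(1, zplane + 0.3, rmax))
    if (sqrt(sum(p^2)) <= rmax) {
      k <- k + 1
      out[k, ] <- p
    }
  }
  out
}

# minimal hand-built fit object for closed-form switch/onset tests
fake_fit <- function(beta, levels = c("dark", "red", "white"),
                     reference = "dark", vcov = NULL) {
  if (is.null(vcov))
    vcov <- diag(0.01, length(beta), length(beta))
  dimnames(vcov) <- list(names(beta), names(beta))
  structure(list(beta = beta, vcov = vcov, re_sd = c(trajectory = 0, date = 0),
                 logLik = NA_real_, AIC = NA_real_, AIC_null = NA_real_,
                 n_obs = 0L, converged = TRUE, reference = reference,
                 levels = levels, zone = "all", species_group = NULL),
            class = "pfif_glmm")
}

# labelled-position table simulated straight from the occupancy model
# (no acoustics), with precision weights from the campaign's quality model
simulate_labeled <- function(n = 2000, beta0 = c(dark = -2, red = 3, white = 4.5),
                             beta_d = c(dark = -0.05, red = -0.75, white = -0.75),
                             sigma_traj = 1, sigma_date = 0.5,
                             n_nights = 12, traj_size = 15,
                             d_max = 15, quality_sdlog = 0.5) {
  night <- sort(rep_len(seq_len(n_nights), n))
  spectrum <- rep(c("dark", "red", "white"), length.out = n_nights)[night]
  traj <- paste0("n", night, "_t", ceiling(seq_along(night) / traj_size))
  u_t <- rnorm(length(unique(traj)), 0, sigma_traj)
  names(u_t) <- unique(traj)
  u_d <- rnorm(n_nights, 0, sigma_date)
  D <- runif(n, 0, d_max)
  eta <- beta0[spectrum] + beta_d[spectrum] * D + u_t[traj] + u_d[night]
  I <- 0.1386 * exp(rnorm(n, 0, quality_sdlog))
  tibble::tibble(
    pfif = rbinom(n, 1, plogis(eta)),
    D = D, spectrum = spectrum,
    trajectory_id = traj, date = paste0("night_", night),
    I = I, weight = 1 / I^2
  )
}
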