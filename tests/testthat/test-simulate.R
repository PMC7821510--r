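test_that("configuration validation rejects impossible campaigns", {
  expect_error(sim_config(n_nights = 0), "n_nights")
  expect_error(sim_config(spectrum_schedule = character(0)))
  expect_error(sim_config(n_nights = 2, spectrum_schedule = c("dark", "dark")),
               "consecutive")
  expect_error(sim_config(sigma_trajectory = -1), "sigma_trajectory")
  expect_error(sim_config(call_interval = 0), "call_interval")
  expect_error(sim_config(peak_freq_bands = list(a = c(10, 30), b = c(25, 40))),
               "overlap")
  expect_error(sim_config(n_nights = 1, spectrum_schedule = "blue"))
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_nights = 3, n_trajectories_per_night = 4,
                    spectrum_schedule = c("dark", "red", "white"),
                    rng_seed = 99)
  a <- simulate_trajectories(cfg)
  b <- simulate_trajectories(cfg)
  expect_identical(a, b)
  expect_identical(emit_calls(a, cfg), emit_calls(b, cfg))
  # and night streams are independent of the nights that precede them
  cfg1 <- sim_config(n_nights = 1, n_trajectories_per_night = 4,
                     spectrum_schedule = "dark", rng_seed = 99)
  one <- simulate_trajectories(cfg1)
  expect_equal(one$x, a$x[a$night == 1])
})

test_that("inside-forest occupancy realizes the generating logistic model", {
  # flat model at logit 0: occupancy 1/2 everywhere
  cfg <- sim_config(n_nights = 6, n_trajectories_per_night = 60,
                    true_beta0 = c(dark = 0, red = 0, white = 0),
                    true_beta_dist = c(dark = 0, red = 0, white = 0),
                    sigma_trajectory = 0, sigma_date = 0, rng_seed = 5)
  tr <- simulate_trajectories(cfg)
  expect_gt(nrow(tr), 4000)
  expect_lt(abs(mean(tr$inside) - 0.5), 3 * sqrt(0.25 / nrow(tr)) + 0.01)

  # logistic crossing 0.5 at D = 6 for beta0 = 3, slope = -0.5
  cfg <- sim_config(n_nights = 6, n_trajectories_per_night = 80,
                    true_beta0 = c(dark = 3, red = 3, white = 3),
                    true_beta_dist = c(dark = -0.5, red = -0.5, white = -0.5),
                    sigma_trajectory = 0, sigma_date = 0, rng_seed = 6)
  tr <- simulate_trajectories(cfg)
  near <- tr[abs(tr$D - 6) < 0.75, ]
  expect_gt(nrow(near), 300)
  expect_lt(abs(mean(near$inside) - 0.5), 0.06)
  # and the empirical curve tracks the generating curve across bins
  bins <- cut(tr$D, seq(1, 13, by = 2))
  emp <- tapply(tr$inside, bins, mean)
  mid <- seq(2, 12, by = 2)
  expect_lt(max(abs(emp - plogis(3 - 0.5 * mid)), na.rm = TRUE), 0.08)
})

test_that("labels agree with the geometric side of the edge plane", {
  cfg <- sim_config(n_nights = 2, n_trajectories_per_night = 10,
                    spectrum_schedule = c("dark", "red"), rng_seed = 3)
  tr <- simulate_trajectories(cfg)
  expect_identical(tr$inside, label_pfif(tr$x, tr$y, tr$z))
})

test_that("flight paths are kinematically plausible in folded coordinates", {
  cfg <- sim_config(n_nights = 2, n_trajectories_per_night = 15,
                    spectrum_schedule = c("dark", "white"), rng_seed = 8)
  tr <- simulate_trajectories(cfg)
  step_max <- cfg$flight_speed * cfg$call_interval
  for (id in unique(tr$trajectory_id)) {
    p <- tr[tr$trajectory_id == id, ]
    expect_true(all(diff(p$t) > 0))
    d <- sqrt(diff(p$x)^2 + diff(abs(p$y - 4))^2 + diff(p$z)^2)
    expect_lte(max(d), step_max + 1e-9)
  }
})

test_that("trajectory random intercepts induce within-trajectory label correlation", {
  base <- list(n_nights = 4, n_trajectories_per_night = 60,
               spectrum_schedule = c("dark", "red", "dark", "red"),
               true_beta0 = c(dark = 0, red = 0, white = 0),
               true_beta_dist = c(dark = 0, red = 0, white = 0),
               sigma_date = 0, rng_seed = 12)
  within_var <- function(sigma) {
    tr <- simulate_trajectories(do.call(sim_config,
                                        c(base, sigma_trajectory = sigma)))
    # variance of trajectory-level means, against the binomial expectation
    m <- tapply(tr$inside, tr$trajectory_id, mean)
    n <- tapply(tr$inside, tr$trajectory_id, length)
    var(m) - mean(0.25 / n)
  }
  expect_gt(within_var(2), within_var(0) + 0.02)
})

test_that("emitted calls carry band-limited peak frequencies and exact geometry", {
  cfg <- sim_config(n_nights = 2, n_trajectories_per_night = 8,
                    spectrum_schedule = c("dark", "red"),
                    toa_noise_sd = 0, rng_seed = 21)
  tr <- simulate_trajectories(cfg)
  calls <- emit_calls(tr, cfg)
  expect_identical(nrow(calls), nrow(tr))
  for (g in names(cfg$peak_freq_bands)) {
    b <- cfg$peak_freq_bands[[g]]
    pf <- calls$peak_freq[calls$species_group_true == g]
    expect_true(all(pf >= b[1] & pf <= b[2]))
  }
  expect_true(all(calls$peak_freq >= 8 & calls$peak_freq <= 160))
  # noiseless arrival-time differences equal geometric path differences / c
  geom <- scene_geometry()
  i <- c(1, 15, 40)
  for (k in i) {
    expected <- toas_for_source(c(tr$x[k], tr$y[k], tr$z[k]), geom, tr$t[k])
    got <- as.numeric(calls[k, paste0("toa_", 1:4)])
    expect_equal(got, unname(expected), tolerance = 1e-12)
  }
  expect_error(emit_calls(tr[0, ], cfg), "non-empty")
})

test_that("a symmetric source gives identical arrival times at symmetric microphones", {
  # four microphones on a square: any source on the vertical axis is
  # equidistant from all of them, so all arrival-time differences vanish
  sq <- rbind(c(1, 0, 0.5), c(0, 1, 0.5), c(-1, 0, 0.5), c(0, -1, 0.5))
  geom <- scene_geometry(mic_positions = sq)
  toa <- toas_for_source(c(0, 0, 6), geom)
  expect_equal(max(toa) - min(toa), 0)
})
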