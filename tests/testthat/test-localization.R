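test_that("cumulated imprecision is the Euclidean norm of the per-axis SDs", {
  expect_equal(cumulated_imprecision(0, 0, 0), 0)
  expect_equal(cumulated_imprecision(0.6, 0.8, 0), 1.0)
  expect_equal(cumulated_imprecision(0.5, 0.5, 0.5), sqrt(0.75))
  expect_equal(round(cumulated_imprecision(0.5, 0.5, 0.5), 4), 0.8660)
  expect_equal(cumulated_imprecision(c(0.6, 0.5), c(0.8, 0.5), c(0, 0.5)),
               c(1, sqrt(0.75)))
  expect_error(cumulated_imprecision(-0.1, 0, 0), ">= 0")
})

test_that("precision weight is the inverse squared imprecision", {
  expect_equal(precision_weight(1), 1)
  expect_equal(precision_weight(0.5), 4)
  expect_equal(precision_weight(0.1), 100)
  expect_equal(precision_weight(c(1, 2)), c(1, 0.25))
  expect_error(precision_weight(0), "positive")
  expect_error(precision_weight(-1), "positive")
})

test_that("noiseless calls are localized back to their sources", {
  geom <- scene_geometry()
  set.seed(10)
  srcs <- random_sources(20, rmax = 12)
  srcs <- rbind(srcs, c(4, 4, 4))
  calls <- calls_for_sources(srcs, geom)
  pos <- localize_calls(calls, geom, toa_noise_sd = 0)
  err <- sqrt((pos$x - srcs[, 1])^2 + (pos$y - srcs[, 2])^2 +
                (pos$z - srcs[, 3])^2)
  expect_true(all(pos$status == "ok"))
  expect_lt(max(err), 1e-6)
  # zero noise: imprecision 0, weight undefined
  expect_true(all(pos$I == 0))
  expect_true(all(is.na(pos$weight)))
})

test_that("a zero-TDOA call resolves onto the array's vertical symmetry axis", {
  sq <- rbind(c(1, 0, 0.5), c(0, 1, 0.5), c(-1, 0, 0.5), c(0, -1, 0.5))
  geom <- scene_geometry(mic_positions = sq)
  toa <- rep(0.03, 4)  # all arrival-time differences zero
  call <- tibble::as_tibble(as.data.frame(t(setNames(toa, paste0("toa_", 1:4)))))
  pos <- localize_calls(call, geom, toa_noise_sd = 0, grid_zmax = 12)
  expect_lt(sqrt(pos$x^2 + pos$y^2), 0.05)
})

test_that("every localized position lies above the microphone plane", {
  geom <- scene_geometry()
  set.seed(11)
  srcs <- random_sources(30, rmax = 12)
  calls <- calls_for_sources(srcs, geom, noise = 2e-5)
  pos <- localize_calls(calls, geom, toa_noise_sd = 2e-5)
  expect_true(all(pos$z >= mean(geom$mic_positions[, 3]) - 1e-9))
})

test_that("reported imprecision grows with source distance", {
  geom <- scene_geometry()
  sg <- 1e-5
  set.seed(12)
  dist <- c(5, 9, 13, 17)
  meanI <- vapply(dist, function(r) {
    src <- c(r * 0.55, r * 0.55, sqrt(max(r^2 * (1 - 2 * 0.55^2), 1)) + 0.9)
    calls <- calls_for_sources(matrix(src, 20, 3, byrow = TRUE), geom,
                               noise = sg)
    pos <- localize_calls(calls, geom, toa_noise_sd = sg, grid_zmax = 20,
                          grid_xy = c(-20, 20))
    mean(pos$I)
  }, numeric(1))
  expect_true(all(diff(meanI) > 0))
})

test_that("per-call timing uncertainty and the quality-scaled floor shape reported SDs", {
  geom <- scene_geometry()
  src <- c(5, 4, 3)
  calls <- calls_for_sources(matrix(src, 2, 3, byrow = TRUE), geom)
  calls$toa_sigma <- c(1e-5, 2e-5)
  pos <- localize_calls(calls, geom)
  # doubling a call's timing uncertainty doubles its per-axis SDs
  expect_equal(pos$dx[2] / pos$dx[1], 2, tolerance = 1e-6)
  expect_equal(pos$I[2] / pos$I[1], 2, tolerance = 1e-6)
  # the floor adds in quadrature and scales with the call-quality factor
  calls$call_quality <- c(1, 2)
  posf <- localize_calls(calls, geom, imprecision_floor = 0.05)
  expect_equal(posf$dx, sqrt(pos$dx^2 + (0.05 * c(1, 2))^2), tolerance = 1e-9)
  expect_true(all(posf$I > pos$I))
})

test_that("the quality filter applies the one-metre rule and trajectory membership", {
  pos <- tibble::tibble(
    time = 1:6, x = 0, y = 0, z = 2,
    I = c(0.5, 1.2, 0.9, 1.0, 0.3, 2.5),
    trajectory_id = c("a", "a", "a", "b", NA, NA),
    status = "ok"
  )
  out <- filter_positions(pos)
  # I of exactly 1.0 is kept (strictly-more-than-one-metre rule)
  expect_identical(sort(out$kept$time), c(1L, 3L, 4L))
  expect_identical(unname(out$counts),
                   c(6L, 3L, 3L))
  reasons <- out$discarded$reason[order(out$discarded$time)]
  expect_identical(reasons,
                   c("imprecision", "no_trajectory", "imprecision;no_trajectory"))
  # positions not in any trajectory are all discarded
  iso <- pos
  iso$trajectory_id <- NA_character_
  expect_identical(nrow(filter_positions(iso)$kept), 0L)
  # failed localizations carry their own reason
  pos$status[1] <- "no_convergence"
  expect_match(filter_positions(pos)$discarded$reason[1], "localization_failed")
})
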