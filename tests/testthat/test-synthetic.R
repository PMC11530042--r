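test_that("noisy release measurements stay valid cumulative profiles", {
  p <- default_release_profile()
  # zero magnitude: identity
  p0 <- gen_release_measurements(p, noise_spec("gaussian_relative", 0,
                                               seed = 1))
  expect_equal(p0$fraction, p$fraction)
  # monotone, bounded, zero at t = 0 for any seed
  for (s in 1:100) {
    q <- gen_release_measurements(p, noise_spec("gaussian_relative", 0.05,
                                                seed = s))
    expect_true(all(diff(q$fraction) >= 0))
    expect_true(all(q$fraction >= 0 & q$fraction <= 1))
    expect_equal(q$fraction[1], 0)
  }
  # determinism per seed
  q1 <- gen_release_measurements(p, noise_spec("gaussian_relative", 0.05,
                                               seed = 7))
  q2 <- gen_release_measurements(p, noise_spec("gaussian_relative", 0.05,
                                               seed = 7))
  expect_identical(q1$fraction, q2$fraction)
})

test_that("relative noise has the folded-normal mean deviation", {
  # 5% gaussian relative noise: E|dev| = 0.05 sqrt(2/pi) = 4% of signal
  p <- peppas_profile(0.1, 0.5, 81, n_points = 10, total_load = 1,
                      coating_area = 1)
  devs <- unlist(lapply(1:1000, function(s) {
    q <- gen_release_measurements(p, noise_spec("gaussian_relative", 0.05,
                                                seed = s))
    abs(q$fraction[-1] - p$fraction[-1]) / p$fraction[-1]
  }))
  expect_equal(mean(devs), 0.05 * sqrt(2 / pi), tolerance = 0.01 / 0.04)
})

test_that("in vivo series sampling interpolates truth and respects the horizon", {
  times <- c(0, 2, 4, 8); values <- c(0, 10, 20, 5)
  m0 <- gen_invivo_series(times, values, noise_spec(magnitude = 0,
                                                    seed = 1), c(1, 3, 6))
  expect_equal(m0$concentration, c(5, 15, 12.5)) # exact linear interpolation
  expect_equal(attr(m0, "units"), "ug/mL")
  expect_error(gen_invivo_series(times, values,
                                 noise_spec(magnitude = 0, seed = 1),
                                 c(1, 9)), "horizon")
  m1 <- gen_invivo_series(times, values,
                          noise_spec(magnitude = 0.1, seed = 5), c(1, 3, 6))
  m2 <- gen_invivo_series(times, values,
                          noise_spec(magnitude = 0.1, seed = 5), c(1, 3, 6))
  expect_identical(m1, m2)
})

test_that("denser sampling improves recovered peak-time accuracy", {
  tt <- seq(0, 24, by = 0.01)
  truth <- tt * exp(-tt / 3) # peak at t = 3
  err <- vapply(c(5, 9, 25), function(ns) {
    s <- gen_invivo_series(tt, truth, noise_spec(magnitude = 0, seed = 1),
                           seq(0, 24, length.out = ns))
    abs(s$time[which.max(s$concentration)] - 3)
  }, numeric(1))
  expect_true(all(diff(err) <= 0))
})

test_that("parameter recovery closes the simulate-noise-fit loop", {
  # elimination half-life from a noisy decay series (5% relative noise)
  tt <- seq(2, 24, by = 1)
  truth <- 100 * 0.5^(tt / 4)
  m <- gen_invivo_series(c(0, tt), c(100, truth),
                         noise_spec("gaussian_relative", 0.05, seed = 1), tt)
  expect_equal(fit_half_life(m$time, m$concentration), 4, tolerance = 0.05)
  # release exponent from a noisy cumulative profile at default noise
  pr <- default_release_profile()
  prn <- gen_release_measurements(pr, noise_spec("gaussian_relative", 0.02,
                                                 seed = 3))
  fit <- fit_release_exponent(prn$times, prn$fraction)
  expect_equal(fit$n, 0.5, tolerance = 0.05)
  expect_error(fit_half_life(1:5, c(1, 2, 3, 4, 5)), "not decaying")
})

test_that("the fixture suite runs the whole pipeline from one directory", {
  dir <- tempfile()
  paths <- gen_fixture_suite(seed = 101, dir = dir)
  expect_true(all(file.exists(unlist(paths))))
  for (sc in c("in_vitro_release", "agar", "rat_tibia",
               "human_bone_plate")) {
    res <- run_scenario(read_scenario_config(paths[[sc]]))
    led <- if (!is.null(res$result)) res$result else res$tissue
    expect_lt(mass_balance(led)$closure_error, 1e-6)
  }
  # different seeds: same config structure, different profile values
  dir2 <- tempfile()
  paths2 <- gen_fixture_suite(seed = 202, dir = dir2)
  p1 <- read_release_profile(paths$release_profile)
  p2 <- read_release_profile(paths2$release_profile)
  expect_equal(p1$times, p2$times)
  expect_false(identical(p1$fraction, p2$fraction))
  c1 <- read_scenario_config(paths$agar)
  c2 <- read_scenario_config(paths2$agar)
  expect_identical(names(unlist(c1)), names(unlist(c2)))
})
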