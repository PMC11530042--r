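test_that("clearance increment matches the per-element half-life term", {
  cl <- clearance_spec(4)
  expect_equal(decay_increment(100, 0.01, cl),
               0.01 * log(0.5) / 4 * 100 * 0.5^(0.01 / 4), tolerance = 1e-12)
  expect_equal(decay_increment(100, 0.01, cl), -0.17299, tolerance = 1e-4)
  expect_identical(decay_increment(0, 0.3, cl), 0)
  expect_identical(decay_increment(50, 0.3, clearance_disabled()), 0)
  # repeated small increments converge to exact halving over one half-life
  C <- 100
  for (i in seq_len(800)) C <- C + decay_increment(C, 0.005, cl)
  expect_equal(C, 50, tolerance = 0.005)
})

test_that("single explicit steps reproduce hand-evaluated updates", {
  # uniform field, sealed ends: zero Laplacian, steady state
  g <- uniform_grid(5)
  st <- list(t = 0, C = rep(7, 5))
  out <- step_1d(st, g, bc_no_flux(), bc_no_flux(), dt = 0.1)
  expect_equal(out$C, rep(7, 5))
  # two cells, D*dt/dx^2 = 0.1: (100, 0) -> (90, 10)
  g2 <- uniform_grid(2, dx = 1, D = 1)
  out2 <- step_1d(list(t = 0, C = c(100, 0)), g2, bc_no_flux(), bc_no_flux(),
                  dt = 0.1)
  expect_equal(out2$C, c(90, 10))
  # single flux cell gains dt/dx * J in consistent units (ug/mL carries the
  # mL per mm^3 factor)
  g1 <- uniform_grid(1, dx = 1, D = 1)
  out1 <- step_1d(list(t = 0, C = 0), g1, bc_flux_in(function(t) 1),
                  bc_no_flux(), dt = 0.1)
  expect_equal(out1$C, 0.1 * 1 / (1 * 1e-3))
})

test_that("time steps beyond the stability bound are rejected loudly", {
  g <- uniform_grid(20, dx = 1, D = 1)
  bound <- max_stable_timestep(1, 1)
  expect_error(step_1d(list(t = 0, C = numeric(20)), g, bc_no_flux(),
                       bc_no_flux(), dt = 3 * bound),
               class = "vanco_stability_error")
  expect_error(simulate_1d(g, t_end = 10, dt = 3 * bound),
               class = "vanco_stability_error")
  # at 0.99x the bound an impulse stays non-negative and finite for 1e4 steps
  dt <- 0.99 * bound
  C0 <- numeric(20); C0[3] <- 1000
  res <- simulate_1d(g, clearance = clearance_spec(4), t_end = 1e4 * dt,
                     dt = dt, record_every = 1e4 * dt, C0 = C0)
  expect_true(all(is.finite(res$states)))
  expect_true(all(res$states >= 0))
})

test_that("constant-concentration boundary reproduces the erfc profile", {
  D <- 1; dx <- 0.1; tv <- 4
  g <- grid_1d(layer_spec("medium", 40, D), dx)
  res <- simulate_1d(g, left = bc_dirichlet(100), right = bc_no_flux(),
                     t_end = tv, record_every = tv, C0 = 0)
  C <- res$states[nrow(res$states), ]
  x <- g$positions - g$positions[1] # distance from the pinned cell center
  ref <- 100 * pracma::erfc(x / (2 * sqrt(D * tv)))
  sel <- ref / 100 > 0.05
  expect_lt(max(abs(C[sel] - ref[sel]) / ref[sel]), 0.01)
})

test_that("decay-only run matches exact exponential halving", {
  g <- uniform_grid(4, D = 1e-9) # uniform field: diffusion term inert anyway
  res <- simulate_1d(g, clearance = clearance_spec(4), t_end = 24, dt = 0.01,
                     record_every = 24, C0 = 100)
  expect_equal(res$states[2, 1] / 100, 0.5^6, tolerance = 0.005)
  # the multiplicative mode is exact at any dt
  res2 <- simulate_1d(g, clearance = clearance_spec(4, mode = "exact"),
                      t_end = 24, dt = 0.04, record_every = 24, C0 = 100)
  expect_equal(res2$states[2, 1] / 100, 0.5^6, tolerance = 1e-10)
})

test_that("zero initial field without influx stays identically zero", {
  g <- uniform_grid(10)
  res <- simulate_1d(g, clearance = clearance_spec(4), t_end = 5,
                     record_every = 1)
  expect_true(all(res$states == 0))
  expect_equal(mass_balance(res)$closure_error, 0)
})

test_that("the mass ledger closes with and without clearance", {
  g <- uniform_grid(10, dx = 0.5, D = 0.5)
  res <- simulate_1d(g, left = bc_flux_in(function(t) 0.3), t_end = 12,
                     record_every = 12, C0 = 2)
  mb <- mass_balance(res)
  expect_lt(mb$closure_error, 1e-6)
  expect_equal(mb$influx, 0.3 * g$A * 12, tolerance = 1e-9)
  expect_equal(mb$stored - mb$stored_initial, mb$influx, tolerance = 1e-9)
  # with clearance: influx = cleared + stored change
  resc <- simulate_1d(g, left = bc_flux_in(function(t) 0.3),
                      clearance = clearance_spec(3), t_end = 12,
                      record_every = 12, C0 = 2)
  mbc <- mass_balance(resc)
  expect_lt(mbc$closure_error, 1e-6)
  expect_gt(mbc$cleared, 0)
  expect_equal(mbc$influx, mbc$cleared + mbc$stored - mbc$stored_initial,
               tolerance = 1e-9 * mbc$influx)
  expect_gte(mbc$closure_error, 0)
})

test_that("negative initial concentrations are rejected", {
  g <- uniform_grid(5)
  expect_error(simulate_1d(g, t_end = 1, C0 = c(1, -1, 1, 1, 1)),
               "non-negative")
})

test_that("flux is continuous across a layer interface at steady state", {
  layers <- list(layer_spec("fast", 1, 1), layer_spec("slow", 1, 0.2))
  g <- grid_1d(layers, dx = 0.125)
  J <- 0.1
  res <- simulate_1d(g, left = bc_flux_in(function(t) J), right = bc_sink(),
                     t_end = 200, record_every = 200)
  C <- res$states[nrow(res$states), ]
  i <- sum(g$cell_layer == "fast") # interface between cells i and i+1
  faceD <- 2 / (1 / g$cell_D[i] + 1 / g$cell_D[i + 1])
  flux_interface <- faceD * (C[i] - C[i + 1]) / g$dx * ML_PER_MM3
  expect_equal(flux_interface, J, tolerance = 1e-6)
})

test_that("halving dx converges the 24-h near-plate average", {
  avg_near <- function(dx) {
    g <- grid_1d(layer_spec("tissue", 3, 0.7488), dx)
    res <- simulate_1d(g, left = bc_flux_in(function(t) 0.2),
                       clearance = clearance_spec(4), t_end = 24,
                       record_every = 24)
    mean(res$states[2, seq_len(round(1 / dx))])
  }
  a <- vapply(c(0.5, 0.25, 0.125), avg_near, numeric(1))
  d1 <- abs(a[2] - a[1]); d2 <- abs(a[3] - a[2])
  expect_lt(d2, d1)
})
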