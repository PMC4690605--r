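# Reaction-diffusion engine.  Small grids with D = 0.01 mm^2/h, k = 1/h
# (xi = 0.1 mm) keep these unit checks fast; the printed study parameters
# are exercised in the acceptance tests.

p_small <- fkpp_params(0.01, 1)

test_that("nine-point stencil is exact on quadratics and matches direct arithmetic", {
  xs <- seq(0, 0.4, by = 0.1)
  u <- outer(xs, xs, function(x, y) x^2 + y^2)
  lap <- nine_point_laplacian(u, 0.1)
  expect_equal(lap[2:4, 2:4], matrix(4, 3, 3))
  expect_equal(nine_point_laplacian(matrix(7, 5, 5), 0.1)[2:4, 2:4],
               matrix(0, 3, 3))
  # quartic: compare against the printed stencil evaluated longhand
  h <- 0.1
  u4 <- outer(xs, xs, function(x, y) x^4)
  x0 <- xs[3]
  direct <- (-20 * x0^4 +
             2 * ((x0 + h)^4 + (x0 - h)^4) +        # four corners, y-shift irrelevant
             4 * ((x0 + h)^4 + (x0 - h)^4 + 2 * x0^4)) / (6 * h^2)
  expect_equal(nine_point_laplacian(u4, h)[3, 3], direct, tolerance = 1e-12)
  expect_error(nine_point_laplacian(matrix(0, 2, 2), 0.1), class = "size_error")
})

test_that("growth-rate inversion and its scaling identities", {
  expect_equal(estimate_growth_rate(0.2, 0.0144), 0.2^2 / (4 * 0.0144))
  expect_equal(round(estimate_growth_rate(0.2, 0.0144), 1), 0.7)
  expect_equal(estimate_growth_rate(0.4, 0.0144),
               4 * estimate_growth_rate(0.2, 0.0144))
  # round trip through the dispersion relation
  expect_equal(2 * sqrt(0.0144 * estimate_growth_rate(0.2, 0.0144)), 0.2)
  expect_error(estimate_growth_rate(-1, 1), class = "parameter_error")
})

test_that("Stokes-Einstein estimate reproduces the printed virion diffusivity", {
  D <- stokes_einstein_D(60, 0.692, 310.15)
  expect_equal(round(D, 2), 0.04)
  expect_equal(stokes_einstein_D(120, 0.692, 310.15), D / 2, tolerance = 1e-12)
  # about a factor three above the agar proxy value
  expect_lt(abs(D / 0.0144 - 2.8), 0.2)
})

test_that("initial condition builds a ramp that develops and degenerate fields stay fixed", {
  env <- environment_make(c(0.1, 3), list())
  st <- initial_condition(env, p_small, y0_front = 0.8)
  ramp <- st$u[1, st$y > 0.8 & st$y < 0.8 + 2 * p_small$xi]
  expect_true(all(ramp > 0 & ramp < 1))

  # u = 0 and u = 1 are fixed points of the dynamics
  st0 <- st; st0$u[] <- 0
  r0 <- fkpp_integrate(st0, 2)
  expect_equal(max(abs(r0$states[[1]]$u)), 0)
  st1 <- st; st1$u[] <- 1
  r1 <- fkpp_integrate(st1, 2)
  expect_lt(max(abs(r1$states[[1]]$u - 1)), 1e-9)

  # an obstacle too close to the founding line is flagged
  envo <- environment_make(c(2, 3), list(make_rhombus(0.3, 0.3, c(1, 1.4))))
  expect_warning(initial_condition(envo, p_small, y0_front = 1),
                 class = "front_development")
})

test_that("integration preserves density bounds and the comparison principle", {
  env <- environment_make(c(0.2, 5), list())
  st <- initial_condition(env, p_small, y0_front = 0.8)
  run <- fkpp_integrate(st, c(1, 2, 4, 6))
  for (s in run$states) {
    expect_gt(min(s$u), -1e-6)
    expect_lt(max(s$u), 1 + 1e-6)
  }
  # ahead of the initially saturated zone every point rides the monotone
  # wave profile upward (behind it, the flat u = 1 state first relaxes DOWN
  # to the traveling profile, so monotonicity is not expected there)
  ahead <- st$y > 0.8 + 2 * p_small$xi
  for (i in 2:4)
    expect_gt(min(run$states[[i]]$u[, ahead] -
                  run$states[[i - 1]]$u[, ahead]), -1e-6)
  # comparison principle: ordered initial data stay ordered
  lo <- initial_condition(env, p_small, y0_front = 0.8, ramp_width = p_small$xi)
  hi <- initial_condition(env, p_small, y0_front = 0.8, ramp_width = 3 * p_small$xi)
  expect_true(all(lo$u <= hi$u + 1e-12))
  run_lo <- fkpp_integrate(lo, 4)
  run_hi <- fkpp_integrate(hi, 4)
  expect_gt(min(run_hi$states[[1]]$u - run_lo$states[[1]]$u), -1e-6)
})

test_that("threshold fronts are straight, symmetric, and tolerance-insensitive", {
  env <- environment_make(c(0.5, 3), list())
  st <- initial_condition(env, p_small, y0_front = 0.8)
  run <- fkpp_integrate(st, 5)
  fr <- extract_front(run$states[[1]])
  expect_lt(diff(range(fr$y)), 1e-3 * p_small$a_grid)

  # halving both tolerances moves the front by well under 0.1 cells
  p_tight <- fkpp_params(0.01, 1, rtol = p_small$rtol / 2, atol = p_small$atol / 2)
  st2 <- initial_condition(env, p_tight, y0_front = 0.8)
  run2 <- fkpp_integrate(st2, 5)
  fr2 <- extract_front(run2$states[[1]])
  expect_lt(abs(mean(fr$y) - mean(fr2$y)), 0.1 * p_small$a_grid)

  # mirror-symmetric obstacle gives a symmetric front (compact test geometry:
  # the development warning is expected and immaterial to symmetry)
  envo <- environment_make(c(2.4, 4), list(make_rhombus(0.4, 0.3, c(1.2, 2.2))))
  sto <- suppressWarnings(initial_condition(envo, p_small, y0_front = 1))
  runo <- fkpp_integrate(sto, 16)
  fro <- extract_front(runo$states[[1]])
  mirrored <- approx(fro$x, fro$y, xout = 2.4 - fro$x)$y
  expect_lt(max(abs(fro$y - mirrored), na.rm = TRUE), p_small$a_grid)
})

test_that("the obstacle interior acts as an absorbing sink with a decaying tail", {
  envo <- environment_make(c(2.4, 4), list(make_rhombus(0.5, 0.5, c(1.2, 2.2))))
  sto <- suppressWarnings(initial_condition(envo, p_small, y0_front = 1))
  runo <- fkpp_integrate(sto, 20)
  s <- runo$states[[1]]
  # by t = 20 the front is far past the obstacle; density inside decays
  # with distance from the boundary toward the obstacle center
  icol <- which.min(abs(s$x - 1.2))
  inside <- which(s$mask[icol, ])
  uin <- s$u[icol, inside]
  ymid <- which.min(abs(s$y[inside] - 2.2))
  expect_lt(uin[ymid], min(uin[1], uin[length(uin)]))
  expect_lt(uin[ymid], 0.9)
})

test_that("comoving profile formula has the analytic midpoint and monotone shape", {
  expect_identical(comoving_profile(0), 0.5)
  z <- seq(-20, 6, by = 0.05)
  u <- comoving_profile(z)
  expect_true(all(diff(u) < 0))
  expect_lt(abs(u[1] - 1), 1e-3)   # saturates like e^{z/c} far behind
})

test_that("lag bookkeeping aligns series and flags disjoint ranges", {
  s1 <- indent_series(1:10, (1:10) * 0.1, w_half = 1)
  expect_equal(lag_vs_eikonal(s1, s1)$lag, rep(0, 10))
  s2 <- indent_series(21:30, rep(1, 10), w_half = 1)
  expect_error(lag_vs_eikonal(s1, s2), class = "alignment_error")
})
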