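test_that("rhombus indent formula: exact values, far field, domain errors", {
  expect_equal(indent_rhombus(1, 1), 1)                       # radical vanishes
  expect_equal(indent_rhombus(2, 1), 2 - sqrt(3), tolerance = 1e-12)
  # far field: Delta * d -> w^2 / 2
  expect_lt(abs(indent_rhombus(100, 1) * 100 - 0.5) / 0.5, 1e-4)
  expect_error(indent_rhombus(0.5, 1), class = "domain_error")
})

test_that("kink forms at sqrt(w^2 + h^2)", {
  expect_equal(kink_distance_rhombus(1.2, 0.9), 1.5)          # 3-4-5 triangle
  expect_equal(kink_distance_rhombus(1, 1), sqrt(2))
  expect_equal(kink_distance_rhombus(2, 0), 2)                # degenerate slit
})

test_that("closed-form rhombus front: straightness, Eq-consistency, h-independence", {
  w <- 1.2; h <- 0.9
  # before the obstacle the front is an unperturbed straight line
  fr <- front_rhombus(-2 * h, w, h)
  expect_lt(diff(range(fr$y)), 1e-12)
  expect_equal(indent_from_front(fr), 0)

  # post-kink indent agrees with the indent formula (arc discretization)
  for (d in c(1.6, 2.5, 5)) {
    fr <- front_rhombus(d, w, h)
    expect_lt(abs(indent_from_front(fr) - indent_rhombus(d, w)), 1e-5)
  }

  # obstacle height does not affect the front beyond the taller kink
  d <- 4
  f1 <- front_rhombus(d, w, h)
  f2 <- front_rhombus(d, w, 2 * h)
  y2 <- approx(f2$x, f2$y, xout = f1$x)$y
  expect_lt(max(abs(f1$y - y2), na.rm = TRUE), 1e-6)
})

test_that("width-rescaled indent curves collapse exactly across the four rhombi", {
  combos <- list(c(0.9, 0.9), c(0.9, 1.2), c(1.2, 0.9), c(1.2, 1.2))
  # sample every rhombus at the same d/w nodes (post-kink for all four), so
  # an exact collapse gives identical rescaled curves up to roundoff
  dw <- seq(2, 10, length.out = 150)
  series <- lapply(combos, function(wh)
    indent_series(wh[1] * dw, indent_rhombus(wh[1] * dw, wh[1]), w_half = wh[1]))
  rep_w <- collapse_check(series)
  expect_lt(rep_w$max_sup_distance, 1e-12)
  # the indent depends on w only: rescaling by h collapses demonstrably worse
  rep_h <- collapse_check(series, scales = vapply(combos, `[`, 0, 2),
                          rescale_by = "h")
  expect_gt(rep_h$max_sup_distance, 0.01)
})

test_that("axis lag behind a disk matches the Huygens-envelope brute force", {
  r <- 1
  # cusp formation at d = pi r / 2 with lag pi/2 - 1
  expect_equal(circle_axis_lag(pi / 2, r), pi / 2 - 1, tolerance = 1e-9)
  expect_lt(abs(huygens_axis_distance(r + 1e-6, r) - pi / 2), 1e-4)
  for (d in c(2, 3.5)) {
    yf <- uniroot(function(y) huygens_axis_distance(y, r) - d,
                  c(r + 1e-9, d + r), tol = 1e-10)$root
    expect_equal(circle_axis_lag(d, r), d - yf, tolerance = 1e-6)
  }
  # far field heals with the same universal law as the rhombus (w = r)
  expect_lt(abs(circle_axis_lag(200, r) * 200 - r^2 / 2) / (r^2 / 2), 1e-3)
  expect_equal(circle_axis_lag(c(2, 3), 0), c(0, 0))
  err <- tryCatch(circle_axis_lag(1, r), condition = function(c) c)
  expect_s3_class(err, "not_yet_formed")
  expect_equal(err$d_kink, pi * r / 2)
})

test_that("tilted thin bar: kink tip forms on the trailing side and recenters", {
  # untilted bar: kink tip on the axis for all post-kink d
  expect_equal(tilted_bar_kink_axis(c(1.5, 3, 10), 1, 0), c(0, 0, 0),
               tolerance = 1e-9)
  # tilted: tip starts on the trailing (upper-endpoint) side ...
  L <- 1; tilt <- 30
  hb <- L * tan(tilt * pi / 180)
  d0 <- sqrt(L^2 + hb^2) - hb
  xs <- tilted_bar_kink_axis(d0 + c(0.01, 0.3, 1, 3, 10, 50), L, tilt)
  expect_gt(xs[1], 0)
  # ... and approaches the bisecting normal monotonically
  expect_true(all(diff(abs(xs)) < 0))
  expect_lt(abs(xs[6]), 0.05)
  # the returned tip satisfies both circle equations (independent check)
  d <- 2
  x <- tilted_bar_kink_axis(d, L, tilt)
  A <- c(-L, -hb); B <- c(L, hb)
  rA <- d + 2 * hb; rB <- d
  # reconstruct y from circle B and check circle A
  y <- B[2] + sqrt(rB^2 - (x - B[1])^2)
  expect_lt(abs(sqrt(sum((c(x, y) - A)^2)) - rA), 1e-9)
  expect_error(tilted_bar_kink_axis(0.1, L, tilt), class = "not_yet_formed")
})

test_that("kink first appears at the closed-form distance", {
  ds <- seq(1.3, 1.7, by = 0.005)
  kinked <- vapply(ds, has_axis_kink, TRUE, w = 1.2, h = 0.9)
  first <- ds[which(kinked)[1]]
  expect_lt(abs(first - 1.5), 0.02)
  expect_true(all(kinked[ds >= first]))   # once formed, stays formed
})
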