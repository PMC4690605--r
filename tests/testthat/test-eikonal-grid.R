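# Grid first-arrival solver, checked against the closed forms

test_that("planar wave arrival is exact and level sets are straight", {
  env <- environment_make(c(2, 5), list())
  fld <- solve_arrival(env, v = 0.5, a_eik = 0.05, y0_front = 0.5)
  # the front expands both ways from the initial line at speed v
  ana <- outer(rep(1, length(fld$x)), abs(fld$y - fld$y0_front)) / fld$v
  expect_lt(max(abs(fld$T - ana)), 1e-9)
  fr <- front_from_arrival(fld, 3)
  expect_lt(diff(range(fr$y)), 1e-9)
})

test_that("eikonal residual is close to 1/v on obstacle-free cells", {
  env <- rhombus_env(1, 1)
  fld <- solve_arrival(env, v = 1, a_eik = 0.025, y0_front = 0.5)
  # central-difference residual in the wrapped region beside the obstacle,
  # away from the kink line and the obstacle itself
  ix <- which(fld$x > env$domain[1] / 2 + 1.6 & fld$x < env$domain[1] / 2 + 2.6)
  iy <- which(fld$y > 4.5 & fld$y < 6.5)
  Tx <- (fld$T[ix + 1, iy] - fld$T[ix - 1, iy]) / (2 * fld$a)
  Ty <- (fld$T[ix, iy + 1] - fld$T[ix, iy - 1]) / (2 * fld$a)
  res <- sqrt(Tx^2 + Ty^2) * fld$v
  expect_true(all(res > 0.95 & res < 1.05))
})

test_that("grid indent matches the rhombus formula within two grid cells", {
  # coarser grid than the default keeps this check cheap; tolerance scales
  w <- 1.2; h <- 0.9
  env <- rhombus_env(w, h, y_center = 2.5, y_top = 11)
  fld <- solve_arrival(env, v = 0.2, a_eik = w / 40, y0_front = 0.5)
  ds <- seq(2, 6, by = 0.5)
  ser <- arrival_indent_series(fld, ds)
  expect_lt(max(abs(ser$delta - indent_rhombus(ds, w))), 2 * fld$a)
})

test_that("grid axis lag behind a disk matches the wrap-geodesic closed form", {
  env <- environment_make(c(8, 10), list(make_circle(1, c(4, 3))))
  fld <- solve_arrival(env, v = 1, a_eik = 0.02, y0_front = 0.5)
  for (d in c(2, 3, 4)) {
    fr <- front_from_arrival(fld, d)
    expect_lt(abs(indent_from_front(fr) - circle_axis_lag(d, 1)), 2 * fld$a)
  }
})

test_that("level-set curves respect mirror symmetry and kink structure", {
  env <- rhombus_env(1.2, 0.9)
  fld <- solve_arrival(env, v = 1, a_eik = 0.02, y0_front = 0.5)
  fr <- front_from_arrival(fld, 2.5)
  xc <- env$domain[1] / 2
  ym <- approx(fr$x, fr$y, xout = xc + (fr$x[fr$x > xc] - xc) * -1)$y
  mirrored <- approx(fr$x, fr$y, xout = 2 * xc - fr$x)$y
  expect_lt(max(abs(fr$y - mirrored), na.rm = TRUE), fld$a)
  # single non-smooth minimum on the axis at the kink
  i <- which.min(fr$y)
  expect_lt(abs(fr$x[i] - xc), 3 * fld$a)
  expect_error(front_from_arrival(fld, -10), class = "empty_front")
})

test_that("resolution and geometry preconditions are enforced", {
  env <- rhombus_env(1, 1)
  expect_warning(solve_arrival(env, v = 1, a_eik = 0.2, y0_front = 0.5),
                 class = "resolution")
  expect_error(solve_arrival(env, v = 1, a_eik = 0.02, y0_front = 5),
               class = "invalid_geometry")
})

test_that("marker paths are geodesics: vertical when free, one bend at the corner", {
  env0 <- environment_make(c(3, 5), list())
  fld0 <- solve_arrival(env0, v = 1, a_eik = 0.05, y0_front = 0.5)
  p0 <- marker_path(fld0, c(1.5, 4))
  expect_lt(diff(range(p0[, 1])), 1e-6)

  env <- rhombus_env(1.2, 0.9)
  fld <- solve_arrival(env, v = 1, a_eik = 0.02, y0_front = 0.5)
  end <- c(env$domain[1] / 2, 6)
  p <- marker_path(fld, end)
  # near-geodesic: length within 5% of v * T(end)
  Tend <- fld$T[which.min(abs(fld$x - end[1])), which.min(abs(fld$y - end[2]))]
  expect_lt(attr(p, "length_mm"), 1.05 * Tend * 1)
  # turning is confined to the start (leaving the kink line) and the corner
  corner <- c(env$domain[1] / 2 + 1.2, 3)   # also mirror-symmetric corner
  corner_l <- c(env$domain[1] / 2 - 1.2, 3)
  tv <- polyline_turns(p)
  big <- which(tv > 5) + 1L
  dstart <- sqrt(rowSums((p[big, , drop = FALSE] -
                          matrix(end, length(big), 2, byrow = TRUE))^2))
  dcorn <- pmin(
    sqrt(rowSums((p[big, , drop = FALSE] -
                  matrix(corner, length(big), 2, byrow = TRUE))^2)),
    sqrt(rowSums((p[big, , drop = FALSE] -
                  matrix(corner_l, length(big), 2, byrow = TRUE))^2)))
  # turning happens either while committing to one characteristic right at
  # the kink-line start, or rounding the max-width corner
  expect_true(all(dstart < 0.5 | dcorn < 0.3))
  expect_error(marker_path(fld, c(env$domain[1] / 2, 3)), class = "invalid_point")
})

test_that("a second obstacle lengthens the marker path between the pair", {
  env2 <- make_two_obstacle_config("pde")
  c1 <- colMeans(env2$obstacles[[1]]$vertices)
  env1 <- environment_make(env2$domain, env2$obstacles[1])
  f2 <- solve_arrival(env2, v = 1, a_eik = 0.03, y0_front = 1)
  f1 <- solve_arrival(env1, v = 1, a_eik = 0.03, y0_front = 1)
  # end point above the second obstacle, between the staggered pair
  end <- c(c1[1] + 2, c1[2] + 2 + 1.5)
  i <- which.min(abs(f2$x - end[1])); j <- which.min(abs(f2$y - end[2]))
  expect_gt(f2$T[i, j], f1$T[i, j])
  p2 <- marker_path(f2, end); p1 <- marker_path(f1, end)
  expect_gt(attr(p2, "length_mm"), attr(p1, "length_mm"))
})
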