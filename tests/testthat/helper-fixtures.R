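# shared helpers: small geometries and independent oracles used across files

# rhombus environment with the obstacle centered laterally, front entering
# from below; margins sized for the tests (not the full study geometry)
rhombus_env <- function(w, h, y_center = 3, x_margin = 2.5 * w, y_top = 8) {
  dom <- c(2 * (w + x_margin), y_top)
  environment_make(dom, list(make_rhombus(w, h, c(dom[1] / 2, y_center))))
}

# dense Huygens-envelope brute force for the axis front behind a disk of
# radius r centered at the origin: minimum over boundary sources of
# wrap-arc + straight segment, chords through the disk excluded
huygens_axis_distance <- function(y, r, n_theta = 20001) {
  th <- seq(0, pi / 2, length.out = n_theta)
  qx <- r * sin(th); qy <- r * cos(th)
  dx <- -qx; dy <- y - qy
  L2 <- dx^2 + dy^2
  tt <- pmin(pmax(-(qx * dx + qy * dy) / pmax(L2, 1e-300), 0), 1)
  dmin2 <- (qx + tt * dx)^2 + (qy + tt * dy)^2
  ok <- dmin2 >= r^2 - 1e-9
  min((r * (pi / 2 - th) + sqrt(L2))[ok])
}

# closed-form front curve: does it show a kinked (non-smooth) minimum on the
# symmetry axis, off the obstacle boundary?
has_axis_kink <- function(d, w, h) {
  fr <- front_rhombus(d, w, h)
  i <- which.min(fr$y)
  if (abs(fr$x[i]) > w / 20 || i <= 1 || i >= nrow(fr)) return(FALSE)
  p <- c(fr$x[i], fr$y[i])
  edge_dist <- min(vapply(list(c(w, 0), c(-w, 0)), function(a) {
    b <- c(0, h); ab <- b - a
    t <- min(max(sum((p - a) * ab) / sum(ab^2), 0), 1)
    sqrt(sum((a + t * ab - p)^2))
  }, 0))
  if (edge_dist < 1e-4 * w) return(FALSE)   # endpoint resting on the obstacle
  v1 <- c(fr$x[i] - fr$x[i - 1], fr$y[i] - fr$y[i - 1])
  v2 <- c(fr$x[i + 1] - fr$x[i], fr$y[i + 1] - fr$y[i])
  turn <- abs(atan2(v1[1] * v2[2] - v1[2] * v2[1], sum(v1 * v2))) * 180 / pi
  turn > 5
}

# turning angles (degrees) along a polyline
polyline_turns <- function(p) {
  dp <- diff(p)
  a <- atan2(dp[, 2], dp[, 1])
  abs(diff(a)) * 180 / pi
}
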