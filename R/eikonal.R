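## Constant-speed (eikonal/Huygens) model.  The front advances at fixed speed
## v normal to itself; an obstacle deletes the overlapping front segment, and
## beyond the obstacle's widest points the shadow is filled by circular arcs
## centered on the boundary.  Closed forms below serve as oracles for the
## general grid first-arrival solver.

# ---- front-curve container --------------------------------------------------

new_front <- function(x, y, d, provenance, y_ref = 0, w_half = NA_real_) {
  structure(data.frame(x = x, y = y),
            d = d, provenance = provenance, y_ref = y_ref, w_half = w_half,
            class = c("fo_front", "data.frame"))
}

#' Front position label of a front curve
#' @param front an `fo_front`
#' @export
front_d <- function(front) attr(front, "d")

# ---- closed forms for the rhombus ------------------------------------------

#' Indent size behind a rhombus-shaped obstacle (constant-speed model)
#'
#' For a rhombus of half-width `w_half` the indent (lag of the most retarded
#' front point behind the unperturbed front) at front position `d` beyond the
#' point of maximal width is
#' \deqn{\Delta(d) = d\,(1 - \sqrt{1 - w^2/d^2}),}
#' independent of the obstacle height; for `d >> w` it heals as
#' `Delta ~ w^2 / (2 d)`.  Valid once the two circular arcs have met on the
#' symmetry axis (`d >= w_half` is required; the kink actually forms at
#' [kink_distance_rhombus()]).
#'
#' @param d front position(s) beyond the point of maximal width (mm)
#' @param w_half obstacle half-width (mm)
#' @return indent size(s) Delta (mm)
#' @examples
#' indent_rhombus(2, 1)          # 2 - sqrt(3)
#' 100 * indent_rhombus(100, 1)  # ~ w^2/2 = 0.5
#' @export
indent_rhombus <- function(d, w_half) {
  if (w_half <= 0) fo_stop("invalid_geometry", "w_half must be positive")
  if (any(d < w_half))
    fo_stop("domain_error", "indent formula requires d >= w_half")
  d * (1 - sqrt(1 - (w_half / d)^2))
}

#' Front position at which the kink forms behind a rhombus
#'
#' The two arcs wrapping a rhombus of half-width `w_half` and half-height
#' `h_half` meet on the symmetry axis after the front has traveled
#' `sqrt(w_half^2 + h_half^2)` beyond the point of maximal width.
#'
#' @inheritParams indent_rhombus
#' @param h_half obstacle half-height (mm); `0` gives the degenerate slit
#' @export
kink_distance_rhombus <- function(w_half, h_half) {
  if (w_half <= 0 || h_half < 0)
    fo_stop("invalid_geometry", "dimensions must be positive")
  sqrt(w_half^2 + h_half^2)
}

#' Closed-form constant-speed front around a rhombus
#'
#' Constructs the front polyline at front position `d` for a rhombus obstacle
#' centered on the symmetry axis: a straight line before the obstacle, a
#' straight line interrupted over the obstacle cross-section while passing it,
#' and, beyond the widest point, straight outer segments joined to circular
#' arcs of radius `d` centered at the max-width corners.  Arcs terminate on
#' the obstacle edge (meeting it at 90 degrees) until they intersect each
#' other on the axis (`d >` [kink_distance_rhombus()]), after which the curve
#' has a kink whose indent equals [indent_rhombus()].
#'
#' @inheritParams indent_rhombus
#' @param h_half obstacle half-height (mm)
#' @param center obstacle center (mm)
#' @param x_max lateral half-extent of the returned curve (mm); default
#'   `2.5 * w_half` beyond the corner
#' @param arc_step_deg arc discretization (degrees per vertex)
#' @return an `fo_front`; when the front touches the obstacle the curve has a
#'   gap across the obstacle cross-section (increasing x throughout)
#' @export
front_rhombus <- function(d, w_half, h_half, center = c(0, 0),
                          x_max = NULL, arc_step_deg = 0.5) {
  if (w_half <= 0 || h_half <= 0)
    fo_stop("invalid_geometry", "dimensions must be positive")
  if (is.null(x_max)) x_max <- w_half + 2.5 * w_half
  w <- w_half; h <- h_half
  straight <- function(xlo, xhi, y) {
    xs <- seq(xlo, xhi, length.out = max(2, ceiling((xhi - xlo) / (w / 50)) + 1))
    cbind(xs, rep(y, length(xs)))
  }
  if (d <= -h) {
    seg <- straight(-x_max, x_max, d)
  } else if (d <= 0) {
    xc <- w * (1 + d / h)    # half-width of the lower cross-section at y = d
    seg <- rbind(straight(-x_max, -xc, d), straight(xc, x_max, d))
  } else {
    s_edge <- sqrt(w^2 + h^2)
    # arc centered at (+w, 0), alpha measured from +x axis; alpha = 90deg is
    # the junction with the straight front at (w, d)
    alpha_edge <- atan2(h, -w)
    alpha_end <- if (d < s_edge) alpha_edge else acos(-w / d)
    nstep <- max(2L, ceiling((alpha_end - pi / 2) / (arc_step_deg * pi / 180)))
    al <- seq(pi / 2, alpha_end, length.out = nstep + 1L)
    arc_r <- cbind(w + d * cos(al), d * sin(al))       # runs x: w -> inner end
    arc_l <- cbind(-arc_r[, 1], arc_r[, 2])           # runs x: -w -> inner end
    arc_r_up <- arc_r[rev(seq_len(nrow(arc_r))), , drop = FALSE]  # inner end -> w
    if (d >= s_edge) {
      # arcs meet on the axis: drop duplicated junction/meeting vertices
      seg <- rbind(straight(-x_max, -w, d), arc_l[-1, , drop = FALSE],
                   arc_r_up[-1, , drop = FALSE],
                   straight(w, x_max, d)[-1, , drop = FALSE])
    } else {
      # arcs terminate on the obstacle edge (90 degree contact); gap between
      seg <- rbind(straight(-x_max, -w, d), arc_l[-1, , drop = FALSE],
                   arc_r_up, straight(w, x_max, d)[-1, , drop = FALSE])
    }
  }
  seg <- sweep(seg, 2, center, "+")
  new_front(seg[, 1], seg[, 2], d = d, provenance = "closed-form",
            y_ref = center[2], w_half = w_half)
}

#' Axis lag behind a disk-shaped obstacle (constant-speed model)
#'
#' Behind a disk of radius `r` the front in the shadow is the envelope of
#' circular segments centered on the boundary; the most retarded point sits on
#' the axis at height `y_f` solving
#' `d = r * asin(r / y_f) + sqrt(y_f^2 - r^2)` (vertical tangent, wrap arc,
#' tangent segment).  The lag is `Delta = d - y_f`.  A cusp (kink of opening
#' angle zero) forms at `d = pi * r / 2` with `y_f = r`; for smaller `d` the
#' kink has not yet formed and a `not_yet_formed` error carrying `d_kink` is
#' raised.
#'
#' @param d front position(s) beyond the disk center height (mm)
#' @param r disk radius (mm)
#' @return lag(s) Delta (mm); `Delta * d -> r^2 / 2` in the far field
#' @export
circle_axis_lag <- function(d, r) {
  if (r < 0) fo_stop("invalid_geometry", "radius must be non-negative")
  if (r == 0) return(rep(0, length(d)))
  d_kink <- pi * r / 2
  if (any(d < d_kink - 1e-12))
    fo_stop("not_yet_formed",
            sprintf("cusp forms at d = pi*r/2 = %.6g", d_kink),
            d_kink = d_kink)
  vapply(d, function(di) {
    f <- function(y) r * asin(pmin(1, r / y)) + sqrt(pmax(0, y^2 - r^2)) - di
    if (abs(f(r)) < 1e-12) return(di - r)
    y <- uniroot(f, c(r, di + r), tol = 1e-12)$root
    di - y
  }, 0)
}

#' Kink-tip lateral position behind a thin tilted bar
#'
#' For a thin bar with projected half-width `L_proj_half`, tilted by `tilt`
#' degrees (endpoints at `(-L, -L tan)` and `(+L, +L tan)`), the shadow front
#' is two circles centered at the endpoints with radii `d + 2 L tan(tilt)`
#' and `d` (front position `d` measured from the trailing endpoint).  The
#' kink tip is their downstream intersection; it forms off-center on the
#' trailing side and approaches the bisecting normal (`x = 0`) as `d` grows.
#'
#' @param d front position(s) beyond the trailing endpoint (mm)
#' @param L_proj_half projected half-width (mm)
#' @param tilt tilt angle (degrees)
#' @return x-coordinate(s) of the kink tip (mm)
#' @export
tilted_bar_kink_axis <- function(d, L_proj_half, tilt) {
  L <- L_proj_half
  if (L <= 0) fo_stop("invalid_geometry", "L_proj_half must be positive")
  hb <- L * tan(tilt * pi / 180)
  d_kink <- sqrt(L^2 + hb^2) - hb
  if (any(d < d_kink - 1e-12))
    fo_stop("not_yet_formed",
            sprintf("kink forms at d = %.6g", d_kink), d_kink = d_kink)
  A <- c(-L, -hb); B <- c(L, hb)
  dist <- sqrt(sum((B - A)^2))
  u <- (B - A) / dist
  nvec <- c(-u[2], u[1])
  vapply(d, function(di) {
    rA <- di + 2 * hb; rB <- di
    a_par <- (dist^2 + rA^2 - rB^2) / (2 * dist)
    h2 <- rA^2 - a_par^2
    h_perp <- sqrt(max(0, h2))
    p1 <- A + a_par * u + h_perp * nvec
    p2 <- A + a_par * u - h_perp * nvec
    if (p1[2] >= p2[2]) p1[1] else p2[1]
  }, 0)
}

# ---- grid first-arrival solver ---------------------------------------------

# cell-center rasterization of the obstacle set, vectorized over the grid
raster_mask <- function(env, xs, ys) {
  nx <- length(xs); ny <- length(ys)
  mask <- matrix(FALSE, nx, ny)
  for (ob in env$obstacles) {
    v <- ob$vertices
    ix <- which(xs >= min(v[, 1]) - 1e-12 & xs <= max(v[, 1]) + 1e-12)
    iy <- which(ys >= min(v[, 2]) - 1e-12 & ys <= max(v[, 2]) + 1e-12)
    if (!length(ix) || !length(iy)) next
    px <- rep(xs[ix], times = length(iy))
    py <- rep(ys[iy], each = length(ix))
    inside <- rep(FALSE, length(px))
    onedge <- rep(FALSE, length(px))
    n <- nrow(v)
    x1v <- v[, 1]; y1v <- v[, 2]
    x2v <- c(x1v[-1], x1v[1]); y2v <- c(y1v[-1], y1v[1])
    for (k in seq_len(n)) {
      x1 <- x1v[k]; y1 <- y1v[k]; x2 <- x2v[k]; y2 <- y2v[k]
      cond <- (y1 > py) != (y2 > py)
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      inside <- xor(inside, cond & (px < xint))
      dx <- x2 - x1; dy <- y2 - y1
      tt <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / (dx * dx + dy * dy), 0), 1)
      onedge <- onedge | ((x1 + tt * dx - px)^2 + (y1 + tt * dy - py)^2 < 1e-18)
    }
    mask[ix, iy] <- mask[ix, iy] | matrix(inside | onedge, length(ix), length(iy))
  }
  mask
}

#' First-arrival times of the constant-speed front on a grid
#'
#' Solves `|grad T| = 1/v` by fast marching on a rectangular grid covering the
#' environment's domain, with `T = 0` on the initial front line and obstacle
#' cells excluded (`T = +Inf`).  A cell is an obstacle cell iff its center
#' lies in a closed obstacle polygon.  The upwind discretization is second
#' order where two accepted neighbors are available (`order = 2`, default),
#' falling back to first order; pass `order = 1` for the plain first-order
#' scheme.
#'
#' @param env an `fo_env`
#' @param v front speed (mm/h)
#' @param a_eik grid spacing (mm); default `w_half / 100` of the smallest
#'   obstacle.  A spacing coarser than `w_half / 20` triggers a resolution
#'   warning.
#' @param y0_front y-coordinate of the initial front line (mm); must lie
#'   below all obstacles
#' @param order upwind order, 1 or 2
#' @return an object of class `fo_arrival`: fields `T` (nx x ny matrix,
#'   hours), `x`, `y` (cell-center coordinates), `a`, `v`, `y0_front`
#'   (grid-aligned), `env`
#' @export
solve_arrival <- function(env, v, a_eik = NULL, y0_front = 0, order = 2) {
  stopifnot(v > 0)
  wmin <- if (env$n_obstacles) min(vapply(env$obstacles, function(o) o$w_half, 0)) else Inf
  if (is.null(a_eik)) a_eik <- if (is.finite(wmin)) wmin / 100 else min(env$domain) / 200
  if (is.finite(wmin) && a_eik > wmin / 20)
    fo_warn("resolution", "grid spacing coarser than w_half/20 of the smallest obstacle")
  for (ob in env$obstacles)
    if (min(ob$vertices[, 2]) <= y0_front)
      fo_stop("invalid_geometry", "initial front must lie below all obstacles")
  xs <- seq(a_eik / 2, env$domain[1], by = a_eik)
  ys <- seq(a_eik / 2, env$domain[2], by = a_eik)
  j0 <- which.min(abs(ys - y0_front))
  mask <- raster_mask(env, xs, ys)
  T <- fmm_solve_cpp(mask, a_eik, v, j0, as.integer(order))
  structure(list(T = T, x = xs, y = ys, a = a_eik, v = v,
                 y0_front = ys[j0], env = env, order = order),
            class = "fo_arrival")
}

#' @export
print.fo_arrival <- function(x, ...) {
  cat(sprintf("<fo_arrival> %d x %d grid, a = %.4g mm, v = %.3g mm/h\n",
              length(x$x), length(x$y), x$a, x$v))
  invisible(x)
}

env_ref_y <- function(env, ref = 1L) {
  if (env$n_obstacles == 0) 0 else env$obstacles[[ref]]$y_maxwidth
}

#' Extract a front curve from an arrival field
#'
#' Returns the sub-cell linearly interpolated level set of `T` whose
#' unperturbed position sits at front position `d` beyond the reference
#' obstacle's point of maximal width (labeled from the unperturbed
#' lateral-edge columns, the plate-assay convention).  For each grid column the topmost
#' crossing of the level is used, so the curve is single valued and ordered
#' by x; obstacle cells (T = +Inf) are never crossed.
#'
#' @param field an `fo_arrival`
#' @param d front position (mm), measured from the reference obstacle's
#'   `y_maxwidth`
#' @param ref index of the reference obstacle (default 1)
#' @return an `fo_front`
#' @export
front_from_arrival <- function(field, d, ref = 1L) {
  y_ref <- env_ref_y(field$env, ref)
  level <- (d + y_ref - field$y0_front) / field$v
  if (level < 0) fo_stop("empty_front", "level lies behind the initial front")
  Tm <- field$T
  nx <- length(field$x); ny <- length(field$y)
  xs <- numeric(0); ysout <- numeric(0)
  for (i in seq_len(nx)) {
    col <- Tm[i, ]
    below <- which(col <= level)
    if (!length(below)) next
    j <- max(below)
    if (j < ny && is.finite(col[j + 1])) {
      yv <- field$y[j] + field$a * (level - col[j]) / (col[j + 1] - col[j])
    } else {
      yv <- field$y[j]
    }
    xs <- c(xs, field$x[i]); ysout <- c(ysout, yv)
  }
  if (!length(xs)) fo_stop("empty_front", "level set is empty on this grid")
  w_half <- if (field$env$n_obstacles) field$env$obstacles[[ref]]$w_half else NA_real_
  new_front(xs, ysout, d = d, provenance = "grid", y_ref = y_ref, w_half = w_half)
}

#' Indent series from an arrival field
#'
#' Convenience wrapper measuring [indent_from_front()] on
#' [front_from_arrival()] level sets for a vector of front positions.
#'
#' @inheritParams front_from_arrival
#' @param d_values front positions (mm)
#' @param window lateral half-window for the indent search (mm); default the
#'   reference obstacle's `w_half`
#' @return an indent series `data.frame(d, delta)` with attribute `w_half`
#' @export
arrival_indent_series <- function(field, d_values, ref = 1L, window = NULL) {
  deltas <- vapply(d_values, function(d)
    indent_from_front(front_from_arrival(field, d, ref), window = window), 0)
  w_half <- if (field$env$n_obstacles) field$env$obstacles[[ref]]$w_half else NA_real_
  indent_series(d_values, deltas, w_half)
}

#' Path of a virtual front marker (geodesic backtrace)
#'
#' Traces the steepest-descent path of the arrival time `T` from `end` back
#' to the initial front line; in the constant-speed model this is the
#' shortest growth-permitted path, the trajectory of a virtual marker riding
#' the front (and the shape of lineages behind the front).  The trace uses a
#' bilinearly interpolated gradient with step `a/2`, falling back to a
#' discrete descent next to obstacle cells; exact ties are broken toward
#' smaller `|x|`.
#'
#' @param field an `fo_arrival`
#' @param end end point `c(x, y)` (mm); must have finite arrival time
#' @return matrix of path vertices (from `end` back to the initial line) with
#'   attribute `length_mm`
#' @export
marker_path <- function(field, end) {
  xs <- field$x; ys <- field$y; Tm <- field$T; a <- field$a
  i0 <- which.min(abs(xs - end[1])); j0 <- which.min(abs(ys - end[2]))
  if (!is.finite(Tm[i0, j0]))
    fo_stop("invalid_point", "end point lies inside an obstacle")
  interpT <- function(x, y) {
    i <- min(max(findInterval(x, xs), 1L), length(xs) - 1L)
    j <- min(max(findInterval(y, ys), 1L), length(ys) - 1L)
    tx <- (x - xs[i]) / a; ty <- (y - ys[j]) / a
    q <- c(Tm[i, j], Tm[i + 1, j], Tm[i, j + 1], Tm[i + 1, j + 1])
    if (any(!is.finite(q))) return(NA_real_)
    (1 - tx) * (1 - ty) * q[1] + tx * (1 - ty) * q[2] +
      (1 - tx) * ty * q[3] + tx * ty * q[4]
  }
  path <- matrix(c(end[1], end[2]), ncol = 2)
  cur <- end
  step <- a / 2
  max_steps <- ceiling(4 * (sum(field$env$domain)) / step)
  for (it in seq_len(max_steps)) {
    if (cur[2] <= field$y0_front + a) break
    eps <- a / 2
    t0 <- interpT(cur[1], cur[2])
    tx1 <- interpT(cur[1] - eps, cur[2]); tx2 <- interpT(cur[1] + eps, cur[2])
    ty1 <- interpT(cur[1], cur[2] - eps); ty2 <- interpT(cur[1], cur[2] + eps)
    if (any(is.na(c(t0, tx1, tx2, ty1, ty2)))) {
      # next to an obstacle: discrete descent on the 8-neighborhood
      i <- which.min(abs(xs - cur[1])); j <- which.min(abs(ys - cur[2]))
      nb <- expand.grid(di = -1:1, dj = -1:1)
      nb <- nb[!(nb$di == 0 & nb$dj == 0), ]
      ii <- pmin(pmax(i + nb$di, 1L), length(xs))
      jj <- pmin(pmax(j + nb$dj, 1L), length(ys))
      tv <- Tm[cbind(ii, jj)]
      ord <- order(tv, abs(xs[ii] - mean(range(xs))))  # ties: toward the axis
      best <- ord[1]
      cur <- c(xs[ii[best]], ys[jj[best]])
    } else {
      # one-sided (upwind) gradients: on a shock line (e.g. the symmetry
      # axis behind an obstacle) the two sides disagree; follow the steeper
      # characteristic, ties broken toward the left/minus side — the
      # documented smaller-|x| convention
      gxm <- (t0 - tx1) / eps; gxp <- (tx2 - t0) / eps
      gym <- (t0 - ty1) / eps; gyp <- (ty2 - t0) / eps
      gx <- if (abs(gxm) >= abs(gxp)) gxm else gxp
      gy <- if (abs(gym) >= abs(gyp)) gym else gyp
      g <- c(gx, gy)
      ng <- sqrt(sum(g^2))
      if (ng < 1e-15) break
      cur <- cur - step * g / ng
    }
    path <- rbind(path, cur)
  }
  path <- rbind(path, c(path[nrow(path), 1], field$y0_front))
  len <- sum(sqrt(rowSums((path[-1, , drop = FALSE] - path[-nrow(path), , drop = FALSE])^2)))
  attr(path, "length_mm") <- len
  path
}
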