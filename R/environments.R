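## Geometry layer shared by all engines.  Coordinates are continuous 2D in mm,
## x lateral, +y the propagation direction.  Obstacle polygons are closed sets:
## their boundary belongs to the obstacle, which makes downstream rasterization
## (cell-center rule) deterministic.

# ---- low-level polygon helpers ----------------------------------------------

polygon_area <- function(v) {
  # shoelace; positive for counterclockwise vertex order
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

polygon_is_simple <- function(v) {
  n <- nrow(v)
  if (n < 3) return(FALSE)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (share a vertex)
      if (j == i || j == i %% n + 1 || i == j %% n + 1) next
      if (segments_intersect(v[idx[i, 1], ], v[idx[i, 2], ],
                             v[idx[j, 1], ], v[idx[j, 2], ])) return(FALSE)
    }
  }
  TRUE
}

cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])

segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- cross2(q1, q2, p1); d2 <- cross2(q1, q2, p2)
  d3 <- cross2(p1, p2, q1); d4 <- cross2(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, q, r) { # collinear r on segment pq
    min(p[1], q[1]) - 1e-12 <= r[1] && r[1] <= max(p[1], q[1]) + 1e-12 &&
    min(p[2], q[2]) - 1e-12 <= r[2] && r[2] <= max(p[2], q[2]) + 1e-12
  }
  (abs(d1) < 1e-12 && on_seg(q1, q2, p1)) ||
  (abs(d2) < 1e-12 && on_seg(q1, q2, p2)) ||
  (abs(d3) < 1e-12 && on_seg(p1, p2, q1)) ||
  (abs(d4) < 1e-12 && on_seg(p1, p2, q2))
}

#' Point-in-polygon test with the boundary counting as inside
#'
#' Vectorized over points.  Used for obstacle membership and rasterization;
#' the closed-set convention makes cell-center rasterization deterministic.
#'
#' @param px,py point coordinates (mm)
#' @param v polygon vertex matrix (n x 2, counterclockwise)
#' @return logical vector
#' @keywords internal
point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  out <- logical(length(px))
  for (i in seq_along(px)) {
    x <- px[i]; y <- py[i]
    # boundary check: point on any edge
    dx <- x2 - x1; dy <- y2 - y1
    tnum <- (x - x1) * dx + (y - y1) * dy
    len2 <- dx * dx + dy * dy
    tt <- pmin(pmax(tnum / pmax(len2, 1e-300), 0), 1)
    d2 <- (x1 + tt * dx - x)^2 + (y1 + tt * dy - y)^2
    if (any(d2 < 1e-18)) { out[i] <- TRUE; next }
    # even-odd ray cast
    inside <- FALSE
    for (k in seq_len(n)) {
      if ((y1[k] > y) != (y2[k] > y)) {
        xint <- x1[k] + (y - y1[k]) / (y2[k] - y1[k]) * (x2[k] - x1[k])
        if (x < xint) inside <- !inside
      }
    }
    out[i] <- inside
  }
  out
}

polygons_disjoint <- function(va, vb) {
  # closed sets: touching boundaries count as overlap
  if (max(va[, 1]) < min(vb[, 1]) || max(vb[, 1]) < min(va[, 1]) ||
      max(va[, 2]) < min(vb[, 2]) || max(vb[, 2]) < min(va[, 2])) return(TRUE)
  na <- nrow(va); nb <- nrow(vb)
  ia <- cbind(seq_len(na), c(seq_len(na)[-1], 1L))
  ib <- cbind(seq_len(nb), c(seq_len(nb)[-1], 1L))
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (segments_intersect(va[ia[i, 1], ], va[ia[i, 2], ],
                           vb[ib[j, 1], ], vb[ib[j, 2], ])) return(FALSE)
  }
  if (any(point_in_polygon(va[, 1], va[, 2], vb))) return(FALSE)
  if (any(point_in_polygon(vb[, 1], vb[, 2], va))) return(FALSE)
  TRUE
}

# ---- obstacles --------------------------------------------------------------

new_obstacle <- function(vertices, kind, w_half, h_half = NA_real_,
                         y_maxwidth, r = NA_real_,
                         L_proj_half = NA_real_, tilt = NA_real_) {
  if (polygon_area(vertices) < 0) vertices <- vertices[rev(seq_len(nrow(vertices))), ]
  if (!polygon_is_simple(vertices))
    fo_stop("invalid_geometry", "obstacle polygon is self-intersecting")
  structure(list(vertices = vertices, kind = kind, w_half = w_half,
                 h_half = h_half, y_maxwidth = y_maxwidth, r = r,
                 L_proj_half = L_proj_half, tilt = tilt),
            class = "fo_obstacle")
}

#' Rhombus-shaped obstacle
#'
#' A rhombus of width `2 * w_half` (perpendicular to propagation) and height
#' `2 * h_half` (along propagation), the obstacle family used throughout the
#' printed-lawn experiments this package models.
#'
#' @param w_half half-width (mm), perpendicular to the propagation direction
#' @param h_half half-height (mm), along the propagation direction
#' @param center obstacle center, numeric length 2 (mm)
#' @return an object of class `fo_obstacle`
#' @examples
#' ob <- make_rhombus(1.2, 0.9)
#' obstacle_area(ob)  # 2 * w * h = 2.16 mm^2
#' @export
make_rhombus <- function(w_half, h_half, center = c(0, 0)) {
  if (!is.numeric(w_half) || !is.numeric(h_half) || w_half <= 0 || h_half <= 0)
    fo_stop("invalid_geometry", "rhombus half-dimensions must be positive")
  v <- rbind(c(w_half, 0), c(0, h_half), c(-w_half, 0), c(0, -h_half))
  v <- sweep(v, 2, center, "+")
  new_obstacle(v, "rhombus", w_half = w_half, h_half = h_half,
               y_maxwidth = center[2])
}

#' Disk-shaped obstacle stored as a fine polygon
#'
#' Circles are represented as regular inscribed n-gons so every engine
#' consumes a single geometry representation.  `w_half` is reported as `r`;
#' the polygonal area deficit is O(n_vertices^-2) (the inscribed polygon has
#' area (n/2) r^2 sin(2 pi / n)).
#'
#' @param r radius (mm)
#' @param center center, numeric length 2 (mm)
#' @param n_vertices number of polygon vertices (>= 16, default 360)
#' @return an object of class `fo_obstacle`
#' @export
make_circle <- function(r, center = c(0, 0), n_vertices = 360L) {
  if (!is.numeric(r) || r <= 0)
    fo_stop("invalid_geometry", "circle radius must be positive")
  if (n_vertices < 16)
    fo_stop("invalid_geometry", "circle approximation needs at least 16 vertices")
  th <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  v <- cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  new_obstacle(v, "circle-approx", w_half = r, y_maxwidth = center[2], r = r)
}

#' Thin tilted-bar obstacle
#'
#' A narrow bar with projected half-width `L_proj_half` perpendicular to the
#' propagation direction, tilted by `tilt` degrees; endpoints are at
#' `center + (-L, -L tan(tilt))` and `center + (L, L tan(tilt))`.  The
#' polygon is a thin rectangle of the given thickness.
#'
#' @param L_proj_half projected half-width (mm)
#' @param tilt tilt angle (degrees)
#' @param center bar midpoint (mm)
#' @param thickness bar thickness (mm)
#' @return an object of class `fo_obstacle`
#' @export
make_tilted_bar <- function(L_proj_half, tilt, center = c(0, 0), thickness = 0.02) {
  if (L_proj_half <= 0 || thickness <= 0)
    fo_stop("invalid_geometry", "bar dimensions must be positive")
  hb <- L_proj_half * tan(tilt * pi / 180)
  a <- c(-L_proj_half, -hb); b <- c(L_proj_half, hb)
  u <- b - a; u <- u / sqrt(sum(u^2))
  nvec <- c(-u[2], u[1]) * thickness / 2
  v <- rbind(a + nvec, b + nvec, b - nvec, a - nvec)
  v <- sweep(v, 2, center, "+")
  new_obstacle(v, "tilted-bar", w_half = L_proj_half,
               y_maxwidth = center[2] + hb, L_proj_half = L_proj_half, tilt = tilt)
}

#' Translate an obstacle
#' @param ob an `fo_obstacle`
#' @param dxy translation vector (mm)
#' @export
obstacle_translate <- function(ob, dxy) {
  ob$vertices <- sweep(ob$vertices, 2, dxy, "+")
  ob$y_maxwidth <- ob$y_maxwidth + dxy[2]
  ob
}

#' Obstacle polygon area (shoelace)
#' @param ob an `fo_obstacle`
#' @export
obstacle_area <- function(ob) abs(polygon_area(ob$vertices))

# ---- environments -----------------------------------------------------------

#' Assemble a growth-permitting rectangular habitat with obstacles
#'
#' The habitat is the axis-aligned rectangle `[0, Lx] x [0, Ly]` (mm) with
#' propagation along +y.  Obstacles must lie strictly inside the domain and
#' be pairwise disjoint.  The growth-permitting area fraction `rho` is derived
#' from exact polygon areas.
#'
#' @param domain numeric length 2: `c(Lx, Ly)` (mm)
#' @param obstacles list of `fo_obstacle`
#' @param metadata optional named list (e.g. generator seed) stored verbatim
#' @return an object of class `fo_env` with fields `domain`, `obstacles`,
#'   `rho`, `n_obstacles`, `metadata`
#' @export
environment_make <- function(domain, obstacles = list(), metadata = list()) {
  if (length(domain) != 2 || any(domain <= 0))
    fo_stop("invalid_geometry", "domain must be c(Lx, Ly) with positive extents")
  for (ob in obstacles) {
    v <- ob$vertices
    if (any(v[, 1] <= 0) || any(v[, 1] >= domain[1]) ||
        any(v[, 2] <= 0) || any(v[, 2] >= domain[2]))
      fo_stop("invalid_geometry", "obstacle not strictly inside domain")
  }
  no <- length(obstacles)
  if (no > 1) {
    for (i in seq_len(no - 1)) for (j in (i + 1):no) {
      if (!polygons_disjoint(obstacles[[i]]$vertices, obstacles[[j]]$vertices))
        fo_stop("invalid_geometry",
                sprintf("obstacles %d and %d overlap", i, j))
    }
  }
  area <- prod(domain)
  obs_area <- if (no) sum(vapply(obstacles, obstacle_area, 0)) else 0
  structure(list(domain = domain, obstacles = obstacles,
                 rho = 1 - obs_area / area, n_obstacles = no,
                 metadata = metadata),
            class = "fo_env")
}

#' @export
print.fo_env <- function(x, ...) {
  cat(sprintf("<fo_env> domain %.3g x %.3g mm, %d obstacle(s), rho = %.4f\n",
              x$domain[1], x$domain[2], x$n_obstacles, x$rho))
  invisible(x)
}

#' Is a point inside any obstacle?
#'
#' Obstacle polygons are closed sets: boundary points (including vertices)
#' count as obstacle.
#'
#' @param env an `fo_env`
#' @param p point `c(x, y)` in mm, or an n x 2 matrix of points
#' @return logical vector
#' @export
env_contains <- function(env, p) {
  p <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  if (any(p[, 1] < 0 | p[, 1] > env$domain[1] |
          p[, 2] < 0 | p[, 2] > env$domain[2]))
    fo_stop("out_of_domain", "point outside habitat domain")
  out <- rep(FALSE, nrow(p))
  for (ob in env$obstacles) {
    todo <- which(!out)
    if (!length(todo)) break
    out[todo] <- point_in_polygon(p[todo, 1], p[todo, 2], ob$vertices)
  }
  out
}

#' Uniformly scale an environment
#'
#' Scales the domain and every obstacle by `s` about the origin; all geometric
#' queries scale with it exactly (the constant-speed front shape is scale
#' covariant).
#'
#' @param env an `fo_env`
#' @param s scale factor (> 0)
#' @export
env_scale <- function(env, s) {
  stopifnot(s > 0)
  obstacles <- lapply(env$obstacles, function(ob) {
    ob$vertices <- ob$vertices * s
    for (f in c("w_half", "h_half", "y_maxwidth", "r", "L_proj_half"))
      if (!is.na(ob[[f]])) ob[[f]] <- ob[[f]] * s
    ob
  })
  environment_make(env$domain * s, obstacles, env$metadata)
}

#' Two-obstacle configurations
#'
#' The staggered-pair geometries used to study how the perturbation from one
#' obstacle interacts with the next.  `engine = "pde"` gives two rhombi with
#' `w = 1.2 mm`, `h = 0.9 mm`, the second offset by 2 mm horizontally and
#' 2 mm vertically.  `engine = "eden"` gives two disks of radius `R` (lattice
#' units) with centers offset by `(5/3 R, 5/2 R)`.
#'
#' @param engine `"pde"` or `"eden"`
#' @param R disk radius for the eden variant (lattice units, default 80)
#' @param center center of the first obstacle; default places the pair inside
#'   a domain sized to fit
#' @param domain habitat rectangle; a suitable default is built when `NULL`
#' @return an `fo_env`
#' @export
make_two_obstacle_config <- function(engine = c("pde", "eden"), R = 80,
                                     center = NULL, domain = NULL) {
  engine <- match.arg(engine)
  if (engine == "pde") {
    if (is.null(domain)) domain <- c(20, 16)
    if (is.null(center)) center <- c(domain[1] / 2 - 1, 4)
    o1 <- make_rhombus(1.2, 0.9, center)
    o2 <- make_rhombus(1.2, 0.9, center + c(2, 2))
    environment_make(domain, list(o1, o2),
                     metadata = list(config = "two-obstacle-pde"))
  } else {
    if (R <= 0) fo_stop("invalid_geometry", "radius must be positive")
    off <- c(5 / 3, 5 / 2) * R
    if (is.null(domain)) domain <- c(7.5 * R, 5 * R + off[2] + 4 * R)
    if (is.null(center)) center <- c((domain[1] - off[1]) / 2, 2.5 * R)
    o1 <- make_circle(R, center)
    o2 <- make_circle(R, center + off)
    environment_make(domain, list(o1, o2),
                     metadata = list(config = "two-obstacle-eden", R = R))
  }
}

#' Random obstacle field
#'
#' Places `N` non-overlapping features of linear size `L` uniformly at random
#' (rejection sampling) in the domain.  Habitats are classified by the
#' growth-permitting area fraction `rho`, the number of features `N` and
#' their linear size `L`; since all three are given, the realized `rho` is
#' fixed by area arithmetic and must agree with the target within 2%
#' (relative), otherwise an error is raised.  Features default to
#' axis-aligned squares of side `L`; `shape = "circle"` uses disks of
#' diameter `L`.
#'
#' @param rho target growth-permitting area fraction, in (0, 1)
#' @param N number of features
#' @param L feature linear size (mm)
#' @param domain habitat rectangle `c(Lx, Ly)` (mm)
#' @param seed integer seed for reproducible placement
#' @param shape `"square"` (default) or `"circle"`
#' @param max_tries rejection-sampling budget
#' @return an `fo_env` (the seed is recorded in `metadata`)
#' @export
make_random_field <- function(rho, N, L, domain, seed = 1L,
                              shape = c("square", "circle"),
                              max_tries = 1000L * N) {
  shape <- match.arg(shape)
  if (rho <= 0 || rho >= 1) fo_stop("parameter_error", "rho must be in (0, 1)")
  if (N < 1) fo_stop("parameter_error", "N must be >= 1")
  feat_area <- if (shape == "square") L^2 else pi * (L / 2)^2
  if (N * feat_area >= prod(domain))
    fo_stop("packing_failure",
            sprintf("total feature area %.3g exceeds domain area %.3g",
                    N * feat_area, prod(domain)))
  realized <- 1 - N * feat_area / prod(domain)
  if (abs(realized - rho) > 0.02 * rho)
    fo_stop("rho_mismatch",
            sprintf("realized growth fraction %.4f not within 2%% of target %.4f (rho is fixed by N, L and the domain)",
                    realized, rho))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  half <- L / 2
  eps <- 1e-9 * max(domain)
  placed <- list()
  tries <- 0L
  while (length(placed) < N) {
    if (tries >= max_tries)
      fo_stop("packing_failure",
              sprintf("failed to place %d features after %d attempts",
                      N, tries))
    tries <- tries + 1L
    cx <- runif(1, half + eps, domain[1] - half - eps)
    cy <- runif(1, half + eps, domain[2] - half - eps)
    cand <- if (shape == "square") {
      new_obstacle(rbind(c(cx - half, cy - half), c(cx + half, cy - half),
                         c(cx + half, cy + half), c(cx - half, cy + half)),
                   "polygon", w_half = half, h_half = half, y_maxwidth = cy)
    } else {
      make_circle(half, c(cx, cy), 64L)
    }
    ok <- TRUE
    for (ob in placed) {
      if (!polygons_disjoint(cand$vertices, ob$vertices)) { ok <- FALSE; break }
    }
    if (ok) placed[[length(placed) + 1L]] <- cand
  }
  environment_make(domain, placed,
                   metadata = list(seed = seed, rho_target = rho, N = N, L = L,
                                   shape = shape, tries = tries))
}
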