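## Engine-agnostic front measurements: indent size, contact angle, and the
## width-rescaling collapse of indent curves.

#' Build an indent series
#'
#' @param d front positions (mm)
#' @param delta indent sizes (mm)
#' @param w_half reference obstacle half-width for rescaling (mm)
#' @return `data.frame(d, delta)` with attribute `w_half`, class
#'   `fo_indent_series`
#' @export
indent_series <- function(d, delta, w_half = NA_real_) {
  structure(data.frame(d = d, delta = delta),
            w_half = w_half, class = c("fo_indent_series", "data.frame"))
}

#' Indent size of a front curve
#'
#' The indent is the distance between the most lagging part of the front
#' (within a lateral window centered on the symmetry axis) and the
#' unperturbed front position:
#' `Delta = (y_ref + d) - min(y)` over the window.  Negative values
#' (overshoot) are clamped to 0 and flagged via attribute `overshoot`.
#'
#' @param front an `fo_front` with attributes `d` and `y_ref`
#' @param window lateral half-window (mm); default the front's recorded
#'   `w_half` (the obstacle half-width)
#' @param x_center window center; default 0... the symmetry axis is taken at
#'   the mean obstacle x-position stored with the front when available
#' @return indent Delta (mm)
#' @export
indent_from_front <- function(front, window = NULL, x_center = NULL) {
  d <- attr(front, "d"); y_ref <- attr(front, "y_ref")
  if (is.null(d)) fo_stop("measurement_error", "front has no d label")
  if (is.null(window) || is.null(window) || is.na(window)) window <- attr(front, "w_half")
  if (is.null(window) || is.na(window)) window <- diff(range(front$x)) / 2
  if (is.null(x_center)) x_center <- mean(range(front$x))
  sel <- abs(front$x - x_center) <= window
  if (!any(sel)) fo_stop("measurement_error", "window contains no front vertices")
  delta <- (y_ref + d) - min(front$y[sel])
  if (delta < 0) {
    out <- 0
    attr(out, "overshoot") <- delta
    return(out)
  }
  delta
}

#' Contact angle between a front and the obstacle boundary
#'
#' Angle (degrees, folded into [0, 90]) between the front tangent and the
#' obstacle edge tangent at the point where the front meets the obstacle
#' beyond its point of maximal width.  In the constant-speed model the front
#' is built from circular arcs centered on the boundary, so the closed-form
#' contact angle is 90 degrees.
#'
#' @param front an `fo_front`
#' @param obstacle an `fo_obstacle`
#' @param tol maximum distance (mm) from a curve endpoint vertex to the
#'   obstacle boundary to count as contact; default `1e-6` for closed-form
#'   fronts, 3 median vertex spacings otherwise
#' @return contact angle in degrees (attribute `side` gives which contact)
#' @export
contact_angle <- function(front, obstacle, tol = NULL) {
  v <- obstacle$vertices
  xy <- cbind(front$x, front$y)
  n <- nrow(xy)
  if (is.null(tol)) {
    tol <- if (identical(attr(front, "provenance"), "closed-form")) 1e-6
           else 3 * stats::median(sqrt(rowSums(diff(xy)^2)))
  }
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  dxe <- x2 - x1; dye <- y2 - y1
  dist_to_boundary <- function(p) {
    tt <- pmin(pmax(((p[1] - x1) * dxe + (p[2] - y1) * dye) / (dxe^2 + dye^2), 0), 1)
    d2 <- (x1 + tt * dxe - p[1])^2 + (y1 + tt * dye - p[2])^2
    k <- which.min(d2)
    list(dist = sqrt(d2[k]), edge = c(dxe[k], dye[k]))
  }
  # contact is sought beyond the point of maximal width: vertices close to
  # the boundary with y above y_maxwidth (below it the curve may merely hug
  # the shadowed lower edge of the obstacle)
  y_mw <- obstacle$y_maxwidth
  db_all <- lapply(seq_len(n), function(i) dist_to_boundary(xy[i, ]))
  dists <- vapply(db_all, function(d) d$dist, 0)
  near <- which(dists <= tol & xy[, 2] > y_mw + tol / 2)
  if (!length(near))
    fo_stop("not_applicable", "front does not touch the obstacle boundary beyond its maximal width")
  x_center <- mean(range(v[, 1]))
  # measure on the right contact (mirror-symmetric geometry); the contact
  # vertex is the innermost near vertex on that side
  right <- near[xy[near, 1] > x_center]
  if (!length(right)) right <- near
  i <- right[which.min(xy[right, 1])]
  # front tangent at the contact, walking outward (increasing x)
  closed_form <- identical(attr(front, "provenance"), "closed-form")
  if (closed_form) {
    ids <- i + 0:2
    ids <- ids[ids <= n]
    if (length(ids) < 2)
      fo_stop("measurement_error", "not enough vertices to estimate the tangent")
    if (length(ids) == 3) {
      p0 <- xy[ids[1], ]; p1 <- xy[ids[2], ]; p2 <- xy[ids[3], ]
      tangent <- (4 * (p1 - p0) - (p2 - p0)) / 2   # parabola tangent at p0
    } else {
      tangent <- xy[ids[2], ] - xy[ids[1], ]
    }
  } else {
    # discretized fronts: vertices within ~2 spacings of the obstacle mask are
    # staircase-distorted, so fit a parabola (arc-length parameterized) over
    # clean vertices further out and extrapolate the tangent to the contact
    sp <- stats::median(sqrt(rowSums(diff(xy)^2)), na.rm = TRUE)
    seg <- xy[i:n, , drop = FALSE]
    tlen <- c(0, cumsum(sqrt(rowSums(diff(seg)^2))))
    use <- which(tlen >= 3 * sp & tlen <= 15 * sp)
    if (length(use) < 4)
      fo_stop("measurement_error", "not enough vertices to estimate the tangent")
    tt2 <- tlen[use]
    cx <- coef(lm(seg[use, 1] ~ tt2 + I(tt2^2)))
    cy <- coef(lm(seg[use, 2] ~ tt2 + I(tt2^2)))
    tangent <- c(cx[2], cy[2])                     # derivative at t = 0
  }
  e <- db_all[[i]]$edge
  cosang <- abs(sum(tangent * e)) /
    (sqrt(sum(tangent^2)) * sqrt(sum(e^2)))
  ang <- acos(pmin(1, cosang)) * 180 / pi
  attr(ang, "contact_point") <- xy[i, ]
  ang
}

#' Width-rescaling collapse of indent curves
#'
#' Rescales each series by its own obstacle half-width (`d/w`, `Delta/w`),
#' interpolates to a common `d/w` grid over the shared range, and reports
#' the maximum pairwise sup-distance.  With `rescale_by = "h"` the same
#' procedure uses the half-heights — for rhombi of different aspect ratio
#' this collapses demonstrably worse, which is the negative control.
#'
#' @param series list of indent series (each with its scale attribute or a
#'   `scale` column); for `rescale_by = "h"` supply `scales` explicitly
#' @param scales numeric vector of rescaling lengths (one per series);
#'   default the series' `w_half` attributes
#' @param rescale_by label stored in the report (`"w"` or `"h"`)
#' @param n_grid number of common-grid points
#' @return an object of class `fo_collapse`: `max_sup_distance`, per-pair
#'   distances, the common grid and rescaled curves
#' @export
collapse_check <- function(series, scales = NULL, rescale_by = "w",
                           n_grid = 200L) {
  if (length(series) < 2) fo_stop("parameter_error", "need at least two series")
  if (is.null(scales))
    scales <- vapply(series, function(s) attr(s, "w_half"), 0)
  if (any(is.na(scales)))
    fo_stop("parameter_error", "every series needs a rescaling length")
  resc <- Map(function(s, sc) data.frame(d = s$d / sc, delta = s$delta / sc),
              series, scales)
  lo <- max(vapply(resc, function(s) min(s$d), 0))
  hi <- min(vapply(resc, function(s) max(s$d), 0))
  if (hi <= lo) fo_stop("alignment_error", "rescaled d ranges do not overlap")
  grid <- seq(lo, hi, length.out = n_grid)
  curves <- vapply(resc, function(s) approx(s$d, s$delta, xout = grid)$y,
                   numeric(n_grid))
  np <- length(series)
  dists <- matrix(0, np, np)
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    dists[i, j] <- dists[j, i] <- max(abs(curves[, i] - curves[, j]))
  }
  structure(list(max_sup_distance = max(dists), pair_distances = dists,
                 grid = grid, curves = curves, rescale_by = rescale_by),
            class = "fo_collapse")
}

#' @export
print.fo_collapse <- function(x, ...) {
  cat(sprintf("<fo_collapse> %d curves rescaled by %s, max sup-distance %.4g\n",
              ncol(x$curves), x$rescale_by, x$max_sup_distance))
  invisible(x)
}
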