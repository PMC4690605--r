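## Generalized FKPP reaction-diffusion model:
##   du/dt = D_eff Lap u + k_eff(x) u (K - u),   K = 1 after rescaling,
## with k_eff = k_hat outside obstacles and 0 inside (diffusion into the
## obstacle remains possible, an absorbing-boundary-like sink).  Space is
## discretized with the nine-point Laplacian, time integrated by an adaptive
## Adams method (method of lines).

#' Parameter set for the FKPP engine
#'
#' @param D_eff diffusion coefficient (mm^2/h)
#' @param k_hat growth rate outside obstacles (1/h)
#' @param u_thresh front threshold on the population density (default 0.05;
#'   0.5 is the alternate used for robustness checks)
#' @param a_grid lattice spacing (mm); default `0.15 * sqrt(D_eff / k_hat)`,
#'   must not exceed `0.2 * xi`
#' @param rtol,atol integrator tolerances.  The absolute tolerance default is
#'   kept well below the front threshold so that the leading edge (where
#'   densities are tiny) stays resolved and density bounds hold to roundoff
#'   of the error control.
#' @param D_obstacle diffusion coefficient inside obstacles (mm^2/h);
#'   defaults to `D_eff` (same diffusivity, zero growth)
#' @return an object of class `fo_fkpp_params` with derived quantities
#'   `v = 2 sqrt(D_eff k_hat)` (pulled-front speed), `xi = sqrt(D_eff/k_hat)`
#'   (front width parameter) and dimensionless front speed constant `c = 2`
#' @export
fkpp_params <- function(D_eff, k_hat, u_thresh = 0.05, a_grid = NULL,
                        rtol = 1e-6, atol = 1e-8, D_obstacle = NULL) {
  if (D_eff <= 0 || k_hat <= 0) fo_stop("parameter_error", "D_eff and k_hat must be positive")
  if (u_thresh <= 0 || u_thresh >= 1) fo_stop("parameter_error", "u_thresh must be in (0,1)")
  xi <- sqrt(D_eff / k_hat)
  if (is.null(a_grid)) a_grid <- 0.15 * xi
  if (a_grid > 0.2 * xi)
    fo_stop("parameter_error", "a_grid must be <= 0.2 * xi")
  if (is.null(D_obstacle)) D_obstacle <- D_eff
  structure(list(D_eff = D_eff, k_hat = k_hat, K = 1, u_thresh = u_thresh,
                 a_grid = a_grid, rtol = rtol, atol = atol,
                 D_obstacle = D_obstacle, c = 2,
                 v = 2 * sqrt(D_eff * k_hat), xi = xi),
            class = "fo_fkpp_params")
}

#' Nine-point discrete Laplacian
#'
#' `Lap u = [-20 u + sum(corner neighbors) + 4 sum(edge neighbors)]/(6 a^2)`,
#' exact on quadratics.  Interior cells only; boundary cells are `NA`.
#'
#' @param u matrix of samples
#' @param a_grid lattice spacing (mm)
#' @return matrix of the same shape (1/mm^2 scaling)
#' @export
nine_point_laplacian <- function(u, a_grid) {
  if (!is.matrix(u) || nrow(u) < 3 || ncol(u) < 3)
    fo_stop("size_error", "grid must be at least 3 x 3")
  nine_point_lap_cpp(u, a_grid)
}

#' Initial condition: saturated region with a linear ramp
#'
#' `u = 1` for `y < y0_front`, a linear ramp down to 0 over `ramp_width`
#' (default `2 xi`), 0 beyond; the ramp develops into the Fisher wave profile
#' while traveling toward the obstacle.  A warning is recorded if any
#' obstacle sits closer than `10 xi` to the initial front.
#'
#' @param env an `fo_env`
#' @param params an `fo_fkpp_params`
#' @param y0_front initial front position (mm)
#' @param ramp_width ramp width (mm)
#' @param nx_min minimum number of lateral columns (quasi-1D runs)
#' @return an object of class `fo_fkpp_state`: fields `u` (nx x ny matrix,
#'   x lateral / periodic, y propagation), `kmap`, `x`, `y`, `t`, `params`,
#'   `env`, `n_clamp_lo`, `n_clamp_hi`
#' @export
initial_condition <- function(env, params, y0_front, ramp_width = NULL,
                              nx_min = 4L) {
  a <- params$a_grid
  if (is.null(ramp_width)) ramp_width <- 2 * params$xi
  xs <- seq(a / 2, env$domain[1], by = a)
  if (length(xs) < nx_min)
    fo_stop("size_error", "domain too narrow for the requested lattice")
  ys <- seq(a / 2, env$domain[2], by = a)
  for (ob in env$obstacles) {
    gap <- min(ob$vertices[, 2]) - y0_front
    if (gap <= 0)
      fo_stop("invalid_geometry", "initial front must lie below all obstacles")
    if (gap < 10 * params$xi)
      fo_warn("front_development",
              "obstacle closer than 10*xi to the initial front; the Fisher profile may not be developed on contact")
  }
  uy <- ifelse(ys < y0_front, 1,
               pmax(0, 1 - (ys - y0_front) / ramp_width))
  u <- matrix(rep(uy, each = length(xs)), length(xs), length(ys))
  mask <- raster_mask(env, xs, ys)
  kmap <- matrix(params$k_hat, length(xs), length(ys))
  kmap[mask] <- 0
  n_clamp <- 2L
  if (any(mask[, c(seq_len(n_clamp), length(ys) - seq_len(n_clamp) + 1L)]))
    fo_stop("invalid_geometry", "obstacle overlaps the clamped boundary rows")
  structure(list(u = u, kmap = kmap, mask = mask, x = xs, y = ys, t = 0,
                 params = params, env = env,
                 n_clamp_lo = n_clamp, n_clamp_hi = n_clamp),
            class = "fo_fkpp_state")
}

#' Integrate the FKPP equation (method of lines)
#'
#' Advances the density field to the requested times with the nine-point
#' stencil, periodic lateral boundaries and rows clamped to 1 (behind) and 0
#' (ahead), using `deSolve::ode` (adaptive Adams by default, mirroring the
#' predictor-corrector family commonly used for this discretization).
#'
#' @param state an `fo_fkpp_state` (from [initial_condition()])
#' @param times increasing vector of output times (h), starting at or after
#'   `state$t`
#' @param method `deSolve` method name
#' @param maxsteps solver step budget between outputs
#' @return an object of class `fo_fkpp_run`: `times`, `states` (list of
#'   `fo_fkpp_state` snapshots)
#' @export
fkpp_integrate <- function(state, times, method = "adams", maxsteps = 1e6) {
  p <- state$params
  nx <- length(state$x); ny <- length(state$y)
  if (any(diff(times) <= 0) || times[1] < state$t)
    fo_stop("parameter_error", "times must increase from the current state time")
  fkpp_set_ctx(as.numeric(state$kmap), p$D_eff, p$a_grid, nx, ny,
               state$n_clamp_lo, state$n_clamp_hi)
  tspan <- if (times[1] > state$t) c(state$t, times) else times
  sol <- deSolve::ode(y = as.numeric(state$u), times = tspan,
                      func = "fkpp_deriv_c", dllname = "frontobstacles",
                      initfunc = NULL, parms = NULL, method = method,
                      rtol = p$rtol, atol = p$atol, maxsteps = maxsteps)
  if (attr(sol, "istate")[1] < 0)
    fo_stop("integration_error", "ODE solver failed; see deSolve diagnostics")
  keep <- match(times, sol[, 1])
  states <- lapply(keep, function(i) {
    s <- state
    s$u <- matrix(sol[i, -1], nx, ny)
    s$t <- sol[i, 1]
    s
  })
  structure(list(times = times, states = states), class = "fo_fkpp_run")
}

#' Extract the threshold front from a density field
#'
#' Sub-cell linearly interpolated contour of `u = u_thresh` taken as the
#' topmost crossing in each lateral column, obstacle cells masked (the front
#' is defined outside the obstacle).  The front-position label `d` uses the
#' lateral-edge columns (the unperturbed part of the front), relative to the
#' reference obstacle's point of maximal width.
#'
#' @param state an `fo_fkpp_state`
#' @param u_thresh threshold (default the parameter set's)
#' @param ref reference obstacle index for the `d` label
#' @return an `fo_front`
#' @export
extract_front <- function(state, u_thresh = NULL, ref = 1L) {
  if (is.null(u_thresh)) u_thresh <- state$params$u_thresh
  u <- state$u
  u[state$mask] <- NA_real_
  nx <- nrow(u); ny <- ncol(u)
  xs <- numeric(0); ysout <- numeric(0)
  for (i in seq_len(nx)) {
    col <- u[i, ]
    above <- which(!is.na(col) & col >= u_thresh)
    if (!length(above)) next
    j <- max(above)
    if (j < ny && !is.na(col[j + 1]) && col[j + 1] < u_thresh) {
      yv <- state$y[j] + state$params$a_grid *
        (col[j] - u_thresh) / (col[j] - col[j + 1])
    } else {
      yv <- state$y[j]
    }
    xs <- c(xs, state$x[i]); ysout <- c(ysout, yv)
  }
  if (!length(xs)) fo_stop("empty_front", "threshold level not present")
  y_ref <- env_ref_y(state$env, ref)
  d <- mean(c(ysout[1], ysout[length(xs)])) - y_ref
  w_half <- if (state$env$n_obstacles) state$env$obstacles[[ref]]$w_half else NA_real_
  new_front(xs, ysout, d = d, provenance = "pde", y_ref = y_ref, w_half = w_half)
}

#' Effective growth rate from front speed and diffusion coefficient
#'
#' Inverts the pulled-front dispersion relation `v = 2 sqrt(D k)`:
#' `k = v^2 / (4 D)`.
#'
#' @param v front speed (mm/h)
#' @param D_eff diffusion coefficient (mm^2/h)
#' @return growth rate (1/h)
#' @examples
#' estimate_growth_rate(0.2, 0.0144)  # ~0.69/h
#' @export
estimate_growth_rate <- function(v, D_eff) {
  if (v <= 0 || D_eff <= 0) fo_stop("parameter_error", "inputs must be positive")
  v^2 / (4 * D_eff)
}

#' Stokes-Einstein diffusion coefficient of a sphere
#'
#' `D = k_B T / (3 pi eta d)`, converted to mm^2/h.  Used as an upper-bound
#' estimate of a virion's diffusivity in water.
#'
#' @param diameter_nm sphere diameter (nm)
#' @param viscosity_mPas dynamic viscosity (mPa s)
#' @param temperature_K temperature (K)
#' @return diffusion coefficient (mm^2/h)
#' @examples
#' stokes_einstein_D(60, 0.692, 310.15)  # ~0.04 mm^2/h
#' @export
stokes_einstein_D <- function(diameter_nm, viscosity_mPas, temperature_K) {
  if (diameter_nm <= 0 || viscosity_mPas <= 0 || temperature_K <= 0)
    fo_stop("parameter_error", "inputs must be positive")
  kB <- 1.380649e-23                       # J/K
  D_m2s <- kB * temperature_K /
    (3 * pi * viscosity_mPas * 1e-3 * diameter_nm * 1e-9)
  D_m2s * 1e6 * 3600                       # m^2/s -> mm^2/h
}

#' Approximate comoving Fisher-wave profile
#'
#' The analytic approximation to the steady pulled-front profile in the
#' comoving coordinate `z = y' * sqrt(k/D)` with dimensionless speed `c = 2`:
#' `u(z) = (1 + e^{z/c})^{-1} + (1/4) e^{z/c} (1 + e^{z/c})^{-2}
#'  ln(4 e^{z/c} (1 + e^{z/c})^{-2})`.  Satisfies `u(0) = 1/2` exactly.
#'
#' @param z comoving coordinate (dimensionless)
#' @param c dimensionless front speed (default 2)
#' @export
comoving_profile <- function(z, c = 2) {
  e <- exp(z / c)
  1 / (1 + e) + 0.25 * e / (1 + e)^2 * log(4 * e / (1 + e)^2)
}

#' Fit the planar front speed of a run
#'
#' Linear fit of the unperturbed (lateral-edge) front position against time
#' over the snapshots of a run.
#'
#' @param run an `fo_fkpp_run` from an obstacle-free (planar) integration
#' @param u_thresh threshold level
#' @return fitted speed (mm/h)
#' @export
fit_front_speed <- function(run, u_thresh = NULL) {
  pos <- vapply(run$states, function(s) {
    fr <- extract_front(s, u_thresh)
    mean(c(fr$y[1], fr$y[nrow(fr)]))
  }, 0)
  unname(coef(lm(pos ~ run$times))[2])
}

#' Lag of the reaction-diffusion front behind the constant-speed prediction
#'
#' Interpolates the eikonal indent series at the d values of the PDE series
#' and reports the per-d excess indent `Delta_pde - Delta_eikonal` (the lag).
#'
#' @param pde_series,eikonal_series indent series (`data.frame(d, delta)`,
#'   from [indent_from_front()] wrappers) over overlapping d ranges
#' @return data.frame with columns `d`, `delta_pde`, `delta_eik`, `lag`
#' @export
lag_vs_eikonal <- function(pde_series, eikonal_series) {
  rng <- range(eikonal_series$d)
  use <- pde_series$d >= rng[1] & pde_series$d <= rng[2]
  if (!any(use))
    fo_stop("alignment_error", "d ranges of the two series do not overlap")
  dmatch <- pde_series$d[use]
  eik <- approx(eikonal_series$d, eikonal_series$delta, xout = dmatch)$y
  data.frame(d = dmatch, delta_pde = pde_series$delta[use],
             delta_eik = eik, lag = pde_series$delta[use] - eik)
}
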