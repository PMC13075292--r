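#' Moving-boundary state
#'
#' Parameters of the idealized moving reaction boundary: the plateau
#' conductivities of the zone behind (`sigma1`, the crystal-violet zone, lower
#' conductivity) and ahead (`sigma2`) of the boundary, the boundary migration
#' velocity `U`, an effective diffusion coefficient `D` governing the width of
#' the error-function front, and optional localized features superimposed on
#' the front: a depletion trough (the nearly carrier-free reaction zone at the
#' leading edge) and an anion-accumulation bump further ahead.
#'
#' `U` may be negative: below the flux-balance concentration the titrant flux
#' exceeds the analyte-ion flux and the boundary retreats toward the anode.
#'
#' @param sigma1,sigma2 Zone conductivities behind/ahead of the boundary,
#'   S m^-1 (both > 0).
#' @param U Boundary migration velocity, mm min^-1 (signed).
#' @param D Effective diffusion coefficient, m^2 s^-1 (> 0).
#' @param c0 Characteristic cation concentration at the boundary midpoint,
#'   mol m^-3.
#' @param depletion_amp Depth of the leading-edge depletion trough, S m^-1
#'   (>= 0; 0 disables it).
#' @param depletion_width Gaussian width (SD) of the trough, mm.
#' @param depletion_offset Trough center relative to the boundary midpoint, mm
#'   (non-negative; 0 centers the trough on the boundary).
#' @param accumulation_amp Height of the anion-accumulation bump, S m^-1
#'   (>= 0; 0 disables it).
#' @param accumulation_width Gaussian width (SD) of the bump, mm.
#' @param accumulation_offset Bump center ahead of the boundary midpoint, mm.
#' @return An object of class `"boundary_state"`.
#' @examples
#' boundary_state(U = 0.25)
#' @export
boundary_state <- function(sigma1 = 0.5, sigma2 = 1.0, U = 0.25, D = 5e-10,
                           c0 = 0.2,
                           depletion_amp = 0, depletion_width = 0.2,
                           depletion_offset = 0,
                           accumulation_amp = 0, accumulation_width = 0.6,
                           accumulation_offset = 1.2) {
  if (!is.finite(sigma1) || sigma1 <= 0 || !is.finite(sigma2) || sigma2 <= 0)
    .stop_domain("sigma1 and sigma2 must be > 0")
  if (!is.finite(D) || D <= 0) .stop_domain("D must be > 0")
  if (!is.finite(U)) .stop_domain("U must be finite")
  if (c0 < 0) .stop_domain("c0 must be >= 0")
  if (depletion_amp < 0 || accumulation_amp < 0)
    .stop_domain("feature amplitudes must be >= 0")
  if (depletion_width <= 0 || accumulation_width <= 0)
    .stop_domain("feature widths must be > 0")
  structure(list(sigma1 = sigma1, sigma2 = sigma2, U = U, D = D, c0 = c0,
                 depletion_amp = depletion_amp,
                 depletion_width = depletion_width,
                 depletion_offset = depletion_offset,
                 accumulation_amp = accumulation_amp,
                 accumulation_width = accumulation_width,
                 accumulation_offset = accumulation_offset),
            class = "boundary_state")
}

#' @export
print.boundary_state <- function(x, ...) {
  cat(sprintf("<boundary_state> sigma1 %.3g, sigma2 %.3g S/m; U %+.3g mm/min; D %.3g m^2/s\n",
              x$sigma1, x$sigma2, x$U, x$D))
  if (x$depletion_amp > 0)
    cat(sprintf("  depletion trough: amp %.3g S/m, width %.3g mm, offset %+.3g mm\n",
                x$depletion_amp, x$depletion_width, x$depletion_offset))
  if (x$accumulation_amp > 0)
    cat(sprintf("  accumulation bump: amp %.3g S/m, width %.3g mm, offset %+.3g mm\n",
                x$accumulation_amp, x$accumulation_width, x$accumulation_offset))
  invisible(x)
}

#' Spatial conductivity profile
#'
#' Conductivity along the channel on a uniform grid at a given electrophoresis
#' time.
#'
#' @param x Strictly increasing, uniformly spaced positions, mm.
#' @param sigma Conductivity at each grid point, S m^-1 (finite).
#' @param time Electrophoresis time of the snapshot, min.
#' @return An object of class `"spatial_profile"`.
#' @export
spatial_profile <- function(x, sigma, time = NA_real_) {
  if (length(x) < 2L || length(x) != length(sigma))
    .stop_domain("x and sigma must have equal length >= 2")
  dx <- diff(x)
  if (any(dx <= 0)) .stop_domain("x must be strictly increasing")
  if (max(dx) - min(dx) > 1e-9 * max(dx)) .stop_domain("x must be uniformly spaced")
  if (any(!is.finite(sigma))) .stop_domain("sigma must be finite")
  structure(list(x = as.numeric(x), sigma = as.numeric(sigma),
                 time = as.numeric(time)),
            class = "spatial_profile")
}

#' @export
print.spatial_profile <- function(x, ...) {
  cat(sprintf("<spatial_profile> %d points over [%.3g, %.3g] mm at t = %.3g min; sigma in [%.3g, %.3g] S/m\n",
              length(x$x), min(x$x), max(x$x), x$time, min(x$sigma), max(x$sigma)))
  invisible(x)
}

#' @export
plot.spatial_profile <- function(x, ...) {
  graphics::plot(x$x, x$sigma, type = "l", xlab = "x (mm)",
                 ylab = expression(sigma ~ (S/m)),
                 main = sprintf("Conductivity profile at t = %.3g min", x$time), ...)
  invisible(x)
}

#' Piecewise-linear boundary profile
#'
#' Sharp-boundary idealization: conductivity `sigma1` behind the boundary
#' (`x <= x1`), `sigma2` ahead (`x >= x2`), and a linear transition in
#' between, continuous at both ends.
#'
#' @param state A [boundary_state()] (only `sigma1`, `sigma2` are used).
#' @param x1,x2 Transition edges, mm, with `x1 < x2`.
#' @param grid Positions at which to evaluate, mm (uniform, increasing).
#' @param time Electrophoresis time label for the profile, min.
#' @return A [spatial_profile()].
#' @export
linear_boundary_profile <- function(state, x1, x2, grid, time = NA_real_) {
  stopifnot(inherits(state, "boundary_state"))
  if (!is.finite(x1) || !is.finite(x2) || x1 >= x2)
    .stop_domain("x1 must be < x2")
  s <- ifelse(grid <= x1, state$sigma1,
              ifelse(grid >= x2, state$sigma2,
                     state$sigma1 + (state$sigma2 - state$sigma1) *
                       (grid - x1) / (x2 - x1)))
  spatial_profile(grid, s, time)
}

#' Error-function concentration front
#'
#' Concentration of the migrating cation around a diffusing advected front:
#' `c(x, t) = c0 * (1 - erf((x - x_origin - U t) / (2 sqrt(D t))))`.
#' The profile decreases monotonically in `x`, approaching `2 c0` far behind
#' the boundary and 0 far ahead; at the boundary midpoint `x = x_origin + U t`
#' it equals `c0`.
#'
#' @param x Positions, mm.
#' @param t Electrophoresis time, min (> 0).
#' @param state A [boundary_state()]; uses `c0`, `U`, `D`.
#' @param x_origin Position where the boundary formed at `t = 0`, mm.
#' @return Concentrations, mol m^-3.
#' @export
erf_front_concentration <- function(x, t, state, x_origin = 0) {
  stopifnot(inherits(state, "boundary_state"))
  if (!is.finite(t) || t <= 0) .stop_domain("t must be > 0")
  state$c0 * (1 - .erf(.front_xi(x, t, state, x_origin)))
}

# dimensionless front coordinate (x - x0 - U t) / (2 sqrt(D t)), lengths in mm
.front_xi <- function(x, t, state, x_origin) {
  ell_mm <- 2 * sqrt(state$D * t * 60) * 1000
  (x - x_origin - state$U * t) / ell_mm
}

#' Error-function conductivity profile
#'
#' Conductivity around the boundary in the diffuse-front model, in the
#' asymptote-consistent form
#' `sigma(x, t) = sigma1 + (sigma2 - sigma1)/2 * (1 + erf((x - x_origin - U t) / (2 sqrt(D t))))`,
#' so that `sigma -> sigma1` far behind and `sigma -> sigma2` far ahead of the
#' boundary, with `(sigma1 + sigma2)/2` at the midpoint. If the state carries
#' nonzero depletion/accumulation amplitudes, a Gaussian trough (and bump) is
#' superimposed near the leading edge, reproducing the characteristic
#' single-trough scan signature.
#'
#' @inheritParams erf_front_concentration
#' @param grid Positions at which to evaluate, mm (uniform, increasing).
#' @return A [spatial_profile()]. Errors if the requested feature amplitudes
#'   drive the conductivity to zero or below anywhere on the grid.
#' @export
erf_conductivity_profile <- function(grid, t, state, x_origin = 0) {
  stopifnot(inherits(state, "boundary_state"))
  if (!is.finite(t) || t <= 0) .stop_domain("t must be > 0")
  s <- state$sigma1 + (state$sigma2 - state$sigma1) / 2 *
    (1 + .erf(.front_xi(grid, t, state, x_origin)))
  xb <- x_origin + state$U * t
  if (state$depletion_amp > 0)
    s <- s - state$depletion_amp *
      exp(-0.5 * ((grid - xb - state$depletion_offset) / state$depletion_width)^2)
  if (state$accumulation_amp > 0)
    s <- s + state$accumulation_amp *
      exp(-0.5 * ((grid - xb - state$accumulation_offset) / state$accumulation_width)^2)
  if (any(s <= 0))
    .stop_domain("feature amplitudes drive conductivity <= 0; reduce depletion_amp")
  spatial_profile(grid, s, t)
}
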