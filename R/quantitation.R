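#' Boundary velocity from a series of fixes
#'
#' Ordinary least-squares line of boundary position (mm) against
#' electrophoresis clock (min); the slope is the average boundary migration
#' velocity `V_MRB`.
#'
#' @param fixes A `boundary_fixes` data frame (see
#'   [fixes_from_scan_series()]), or any data frame with columns `clock_min`
#'   and `x_boundary_mm` (and optionally `valid`).
#' @return An object of class `"mrb_velocity"` with fields `v_mrb`
#'   (mm min^-1), `intercept` (mm), `r2`, `n_points`, `residual_sd` (mm) and
#'   the fitted data. Requires at least 3 fixes with distinct clocks.
#' @examples
#' f <- data.frame(clock_min = c(5, 7, 9, 11), x_boundary_mm = 1:4)
#' fit_velocity(f)
#' @export
fit_velocity <- function(fixes) {
  if (!is.data.frame(fixes) ||
      !all(c("clock_min", "x_boundary_mm") %in% names(fixes)))
    .stop_config("fixes must have columns clock_min and x_boundary_mm")
  if ("valid" %in% names(fixes)) fixes <- fixes[fixes$valid, , drop = FALSE]
  fixes <- fixes[is.finite(fixes$clock_min) & is.finite(fixes$x_boundary_mm), ,
                 drop = FALSE]
  n <- nrow(fixes)
  if (n < 3L) .stop_nodata(sprintf("need >= 3 valid fixes, got %d", n))
  if (length(unique(fixes$clock_min)) < 2L)
    .stop_nodata("degenerate clocks: all fixes at the same time")
  fit <- stats::lm(x_boundary_mm ~ clock_min, data = fixes)
  res <- stats::residuals(fit)
  tss <- sum((fixes$x_boundary_mm - mean(fixes$x_boundary_mm))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
  structure(list(v_mrb = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = r2, n_points = n,
                 residual_sd = if (n > 2) sqrt(sum(res^2) / (n - 2)) else 0,
                 data = fixes[, c("clock_min", "x_boundary_mm")]),
            class = "mrb_velocity")
}

#' @export
print.mrb_velocity <- function(x, ...) {
  cat(sprintf("Boundary velocity fit (n = %d)\n  V_MRB = %.4f mm/min, intercept = %.4f mm, R^2 = %.4f\n",
              x$n_points, x$v_mrb, x$intercept, x$r2))
  invisible(x)
}

#' @export
coef.mrb_velocity <- function(object, ...)
  c(intercept = object$intercept, v_mrb = object$v_mrb)

#' @export
summary.mrb_velocity <- function(object, ...) {
  print(object)
  cat(sprintf("  residual SD = %.4g mm\n", object$residual_sd))
  invisible(object)
}

#' @export
predict.mrb_velocity <- function(object, clock_min, ...)
  object$intercept + object$v_mrb * clock_min

#' @export
residuals.mrb_velocity <- function(object, ...)
  object$data$x_boundary_mm - predict(object, object$data$clock_min)

#' @export
plot.mrb_velocity <- function(x, ...) {
  graphics::plot(x$data$clock_min, x$data$x_boundary_mm,
                 xlab = "electrophoresis time (min)",
                 ylab = "boundary position (mm)",
                 main = sprintf("V_MRB = %.3f mm/min (R^2 = %.3f)", x$v_mrb, x$r2),
                 ...)
  graphics::abline(x$intercept, x$v_mrb)
  invisible(x)
}

#' Velocity-versus-log-concentration calibration
#'
#' Fits the quantitation law `v = a * log10(C) + b` by ordinary least squares
#' on calibration points (concentration in mM, velocity in mm min^-1). The
#' slope is in mm min^-1 per decade of concentration.
#'
#' @param conc Concentrations, mM (all > 0), or a data frame with columns
#'   `conc_mM` and `v_mrb`.
#' @param v Velocities, mm min^-1 (ignored when `conc` is a data frame).
#' @return An object of class `"mrb_calibration"` with fields `slope_a`,
#'   `intercept_b`, `r2`, `conc_range` (mM), `lod` (`NA` until
#'   [compute_lod()] is applied) and the calibration data.
#' @examples
#' cal <- fit_calibration(c(0.2, 1, 10, 50), 0.272 * log10(c(0.2, 1, 10, 50)) - 0.011)
#' coef(cal)
#' @export
fit_calibration <- function(conc, v = NULL) {
  if (is.data.frame(conc)) {
    if (!all(c("conc_mM", "v_mrb") %in% names(conc)))
      .stop_config("calibration data frame needs columns conc_mM and v_mrb")
    v <- conc$v_mrb
    conc <- conc$conc_mM
  }
  if (length(conc) != length(v)) .stop_config("conc and v lengths differ")
  if (length(conc) < 3L) .stop_nodata("need >= 3 calibration points")
  if (any(!is.finite(conc)) || any(conc <= 0))
    .stop_domain("concentrations must be finite and > 0")
  lx <- log10(conc)
  fit <- stats::lm(v ~ lx)
  res <- stats::residuals(fit)
  tss <- sum((v - mean(v))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
  structure(list(slope_a = unname(coef(fit)[2]),
                 intercept_b = unname(coef(fit)[1]),
                 r2 = r2, conc_range = range(conc), lod = NA_real_,
                 data = data.frame(conc_mM = conc, v_mrb = v)),
            class = "mrb_calibration")
}

#' @export
print.mrb_calibration <- function(x, ...) {
  cat(sprintf("Calibration v = a*log10(C) + b (n = %d)\n  a = %.4f mm/min per decade, b = %.4f mm/min, R^2 = %.4f\n  range %.3g-%.3g mM%s\n",
              nrow(x$data), x$slope_a, x$intercept_b, x$r2,
              x$conc_range[1], x$conc_range[2],
              if (is.na(x$lod)) "" else sprintf(", LOD %.3g mM", x$lod)))
  invisible(x)
}

#' @export
coef.mrb_calibration <- function(object, ...)
  c(slope_a = object$slope_a, intercept_b = object$intercept_b)

#' @export
summary.mrb_calibration <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.mrb_calibration <- function(x, ...) {
  graphics::plot(log10(x$data$conc_mM), x$data$v_mrb,
                 xlab = "log10 concentration (mM)",
                 ylab = "V_MRB (mm/min)",
                 main = sprintf("v = %.3f log10(C) %+.3f (R^2 = %.3f)",
                                x$slope_a, x$intercept_b, x$r2),
                 ...)
  graphics::abline(x$intercept_b, x$slope_a)
  invisible(x)
}

#' @export
predict.mrb_calibration <- function(object, v, ...)
  predict_concentration(object, v)

#' Inverse prediction of concentration from velocity
#'
#' Inverts the calibration: `C = 10^((v - b) / a)` mM. Values outside the
#' calibrated concentration range are returned with a warning attribute.
#'
#' @param model An `"mrb_calibration"` object.
#' @param v Measured velocities, mm min^-1.
#' @return Concentrations, mM, with attribute `"extrapolated"` (logical
#'   vector) flagging predictions outside the calibration range.
#' @export
predict_concentration <- function(model, v) {
  stopifnot(inherits(model, "mrb_calibration"))
  if (abs(model$slope_a) < 1e-12) .stop_domain("degenerate model: zero slope")
  conc <- 10^((v - model$intercept_b) / model$slope_a)
  extra <- conc < model$conc_range[1] | conc > model$conc_range[2]
  attr(conc, "extrapolated") <- extra
  conc
}

#' Limit of detection by inverse prediction
#'
#' Concentration whose calibrated velocity equals the blank velocity plus `k`
#' blank standard deviations: `LOD = 10^(((v_blank + k * blank_sd) - b) / a)`.
#' The blank velocity defaults to 0; both the multiplier and the blank
#' convention are explicit parameters because detection-limit conventions
#' vary. Note that with a log-linear law whose zero-velocity crossing lies
#' inside the calibrated range, the `v_blank = 0` default names the crossing
#' concentration rather than a vanishing amount, so choose `v_blank`
#' deliberately for the instrument at hand.
#'
#' @param model An `"mrb_calibration"` with positive slope.
#' @param blank_sd Standard deviation of replicate blank velocities,
#'   mm min^-1 (>= 0).
#' @param k Multiplier (default 3).
#' @param v_blank Mean blank velocity, mm min^-1 (default 0).
#' @return LOD in mM.
#' @export
compute_lod <- function(model, blank_sd, k = 3, v_blank = 0) {
  stopifnot(inherits(model, "mrb_calibration"))
  if (!is.finite(blank_sd) || blank_sd < 0) .stop_domain("blank_sd must be >= 0")
  if (!is.finite(model$slope_a) || model$slope_a < 1e-12)
    .stop_domain("degenerate model: slope must be > 0 for an LOD")
  10^(((v_blank + k * blank_sd) - model$intercept_b) / model$slope_a)
}

#' Relative standard deviation of replicates
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation.
#'
#' @param values Replicate measurements (n >= 2, nonzero mean).
#' @return RSD in percent.
#' @examples
#' compute_rsd(c(9, 10, 11))  # 10
#' @export
compute_rsd <- function(values) {
  if (length(values) < 2L) .stop_domain("need >= 2 replicates")
  m <- mean(values)
  if (m == 0) .stop_domain("zero mean: RSD undefined")
  100 * stats::sd(values) / m
}

#' Spike recovery
#'
#' `100 * found / spiked`, reported to one decimal place.
#'
#' @param spiked Spiked concentration (> 0).
#' @param found Measured (found) concentration.
#' @return Recovery in percent, rounded to 1 decimal.
#' @examples
#' compute_recovery(100, 89.1)   # 89.1
#' compute_recovery(350, 376.8)  # 107.7
#' @export
compute_recovery <- function(spiked, found) {
  if (any(!is.finite(spiked)) || any(spiked <= 0))
    .stop_domain("spiked must be > 0")
  round(100 * found / spiked, 1)
}
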