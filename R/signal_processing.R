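#' Subtract a background scan from a sample scan
#'
#' Removes the background recorded by an initial scan of the pre-filled chip.
#' The baseline is registered on the detector position axis and resampled onto
#' the sample trace's grid by linear interpolation (no warping), then
#' subtracted pointwise. Scan kinematics metadata of the sample trace are
#' preserved.
#'
#' @param trace Sample [scan_trace()].
#' @param baseline Background [scan_trace()] recorded with the same scan
#'   speed (an error is raised otherwise).
#' @return A [scan_trace()] with the background removed.
#' @export
subtract_baseline <- function(trace, baseline) {
  stopifnot(inherits(trace, "scan_trace"), inherits(baseline, "scan_trace"))
  if (abs(trace$scan_speed - baseline$scan_speed) >
      1e-9 * max(trace$scan_speed, baseline$scan_speed))
    .stop_config("incompatible scan kinematics: scan speeds differ")
  xs <- scan_positions(trace)
  xb <- scan_positions(baseline)
  b <- stats::approx(xb, baseline$signal, xout = xs, rule = 2)$y
  scan_trace(trace$t, trace$signal - b, scan_speed = trace$scan_speed,
             scan_start_clock = trace$scan_start_clock,
             x_start = trace$x_start, sample_rate = trace$sample_rate)
}

#' Centered moving-average filter
#'
#' Smooths a signal with a centered mean over an odd-width window (default 5
#' points). At the edges the window shrinks symmetrically so the output has
#' the same length as the input and no data are fabricated.
#'
#' @param signal Numeric vector.
#' @param window Odd positive integer window width, at most `length(signal)`.
#' @return Smoothed vector, same length as the input.
#' @examples
#' moving_average(c(1, 2, 6, 2, 1))
#' @export
moving_average <- function(signal, window = 5L) {
  n <- length(signal)
  if (length(window) != 1L || !is.finite(window) || window < 1 ||
      window %% 2 == 0)
    .stop_domain("window must be an odd positive integer")
  if (window > n) .stop_domain("window exceeds signal length")
  if (window == 1L) return(as.numeric(signal))
  h <- (window - 1) / 2
  cs <- cumsum(c(0, signal))
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- min(h, i - 1, n - i)
    out[i] <- (cs[i + hi + 1] - cs[i - hi]) / (2 * hi + 1)
  }
  out
}

.new_fix <- function(trace, t_boundary, method, quality, valid = TRUE) {
  x_b <- trace$x_start + trace$scan_speed * t_boundary
  structure(list(t_boundary = t_boundary, x_boundary = x_b,
                 clock = trace$scan_start_clock + t_boundary / 60,
                 method = method, quality = quality, valid = valid),
            class = "boundary_fix")
}

#' @export
print.boundary_fix <- function(x, ...) {
  cat(sprintf("<boundary_fix> %s: t = %.3f s, x = %.3f mm, clock = %.3f min, quality %.3g%s\n",
              x$method, x$t_boundary, x$x_boundary, x$clock, x$quality,
              if (x$valid) "" else " (low quality)"))
  invisible(x)
}

#' Gradient-based boundary localization
#'
#' Implements the derivative rule of the data-processing algorithm: compute
#' the forward-difference time derivative of the (baseline-subtracted,
#' filtered) signal, find its global maximum (earliest index on ties), take
#' the maximal contiguous run of indices with derivative `>= -eps` containing
#' that maximum, and report the first sample of that run as the boundary
#' detection time. For the characteristic trough signature this is the sample
#' where the signal stops falling and starts rising, i.e. the trough bottom.
#' The detected time maps to the channel position
#' `x_boundary = x_start + scan_speed * t_boundary`.
#'
#' @param trace A baseline-subtracted, filtered [scan_trace()] with at least
#'   3 samples.
#' @param eps Non-negativity tolerance for the derivative run (default 0;
#'   raise for noisy data).
#' @param quality_min Quality floor: fixes whose maximum derivative does not
#'   exceed it are flagged `valid = FALSE` (default 0).
#' @return A `boundary_fix`: list with `t_boundary` (s), `x_boundary` (mm),
#'   `clock` (min), `method`, `quality` (peak derivative, units s^-1) and
#'   `valid`.
#' @export
locate_boundary_gradient <- function(trace, eps = 0, quality_min = 0) {
  stopifnot(inherits(trace, "scan_trace"))
  if (length(trace$t) < 3L) .stop_domain("need at least 3 samples")
  dt <- trace$t[2] - trace$t[1]
  d <- diff(trace$signal) / dt
  if (all(d == 0)) .stop_noboundary("flat trace: derivative identically zero")
  imax <- which.max(d)
  j <- imax
  while (j > 1 && d[j - 1] >= -eps) j <- j - 1
  .new_fix(trace, trace$t[j], "gradient_start", d[imax],
           valid = d[imax] > quality_min)
}

#' Trough-based boundary localization
#'
#' Boundary fix at the global minimum of the filtered signal (earliest sample
#' on ties). Quality is the trough depth, measured from the trace maximum.
#'
#' @inheritParams locate_boundary_gradient
#' @param quality_min Quality floor on the trough depth (default 0).
#' @return A `boundary_fix` (see [locate_boundary_gradient()]).
#' @export
locate_boundary_trough <- function(trace, quality_min = 0) {
  stopifnot(inherits(trace, "scan_trace"))
  if (length(trace$t) < 3L) .stop_domain("need at least 3 samples")
  s <- trace$signal
  if (max(s) == min(s)) .stop_noboundary("flat trace: no trough")
  j <- which.min(s)
  depth <- max(s) - s[j]
  .new_fix(trace, trace$t[j], "trough", depth, valid = depth > quality_min)
}

#' Trough localization with the pickup-cleared position convention
#'
#' Variant of [locate_boundary_trough()] for instruments whose signal peaks
#' when the pick-up electrode has completely cleared the boundary: the
#' reported position is the window-center position at the trough minus a fixed
#' geometric offset (half the gap plus the pickup width for a physical
#' electrode pair; 0 for a point response).
#'
#' @inheritParams locate_boundary_trough
#' @param offset Geometric offset subtracted from the window-center position,
#'   mm.
#' @return A `boundary_fix` with `method = "t2"`.
#' @export
locate_boundary_t2 <- function(trace, offset = 0, quality_min = 0) {
  fix <- locate_boundary_trough(trace, quality_min = quality_min)
  fix$x_boundary <- fix$x_boundary - offset
  fix$method <- "t2"
  fix
}

# adaptive validity floors from the trace's own noise scale; the raw per-sample
# noise is estimated robustly from first differences of the filtered signal
.auto_quality_min <- function(s, dt, method) {
  nd <- stats::mad(diff(s))
  if (!is.finite(nd)) nd <- 0
  switch(method,
         gradient = 5 * nd / dt,     # vs expected max noise derivative ~3.5 sd
         trough = ,
         t2 = 25 * nd / sqrt(2))     # vs expected noise range of the trace
}

#' Boundary fixes from a timed scan series
#'
#' Runs the full per-scan pipeline -- baseline subtraction, moving-average
#' filtering, boundary localization -- over an ordered series of scans, flags
#' invalid fixes (flat traces, quality below threshold), and retains at most
#' the first `max_fixes` valid fixes (default 4, the "first four valid signal
#' peaks" rule). Fewer than `min_fixes` (default 3) valid fixes is an error.
#'
#' @param traces List of [scan_trace()] ordered by `scan_start_clock`.
#' @param baseline Background [scan_trace()].
#' @param method Localization method: `"gradient"` (default), `"trough"` or
#'   `"t2"`.
#' @param smooth_window Moving-average width (odd, default 5).
#' @param eps Derivative tolerance for the gradient method.
#' @param quality_min Validity floor on the fix quality. `NULL` (default)
#'   derives a per-trace floor from the trace's own noise level, so that
#'   noise-only (boundary-free) scans are flagged invalid; `0` accepts any
#'   fix with positive quality.
#' @param t2_offset Geometric offset for the `"t2"` convention, mm.
#' @param max_fixes Keep at most this many valid fixes (default 4).
#' @param min_fixes Minimum number of valid fixes required (default 3).
#' @return A `data.frame` of class `"boundary_fixes"` with columns
#'   `clock_min`, `t_boundary_s`, `x_boundary_mm`, `method`, `quality`,
#'   `valid`, restricted to the retained valid fixes; all per-scan results
#'   (including invalid ones) are attached as attribute `"all_fixes"`.
#' @export
fixes_from_scan_series <- function(traces, baseline,
                                   method = c("gradient", "trough", "t2"),
                                   smooth_window = 5L, eps = 0,
                                   quality_min = NULL, t2_offset = 0,
                                   max_fixes = 4L, min_fixes = 3L) {
  method <- match.arg(method)
  stopifnot(is.list(traces), inherits(baseline, "scan_trace"))
  clocks <- vapply(traces, `[[`, 0, "scan_start_clock")
  if (is.unsorted(clocks, strictly = FALSE))
    .stop_config("traces must be ordered by scan_start_clock")
  rows <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- subtract_baseline(traces[[i]], baseline)
    tr$signal <- moving_average(tr$signal, smooth_window)
    dt <- tr$t[2] - tr$t[1]
    qmin <- if (is.null(quality_min))
      .auto_quality_min(tr$signal, dt, method) else quality_min
    fix <- tryCatch(
      switch(method,
             gradient = locate_boundary_gradient(tr, eps = eps, quality_min = qmin),
             trough = locate_boundary_trough(tr, quality_min = qmin),
             t2 = locate_boundary_t2(tr, offset = t2_offset, quality_min = qmin)),
      mrbscan_no_boundary = function(e) NULL)
    rows[[i]] <- if (is.null(fix)) {
      data.frame(clock_min = clocks[i], t_boundary_s = NA_real_,
                 x_boundary_mm = NA_real_, method = method, quality = 0,
                 valid = FALSE)
    } else {
      data.frame(clock_min = fix$clock, t_boundary_s = fix$t_boundary,
                 x_boundary_mm = fix$x_boundary, method = method,
                 quality = fix$quality, valid = fix$valid)
    }
  }
  all <- do.call(rbind, rows)
  ok <- which(all$valid)
  if (length(ok) < min_fixes)
    .stop_nodata(sprintf("only %d valid fixes; need at least %d",
                         length(ok), min_fixes))
  keep <- ok[seq_len(min(max_fixes, length(ok)))]
  out <- all[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("boundary_fixes", "data.frame")
  attr(out, "all_fixes") <- all
  out
}
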