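#' Scan trace container
#'
#' Detector output versus time for one unidirectional scan, together with the
#' scan kinematics needed to map sample times to channel positions:
#' the detector (window center) position at sample time `t` seconds after the
#' scan started is `x(t) = x_start + scan_speed * t`.
#'
#' @param t Sample times since scan start, s (uniform, increasing).
#' @param signal Detector output, arbitrary units (conductivity scale for
#'   simulated traces).
#' @param scan_speed Scan speed, mm s^-1 (> 0).
#' @param scan_start_clock Electrophoresis clock at scan start, min.
#' @param x_start Window-center position at `t = 0`, mm.
#' @param sample_rate Sampling rate, Hz.
#' @return An object of class `"scan_trace"`.
#' @export
scan_trace <- function(t, signal, scan_speed, scan_start_clock = NA_real_,
                       x_start = 0, sample_rate = NULL) {
  if (length(t) < 2L || length(t) != length(signal))
    .stop_domain("t and signal must have equal length >= 2")
  dt <- diff(t)
  if (any(dt <= 0)) .stop_domain("t must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9 * max(dt)) .stop_domain("t must be uniformly sampled")
  if (!is.finite(scan_speed) || scan_speed <= 0) .stop_domain("scan_speed must be > 0")
  if (is.null(sample_rate)) sample_rate <- 1 / dt[1]
  structure(list(t = as.numeric(t), signal = as.numeric(signal),
                 scan_speed = scan_speed, scan_start_clock = scan_start_clock,
                 x_start = x_start, sample_rate = sample_rate),
            class = "scan_trace")
}

#' @export
print.scan_trace <- function(x, ...) {
  cat(sprintf("<scan_trace> %d samples @ %.3g Hz, %.3g mm/s from x = %.3g mm, clock %.3g min\n",
              length(x$t), x$sample_rate, x$scan_speed, x$x_start,
              x$scan_start_clock))
  invisible(x)
}

#' @export
plot.scan_trace <- function(x, xaxis = c("position", "time"), ...) {
  xaxis <- match.arg(xaxis)
  if (xaxis == "position") {
    graphics::plot(x$x_start + x$scan_speed * x$t, x$signal, type = "l",
                   xlab = "detector position (mm)", ylab = "signal", ...)
  } else {
    graphics::plot(x$t, x$signal, type = "l", xlab = "t (s)", ylab = "signal", ...)
  }
  invisible(x)
}

# detector position axis of a trace
scan_positions <- function(trace) trace$x_start + trace$scan_speed * trace$t

#' Sliding-window detector response of a scan
#'
#' Converts a spatial conductivity profile into the time-domain trace a
#' scanning detector records. The boundary is treated as stationary during one
#' scan (the scan speed far exceeds the boundary velocity), so at sample time
#' `t` the window center sits at `x(t) = x_start + scan_speed * t` and the
#' output is the discrete sliding-window transform
#' `signal(t) = sum_k f_k * sigma(x(t) + offset_k)`,
#' with `f` the discretized window weights and profile values interpolated
#' linearly between grid points. With the delta window the trace is simply the
#' profile resampled along the scan path.
#'
#' @param profile A [spatial_profile()].
#' @param window An [electrode_window()].
#' @param scan_speed Scan speed, mm s^-1 (default 1.0).
#' @param x_start Window-center position at scan start, mm; defaults to the
#'   smallest position where the window fits fully on the profile grid.
#' @param x_end Window-center position at scan end, mm; defaults to the
#'   largest position where the window fits.
#' @param sample_rate Sampling rate, Hz (default 40).
#' @param scan_start_clock Electrophoresis clock at scan start, min; defaults
#'   to the profile time.
#' @return A [scan_trace()].
#' @export
scan_response <- function(profile, window, scan_speed = 1.0, x_start = NULL,
                          x_end = NULL, sample_rate = 40,
                          scan_start_clock = NULL) {
  stopifnot(inherits(profile, "spatial_profile"),
            inherits(window, "electrode_window"))
  if (scan_speed <= 0) .stop_domain("scan_speed must be > 0")
  if (sample_rate <= 0) .stop_domain("sample_rate must be > 0")
  half <- window$support / 2
  lo <- min(profile$x); hi <- max(profile$x)
  if (window$support >= hi - lo)
    .stop_config("window support exceeds the profile extent (window wider than channel)")
  if (is.null(x_start)) x_start <- lo + half
  if (is.null(x_end)) x_end <- hi - half
  if (x_start < lo + half - 1e-9 || x_end > hi + 1e-9 - half || x_end <= x_start)
    .stop_config("scan path leaves the channel for part of the window support")
  if (is.null(scan_start_clock)) scan_start_clock <- profile$time
  tt <- seq(0, (x_end - x_start) / scan_speed, by = 1 / sample_rate)
  centers <- x_start + scan_speed * tt
  # positions matrix: one row per tap, one column per sample
  sig <- numeric(length(centers))
  for (k in seq_along(window$offsets)) {
    sig <- sig + window$weights[k] *
      stats::approx(profile$x, profile$sigma, xout = centers + window$offsets[k],
                    rule = 2)$y
  }
  scan_trace(tt, sig, scan_speed = scan_speed,
             scan_start_clock = scan_start_clock, x_start = x_start,
             sample_rate = sample_rate)
}
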