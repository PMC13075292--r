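#' Separation channel geometry
#'
#' Geometry of one straight separation channel. The spatial origin `x = 0` is
#' the anode-side channel entrance; `x` increases toward the cathode, the
#' direction the boundary normally migrates.
#'
#' @param length Channel length, mm (default 24).
#' @param width Channel width, um (default 200).
#' @param depth Channel depth, um (default 100).
#' @return An object of class `"channel_geometry"`.
#' @examples
#' channel_geometry()
#' @export
channel_geometry <- function(length = 24, width = 200, depth = 100) {
  if (!is.finite(length) || length <= 0) .stop_domain("channel length must be > 0")
  if (!is.finite(width) || width <= 0) .stop_domain("channel width must be > 0")
  if (!is.finite(depth) || depth <= 0) .stop_domain("channel depth must be > 0")
  structure(list(length = length, width = width, depth = depth, x_origin = 0),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> %g mm x %g um x %g um (x = 0 at anode-side entrance)\n",
              x$length, x$width, x$depth))
  invisible(x)
}

#' Detector window function
#'
#' Discretized spatial sensitivity (sliding-window function) of the scanning
#' conductivity detector, defined over offsets from the window center.
#'
#' Three shapes are available:
#' \describe{
#'   \item{`"delta"`}{Point response: a single unit weight at offset 0. The
#'     scan then resamples the conductivity profile along the scan path. This
#'     is the generator default: the repeatability of boundary fixes achieved
#'     by real scanning C4D instruments implies an effective axial response
#'     much narrower than the electrode footprint (sensitivity concentrates in
#'     the inter-electrode gap), and a point response models that limit.}
#'   \item{`"unipolar_trapezoid"`}{Non-negative trapezoid spanning the
#'     actuator--gap--pickup footprint: linear rise across the actuator,
#'     plateau across the gap, linear fall across the pickup; weights
#'     normalized to sum to 1 so a constant profile maps to itself.}
#'   \item{`"bipolar_differential"`}{Antisymmetric variant for pick-up
#'     electrodes wired differentially: positive actuator lobe, negative
#'     pickup lobe, zero net sum; the positive lobe is normalized to 1.}
#' }
#'
#' @param shape One of `"delta"`, `"unipolar_trapezoid"`,
#'   `"bipolar_differential"`.
#' @param actuator_width,pickup_width Electrode widths, mm (default 2.5).
#' @param gap Gap between the electrodes, mm (default 1.5).
#' @param dx Discretization step for the weights, mm.
#' @return An object of class `"electrode_window"` with fields `offsets` (mm),
#'   `weights`, `support` (total extent, mm) and `shape`.
#' @examples
#' w <- electrode_window("unipolar_trapezoid")
#' sum(w$weights)  # 1
#' @export
electrode_window <- function(shape = c("delta", "unipolar_trapezoid",
                                       "bipolar_differential"),
                             actuator_width = 2.5, pickup_width = 2.5,
                             gap = 1.5, dx = 0.01) {
  shape <- match.arg(shape)
  if (shape == "delta") {
    return(structure(list(offsets = 0, weights = 1, support = 0, shape = shape),
                     class = "electrode_window"))
  }
  if (actuator_width <= 0 || pickup_width <= 0 || gap <= 0)
    .stop_domain("electrode widths and gap must be > 0")
  if (dx <= 0) .stop_domain("dx must be > 0")
  support <- actuator_width + gap + pickup_width
  offsets <- seq(-support / 2, support / 2, by = dx)
  u <- offsets + support / 2
  w <- ifelse(u < actuator_width, u / actuator_width,
              ifelse(u <= actuator_width + gap, 1,
                     pmax(0, (support - u) / pickup_width)))
  if (shape == "unipolar_trapezoid") {
    w <- w / sum(w)
  } else {
    sgn <- ifelse(offsets < 0, 1, ifelse(offsets > 0, -1, 0))
    w <- w * sgn
    pos <- sum(w[w > 0])
    w <- w / pos
  }
  structure(list(offsets = offsets, weights = w, support = support,
                 shape = shape, actuator_width = actuator_width,
                 pickup_width = pickup_width, gap = gap),
            class = "electrode_window")
}

#' @export
print.electrode_window <- function(x, ...) {
  cat(sprintf("<electrode_window> %s, support %.2f mm, %d taps\n",
              x$shape, x$support, length(x$offsets)))
  invisible(x)
}
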