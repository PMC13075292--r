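#' Synthetic experiment configuration
#'
#' Describes one complete synthetic scanning experiment: the concentrations to
#' titrate, the velocity law mapping concentration to boundary velocity, the
#' scan schedule, the instrument model and the noise model. The default
#' schedule is the standard protocol: first scan 7 min after the run starts,
#' one scan every 2 min, four scans in total, 1.0 mm s^-1 scan speed.
#'
#' The velocity law is `U = a * log10(C) + b` (mm min^-1, C in mM) with
#' defaults `a = 0.272`, `b = -0.011`. `U` is negative below the
#' zero-crossing concentration (the boundary retreats at low analyte); the
#' boundary forms at `x_origin` so all positions stay inside the channel.
#'
#' The generator refuses configurations whose implied boundary speed reaches
#' the scan speed: the detector could then never overtake the boundary and no
#' signal peak would be recorded (the catch-up constraint).
#'
#' @param concentrations Analyte concentrations, mM (> 0).
#' @param velocity_law Named vector `c(a = , b = )`, mm min^-1 per decade and
#'   mm min^-1.
#' @param first_scan_clock Clock of the first scan, min (default 7).
#' @param scan_interval Time between scan starts, min (default 2).
#' @param n_scans Number of scans (default 4, minimum 3).
#' @param scan_speed Scan speed, mm s^-1 (default 1.0).
#' @param sample_rate Detector sampling rate, Hz (default 40).
#' @param channel [channel_geometry()].
#' @param window [electrode_window()]; the default point response models the
#'   sub-millimeter effective axial resolution of the scanning detector.
#' @param x_origin Boundary formation position, mm (default 6).
#' @param sigma1,sigma2 Zone conductivities, S m^-1.
#' @param D Effective front diffusion coefficient, m^2 s^-1.
#' @param depletion_amp,depletion_width Depth (S m^-1) and Gaussian width (mm)
#'   of the leading-edge depletion trough, the feature the localizers track.
#' @param noise_sd Additive white noise SD, signal units (default 0.01, i.e.
#'   2 percent of the default 0.5 S m^-1 zone step).
#' @param drift_coeffs Polynomial coefficients of a slow baseline drift in
#'   normalized scan time (constant, linear, quadratic, ...), signal units;
#'   empty disables drift.
#' @param spike_prob Per-sample probability of an impulsive spike (default 0).
#' @param spike_amp Spike amplitude, signal units.
#' @param grid_dx Spatial grid step for profile rendering, mm.
#' @param seed Integer seed; mandatory, every generated dataset is fully
#'   reproducible from it.
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(concentrations = c(0.2, 0.5, 1, 3.5, 10, 30, 50),
                              velocity_law = c(a = 0.272, b = -0.011),
                              first_scan_clock = 7, scan_interval = 2,
                              n_scans = 4, scan_speed = 1.0, sample_rate = 40,
                              channel = channel_geometry(),
                              window = electrode_window("delta"),
                              x_origin = 6, sigma1 = 0.5, sigma2 = 1.0,
                              D = 5e-10, depletion_amp = 0.65,
                              depletion_width = 0.2, noise_sd = 0.01,
                              drift_coeffs = numeric(0), spike_prob = 0,
                              spike_amp = 0.2, grid_dx = 0.01, seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    .stop_config("a numeric seed is mandatory for reproducibility")
  if (any(concentrations <= 0)) .stop_domain("concentrations must be > 0")
  if (!all(c("a", "b") %in% names(velocity_law)))
    .stop_config("velocity_law must have named components a and b")
  if (n_scans < 3) .stop_config("n_scans must be >= 3")
  if (scan_speed <= 0 || sample_rate <= 0 || scan_interval <= 0 ||
      first_scan_clock <= 0)
    .stop_domain("schedule parameters must be > 0")
  stopifnot(inherits(channel, "channel_geometry"),
            inherits(window, "electrode_window"))
  U <- velocity_law[["a"]] * log10(concentrations) + velocity_law[["b"]]
  if (max(abs(U)) / 60 >= scan_speed)
    .stop_config(sprintf(
      "catch-up constraint violated: max |U| = %.3g mm/s >= scan speed %.3g mm/s; the detector would never overtake the boundary",
      max(abs(U)) / 60, scan_speed))
  clocks <- first_scan_clock + scan_interval * (seq_len(n_scans) - 1)
  xb <- x_origin + outer(U, clocks)
  margin <- window$support / 2 + 0.5
  if (any(xb < margin) || any(xb > channel$length - margin))
    .stop_config("boundary leaves the scannable region for some concentration; adjust x_origin or the schedule")
  structure(list(concentrations = concentrations, velocity_law = velocity_law,
                 first_scan_clock = first_scan_clock,
                 scan_interval = scan_interval, n_scans = n_scans,
                 scan_speed = scan_speed, sample_rate = sample_rate,
                 channel = channel, window = window, x_origin = x_origin,
                 sigma1 = sigma1, sigma2 = sigma2, D = D,
                 depletion_amp = depletion_amp,
                 depletion_width = depletion_width, noise_sd = noise_sd,
                 drift_coeffs = drift_coeffs, spike_prob = spike_prob,
                 spike_amp = spike_amp, grid_dx = grid_dx,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %d concentration(s), %d scans at %g + %g*k min, %.3g mm/s, seed %d\n",
              length(x$concentrations), x$n_scans, x$first_scan_clock,
              x$scan_interval, x$scan_speed, x$seed))
  invisible(x)
}

# scan clocks of a config
.config_clocks <- function(config)
  config$first_scan_clock + config$scan_interval * (seq_len(config$n_scans) - 1)

# additive noise for one trace; drawn in a fixed order for reproducibility
.trace_noise <- function(config, n) {
  e <- stats::rnorm(n, 0, config$noise_sd)
  if (length(config$drift_coeffs)) {
    u <- seq(0, 1, length.out = n)
    scale <- stats::runif(1, 0.5, 1.5)  # drift amplitude wanders between scans
    for (j in seq_along(config$drift_coeffs))
      e <- e + scale * config$drift_coeffs[j] * u^(j - 1)
  }
  if (config$spike_prob > 0) {
    hits <- stats::rbinom(n, 1, config$spike_prob)
    e <- e + hits * config$spike_amp * sign(stats::rnorm(n))
  }
  e
}

.background_profile <- function(config) {
  grid <- seq(0, config$channel$length, by = config$grid_dx)
  spatial_profile(grid, rep(config$sigma2, length(grid)), time = 0)
}

.scan_of_profile <- function(config, profile, clock) {
  scan_response(profile, config$window, scan_speed = config$scan_speed,
                sample_rate = config$sample_rate, scan_start_clock = clock)
}

#' Generate a complete synthetic scanning experiment
#'
#' For each configured concentration, derives the boundary velocity from the
#' velocity law, renders the error-function conductivity profile (with its
#' depletion trough) at each scheduled scan clock, converts it to a detector
#' trace through the configured window, and adds seeded noise and drift. A
#' boundary-free background scan with independent noise is generated first,
#' as in the real protocol. All randomness derives from `config$seed`; the
#' same configuration reproduces bit-identical data.
#'
#' @param config An [experiment_config()].
#' @return A list with
#'   \describe{
#'     \item{`baseline`}{the background [scan_trace()],}
#'     \item{`experiments`}{one entry per concentration: `conc_mM`, `U_true`
#'       (mm min^-1), `traces` (list of [scan_trace()]), and `truth` (data
#'       frame of true boundary positions at each scan clock),}
#'     \item{`truth`}{all ground truth rows combined
#'       (`conc_mM`, `clock_min`, `true_x_mm`, `true_U`),}
#'     \item{`config`}{the generating configuration, echoed.}
#'   }
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  clocks <- .config_clocks(config)
  bg <- .background_profile(config)
  baseline <- .scan_of_profile(config, bg, clock = 0)
  baseline$signal <- baseline$signal + .trace_noise(config, length(baseline$t))
  grid <- bg$x
  a <- config$velocity_law[["a"]]; b <- config$velocity_law[["b"]]
  experiments <- vector("list", length(config$concentrations))
  for (i in seq_along(config$concentrations)) {
    C <- config$concentrations[i]
    U <- a * log10(C) + b
    state <- boundary_state(sigma1 = config$sigma1, sigma2 = config$sigma2,
                            U = U, D = config$D,
                            depletion_amp = config$depletion_amp,
                            depletion_width = config$depletion_width)
    traces <- vector("list", config$n_scans)
    for (k in seq_len(config$n_scans)) {
      prof <- erf_conductivity_profile(grid, clocks[k], state,
                                       x_origin = config$x_origin)
      tr <- .scan_of_profile(config, prof, clock = clocks[k])
      tr$signal <- tr$signal + .trace_noise(config, length(tr$t))
      traces[[k]] <- tr
    }
    experiments[[i]] <- list(conc_mM = C, U_true = U, traces = traces,
                             truth = data.frame(conc_mM = C, clock_min = clocks,
                                                true_x_mm = config$x_origin + U * clocks,
                                                true_U = U))
  }
  truth <- do.call(rbind, lapply(experiments, `[[`, "truth"))
  rownames(truth) <- NULL
  list(baseline = baseline, experiments = experiments, truth = truth,
       config = config)
}

#' Generate boundary-free negative-control scans
#'
#' Scans of a channel with no moving boundary: background conductivity plus
#' the configured noise and drift only. The downstream pipeline should flag
#' every such scan invalid (no valid boundary), so a series of them raises an
#' insufficient-data error.
#'
#' @param config An [experiment_config()].
#' @return A list with `baseline` (noiseless-free background scan with its own
#'   noise draw) and `traces` (one noise-only [scan_trace()] per scheduled
#'   scan).
#' @export
generate_negative_control <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  clocks <- .config_clocks(config)
  bg <- .background_profile(config)
  baseline <- .scan_of_profile(config, bg, clock = 0)
  baseline$signal <- baseline$signal + .trace_noise(config, length(baseline$t))
  traces <- lapply(clocks, function(cl) {
    tr <- .scan_of_profile(config, bg, clock = cl)
    tr$signal <- tr$signal + .trace_noise(config, length(tr$t))
    tr
  })
  list(baseline = baseline, traces = traces, config = config)
}
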