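# shared fixtures, all generated in code

# two-ion test electrolyte
kcl_species <- function() list(
  ion_species("K+", +1, 7.62e-8, 1.957e-9),
  ion_species("Cl-", -1, 7.91e-8, 2.032e-9))

# small, fast synthetic configuration; noiseless unless asked otherwise
quick_config <- function(concentrations = 10, noise_sd = 0, seed = 1, ...)
  experiment_config(concentrations = concentrations, noise_sd = noise_sd,
                    seed = seed, ...)

# single-velocity configuration: velocity law collapses to constant U
const_u_config <- function(U, ...)
  quick_config(concentrations = 1, velocity_law = c(a = 0, b = U), ...)

# brute-force sliding-window transform: double loop with manual linear
# interpolation; independent of scan_response()
oracle_window_transform <- function(px, psig, window, centers) {
  interp1 <- function(x0) {
    if (x0 <= px[1]) return(psig[1])
    if (x0 >= px[length(px)]) return(psig[length(px)])
    i <- findInterval(x0, px)
    w <- (x0 - px[i]) / (px[i + 1] - px[i])
    (1 - w) * psig[i] + w * psig[i + 1]
  }
  out <- numeric(length(centers))
  for (i in seq_along(centers)) {
    acc <- 0
    for (k in seq_along(window$offsets))
      acc <- acc + window$weights[k] * interp1(centers[i] + window$offsets[k])
    out[i] <- acc
  }
  out
}

# exhaustive enumeration of maximal runs with d >= 0; returns the first index
# of the run containing the (earliest) global maximum of d
oracle_run_start <- function(d) {
  nonneg <- d >= 0
  runs <- rle(nonneg)
  ends <- cumsum(runs$lengths)
  starts <- c(1, head(ends, -1) + 1)
  imax <- which.max(d)
  k <- which(starts <= imax & ends >= imax & runs$values)
  starts[k]
}
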