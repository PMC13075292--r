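#' 1-D Nernst--Planck electromigration simulator
#'
#' Explicit finite-difference simulation of electromigration (advection signed
#' by charge), diffusion and, optionally, the fast neutralization reaction
#' between the colored cation (`CV+`) and hydroxide (`OH-`) in a straight
#' channel. Each species is advected with velocity
#' `v_i = charge_sign_i * mobility_i * field` (upwind differencing) and
#' diffuses with its own coefficient (central differencing). With the reaction
#' enabled, each step removes equal amounts of `CV+` and `OH-` per cell:
#' instantaneous annihilation of the limiting species by default
#' (`rate_k = Inf`), or the bimolecular rate `k * [CV+] * [OH-] * dt`, capped
#' at the limiting species, for finite `rate_k`. A step-like conductivity
#' transition forms where the two fronts meet.
#'
#' Boundary conditions: `"fixed"` holds the reservoir concentrations
#' (`init_conc_left`/`init_conc_right`) at the channel ends; `"closed"`
#' imposes zero flux at both ends, the configuration used for mass-conservation
#' checks.
#'
#' Stability: the explicit scheme requires `max(|v|) * dt / dx <= 1`
#' (advection Courant number) and `max(D) * dt / dx^2 <= 0.5` (diffusion
#' number); violating either raises a configuration error naming the bound.
#'
#' @param species List of [ion_species()]; initial condition is
#'   `init_conc_left` on the left half of the channel and `init_conc_right` on
#'   the right half, with reservoirs at the ends.
#' @param field Axial electric field, V m^-1 (positive drives cations toward
#'   the cathode, i.e. +x).
#' @param grid Uniform spatial grid, mm.
#' @param dt Time step, s.
#' @param t_end Total simulated time, min.
#' @param reaction Logical; enable the `CV+` + `OH-` annihilation reaction.
#' @param rate_k Bimolecular rate constant, m^3 mol^-1 s^-1; `Inf` (default)
#'   means instantaneous annihilation of the limiting species per cell.
#' @param boundary `"fixed"` reservoirs or `"closed"` (no-flux) ends.
#' @param out_times Electrophoresis times (min) at which to record
#'   conductivity profiles; defaults to `t_end`.
#' @return A list with `profiles` (list of [spatial_profile()] at
#'   `out_times`), `conc` (final concentration matrix, cells x species),
#'   `grid`, `species_names`, and `consumed` (named vector of cumulative moles
#'   removed by the reaction per unit area, for `CV+` and `OH-`).
#' @export
simulate_electromigration <- function(species, field, grid, dt, t_end,
                                      reaction = FALSE, rate_k = Inf,
                                      boundary = c("fixed", "closed"),
                                      out_times = NULL) {
  boundary <- match.arg(boundary)
  if (length(species) == 0L) .stop_config("species list is empty")
  if (!all(vapply(species, inherits, TRUE, "ion_species")))
    .stop_config("'species' must be a list of ion_species objects")
  if (length(grid) < 5L) .stop_config("grid must have at least 5 points")
  dxs <- diff(grid)
  if (any(dxs <= 0) || max(dxs) - min(dxs) > 1e-9 * max(dxs))
    .stop_config("grid must be uniform and increasing")
  if (dt <= 0 || t_end <= 0) .stop_config("dt and t_end must be > 0")
  dx_m <- dxs[1] / 1000
  nm <- vapply(species, `[[`, "", "name")
  mu <- vapply(species, `[[`, 0, "mobility")
  zs <- vapply(species, `[[`, 0, "charge_sign")
  DD <- vapply(species, `[[`, 0, "diffusion_coeff")
  vel <- zs * mu * field                      # m/s, signed
  co_adv <- max(abs(vel)) * dt / dx_m
  co_dif <- max(DD) * dt / dx_m^2
  if (co_adv > 1)
    .stop_config(sprintf(
      "unstable step: advection Courant number max(|v|)*dt/dx = %.3g > 1", co_adv))
  if (co_dif > 0.5)
    .stop_config(sprintf(
      "unstable step: diffusion number max(D)*dt/dx^2 = %.3g > 0.5", co_dif))
  if (is.null(out_times)) out_times <- t_end
  out_times <- sort(unique(out_times))
  if (any(out_times <= 0) || max(out_times) > t_end + 1e-9)
    .stop_config("out_times must lie in (0, t_end]")

  n <- length(grid)
  nsp <- length(species)
  left_half <- grid <= (grid[1] + grid[n]) / 2
  conc <- matrix(0, n, nsp, dimnames = list(NULL, nm))
  for (j in seq_len(nsp))
    conc[, j] <- ifelse(left_half, species[[j]]$init_conc_left,
                        species[[j]]$init_conc_right)

  icv <- match("CV+", nm)
  ioh <- match("OH-", nm)
  if (reaction && (is.na(icv) || is.na(ioh)))
    .stop_config("reaction = TRUE requires species named 'CV+' and 'OH-'")
  consumed <- c("CV+" = 0, "OH-" = 0)

  nsteps <- ceiling(t_end * 60 / dt)
  out_steps <- pmin(pmax(round(out_times * 60 / dt), 1L), nsteps)
  profiles <- vector("list", length(out_times))
  idx <- 2:(n - 1)

  sigma_of <- function(cm) .FARADAY * as.numeric(cm %*% mu)

  for (step in seq_len(nsteps)) {
    newc <- conc
    for (j in seq_len(nsp)) {
      c_j <- conc[, j]
      # upwind advection
      adv <- numeric(n)
      if (vel[j] > 0) {
        adv[idx] <- -vel[j] * (c_j[idx] - c_j[idx - 1]) / dx_m
      } else if (vel[j] < 0) {
        adv[idx] <- -vel[j] * (c_j[idx + 1] - c_j[idx]) / dx_m
      }
      dif <- numeric(n)
      dif[idx] <- DD[j] * (c_j[idx + 1] - 2 * c_j[idx] + c_j[idx - 1]) / dx_m^2
      c_new <- c_j + dt * (adv + dif)
      if (boundary == "fixed") {
        c_new[1] <- species[[j]]$init_conc_left
        c_new[n] <- species[[j]]$init_conc_right
      } else {
        # zero-flux: mirror ghost cells (diffusion), no advective inflow
        c_new[1] <- c_j[1] + dt * (DD[j] * (c_j[2] - c_j[1]) / dx_m^2 -
                                     max(vel[j], 0) * 0 -
                                     min(vel[j], 0) * (c_j[2] - c_j[1]) / dx_m)
        c_new[n] <- c_j[n] + dt * (DD[j] * (c_j[n - 1] - c_j[n]) / dx_m^2 -
                                     max(vel[j], 0) * (c_j[n] - c_j[n - 1]) / dx_m)
        if (vel[j] > 0) c_new[1] <- c_j[1] + dt * DD[j] * (c_j[2] - c_j[1]) / dx_m^2
        if (vel[j] < 0) c_new[n] <- c_j[n] + dt * DD[j] * (c_j[n - 1] - c_j[n]) / dx_m^2
      }
      newc[, j] <- pmax(c_new, 0)
    }
    if (reaction) {
      if (is.finite(rate_k)) {
        r <- pmin(rate_k * newc[, icv] * newc[, ioh] * dt,
                  pmin(newc[, icv], newc[, ioh]))
      } else {
        r <- pmin(newc[, icv], newc[, ioh])
      }
      newc[, icv] <- newc[, icv] - r
      newc[, ioh] <- newc[, ioh] - r
      consumed["CV+"] <- consumed["CV+"] + sum(r) * dx_m
      consumed["OH-"] <- consumed["OH-"] + sum(r) * dx_m
    }
    conc <- newc
    hit <- which(out_steps == step)
    for (h in hit)
      profiles[[h]] <- spatial_profile(grid, pmax(sigma_of(conc), 1e-12),
                                       time = step * dt / 60)
  }
  list(profiles = profiles, conc = conc, grid = grid, species_names = nm,
       consumed = consumed)
}

#' Boundary midpoint of a conductivity profile
#'
#' Position where the profile crosses the mid-conductivity level
#' `(sigma1 + sigma2)/2`, located by linear interpolation between the
#' bracketing grid points. Used to track how the simulated boundary advances.
#'
#' @param profile A [spatial_profile()].
#' @param sigma1,sigma2 Plateau conductivities defining the mid level.
#' @return Crossing position, mm (`NA` if the level is never crossed).
#' @export
profile_midpoint <- function(profile, sigma1, sigma2) {
  stopifnot(inherits(profile, "spatial_profile"))
  mid <- (sigma1 + sigma2) / 2
  s <- profile$sigma - mid
  cross <- which(s[-length(s)] * s[-1] <= 0 & (s[-length(s)] != 0 | s[-1] != 0))
  if (!length(cross)) return(NA_real_)
  i <- cross[1]
  x0 <- profile$x[i]; x1 <- profile$x[i + 1]
  y0 <- s[i]; y1 <- s[i + 1]
  if (y1 == y0) return((x0 + x1) / 2)
  x0 - y0 * (x1 - x0) / (y1 - y0)
}
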