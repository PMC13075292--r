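#' Ion species description
#'
#' Bundles the transport properties of one ionic species: sign of charge,
#' electrophoretic mobility and diffusion coefficient, plus the reservoir
#' concentrations used as initial/boundary conditions by
#' [simulate_electromigration()]. All species are treated as singly charged.
#'
#' @param name Species label, e.g. `"K+"`.
#' @param charge_sign `+1` for cations, `-1` for anions.
#' @param mobility Electrophoretic mobility, m^2 V^-1 s^-1 (non-negative).
#' @param diffusion_coeff Diffusion coefficient, m^2 s^-1 (positive).
#' @param init_conc_left,init_conc_right Reservoir concentrations at the
#'   anode-side (left) and cathode-side (right) channel ends, mol m^-3.
#' @return An object of class `"ion_species"`.
#' @examples
#' ion_species("K+", +1, 7.62e-8, 1.957e-9, init_conc_left = 1)
#' @export
ion_species <- function(name, charge_sign, mobility, diffusion_coeff,
                        init_conc_left = 0, init_conc_right = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    .stop_config("'name' must be a non-empty string")
  if (!charge_sign %in% c(-1, 1))
    .stop_config(sprintf("species '%s': charge_sign must be +1 or -1", name))
  if (!is.finite(mobility) || mobility < 0)
    .stop_domain(sprintf("species '%s': mobility must be >= 0", name))
  if (!is.finite(diffusion_coeff) || diffusion_coeff <= 0)
    .stop_domain(sprintf("species '%s': diffusion_coeff must be > 0", name))
  if (init_conc_left < 0 || init_conc_right < 0)
    .stop_domain(sprintf("species '%s': concentrations must be >= 0", name))
  structure(list(name = name, charge_sign = charge_sign, mobility = mobility,
                 diffusion_coeff = diffusion_coeff,
                 init_conc_left = init_conc_left,
                 init_conc_right = init_conc_right),
            class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> %s (z = %+d)\n  mobility %.3e m^2/V/s, D %.3e m^2/s, reservoirs L %.3g / R %.3g mol/m^3\n",
              x$name, x$charge_sign, x$mobility, x$diffusion_coeff,
              x$init_conc_left, x$init_conc_right))
  invisible(x)
}

#' Load an ion parameter table
#'
#' Reads a CSV with columns `name`, `charge_sign`, `mobility_m2_V_s`,
#' `diffusion_m2_s` and optional `init_conc_left`, `init_conc_right`, and
#' validates the schema. The table shipped with the package
#' (`system.file("extdata", "ion_defaults.csv", package = "mrbscan")`) holds
#' literature mobilities and diffusion coefficients for the ions of the
#' crystal-violet / hydroxide titration system; the crystal-violet values are
#' order-of-magnitude literature estimates for a bulky organic cation and are
#' meant to be overridden when better values are available.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return A list of [ion_species()] objects, named by species.
#' @export
load_ion_table <- function(path = system.file("extdata", "ion_defaults.csv",
                                              package = "mrbscan")) {
  if (!file.exists(path)) .stop_io(sprintf("ion table not found: %s", path))
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "charge_sign", "mobility_m2_V_s", "diffusion_m2_s")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    .stop_config(sprintf("ion table %s lacks column(s): %s", path,
                         paste(missing, collapse = ", ")))
  if (is.null(tab$init_conc_left)) tab$init_conc_left <- 0
  if (is.null(tab$init_conc_right)) tab$init_conc_right <- 0
  out <- lapply(seq_len(nrow(tab)), function(i)
    ion_species(tab$name[i], tab$charge_sign[i], tab$mobility_m2_V_s[i],
                tab$diffusion_m2_s[i], tab$init_conc_left[i], tab$init_conc_right[i]))
  names(out) <- tab$name
  out
}

#' Conductivity of an electrolyte from its composition
#'
#' Kohlrausch-type conductivity of a fully dissociated electrolyte of singly
#' charged ions: `sigma = F * sum(mu_i * c_i)` with `F` the Faraday constant,
#' summed over cations and anions alike.
#'
#' @param concs Named or positionally matched numeric vector of concentrations,
#'   mol m^-3, one per species (all `>= 0`).
#' @param species List of [ion_species()] objects (non-empty).
#' @return Conductivity in S m^-1.
#' @examples
#' sp <- list(ion_species("K+", 1, 7.62e-8, 1.957e-9),
#'            ion_species("Cl-", -1, 7.91e-8, 2.032e-9))
#' conductivity_from_species(c(1, 1), sp)
#' @export
conductivity_from_species <- function(concs, species) {
  if (length(species) == 0L) .stop_config("species list is empty")
  if (!all(vapply(species, inherits, TRUE, "ion_species")))
    .stop_config("'species' must be a list of ion_species objects")
  if (length(concs) != length(species))
    .stop_config("one concentration per species is required")
  if (!is.null(names(concs)) && any(nzchar(names(concs)))) {
    nm <- vapply(species, `[[`, "", "name")
    if (!setequal(names(concs), nm))
      .stop_config("names of 'concs' do not match the species list")
    concs <- concs[nm]
  }
  if (any(!is.finite(concs)) || any(concs < 0))
    .stop_domain("concentrations must be finite and >= 0")
  mu <- vapply(species, `[[`, 0, "mobility")
  .FARADAY * sum(mu * concs)
}
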