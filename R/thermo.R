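# Physical constants. All energies are kcal/mol, lengths A, concentrations
# mM at the user-facing surface and A^-3 internally; the converters below are
# the only crossing points between the two unit systems.

.kB <- 1.987204e-3 # Boltzmann constant, kcal/mol/K

# Standard state: C0 = 1 M, i.e. one molecule per 1660 A^3. The mM <-> A^-3
# conversion factor is derived from the same reference volume so that unit
# round-trips and standard free energies are exact identities.
.std_volume <- 1660 # A^3 per molecule at 1 M
.density_per_mM <- 1e-3 / .std_volume # A^-3 per mM (6.024e-7)

#' Thermodynamic context
#'
#' Bundles the temperature-dependent quantities shared by all downstream
#' calculations: the inverse temperature `beta = 1/(kB*T)` (mol/kcal) and the
#' standard-state reference density `C0 = 1 M = (1660 A^3)^-1`.
#'
#' The temperature default of 298.15 K reproduces the shipped reference
#' affinity table (see [kv12_affinity_table()]) to within the rounding of its
#' work values; it is a configurable choice, not a fitted parameter.
#'
#' @param temperature Absolute temperature in kelvin (single positive value).
#' @return An object of class `thermo_context`: a list with elements
#'   `temperature` (K), `kB` (kcal/mol/K), `beta` (mol/kcal),
#'   `standard_density` (A^-3) and `standard_concentration_mM` (1000).
#' @examples
#' ctx <- thermo_context()
#' ctx$beta # ~1.688 mol/kcal at 298.15 K
#' @export
thermo_context <- function(temperature = 298.15) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number (kelvin)",
         call. = FALSE)
  }
  structure(
    list(
      temperature = temperature,
      kB = .kB,
      beta = 1 / (.kB * temperature),
      standard_density = 1 / .std_volume,
      standard_concentration_mM = 1000
    ),
    class = "thermo_context"
  )
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("<thermo_context> T = %.2f K, beta = %.6g mol/kcal, C0 = 1 M = (1660 A^3)^-1\n",
              x$temperature, x$beta))
  invisible(x)
}

.as_context <- function(ctx) {
  if (inherits(ctx, "thermo_context")) return(ctx)
  stop("`ctx` must be a thermo_context (see thermo_context())", call. = FALSE)
}

#' Convert a molar concentration to a number density
#'
#' `concentration_to_density()` maps a reservoir concentration in mM to a
#' number density in A^-3 (1 mM corresponds to 6.02e-7 A^-3);
#' `density_to_concentration()` is its exact inverse.
#'
#' @param concentration Concentration(s) in mM, non-negative.
#' @param density Number density(ies) in A^-3, non-negative.
#' @return Numeric vector of the converted values.
#' @examples
#' concentration_to_density(1)    # 6.02e-7 A^-3
#' concentration_to_density(1000) # 6.02e-4 A^-3
#' @export
concentration_to_density <- function(concentration) {
  if (!is.numeric(concentration) || any(!is.finite(concentration)) ||
      any(concentration < 0)) {
    stop("`concentration` must be finite and >= 0 (mM)", call. = FALSE)
  }
  concentration * .density_per_mM
}

#' @rdname concentration_to_density
#' @export
density_to_concentration <- function(density) {
  if (!is.numeric(density) || any(!is.finite(density)) || any(density < 0)) {
    stop("`density` must be finite and >= 0 (A^-3)", call. = FALSE)
  }
  density / .density_per_mM
}

#' Ligand reservoir description
#'
#' The membrane-aqueous reservoir is treated as homogeneous, characterised by
#' an excess chemical potential (the ligand's solvation free energy, equal to
#' its single-molecule reversible coupling work anywhere in the reservoir) and
#' a bulk concentration.
#'
#' @param excess_mu Excess chemical potential in kcal/mol.
#' @param concentration Reservoir concentration in mM (non-negative).
#' @return An object of class `ligand_reservoir` with elements `excess_mu`
#'   (kcal/mol), `concentration` (mM) and `number_density` (A^-3).
#' @examples
#' res <- ligand_reservoir(excess_mu = -0.1, concentration = 1)
#' @export
ligand_reservoir <- function(excess_mu, concentration = 1) {
  if (!is.numeric(excess_mu) || length(excess_mu) != 1L || !is.finite(excess_mu))
    stop("`excess_mu` must be a single finite number (kcal/mol)", call. = FALSE)
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration) || concentration < 0)
    stop("`concentration` must be a single number >= 0 (mM)", call. = FALSE)
  structure(
    list(
      excess_mu = excess_mu,
      concentration = concentration,
      number_density = concentration_to_density(concentration)
    ),
    class = "ligand_reservoir"
  )
}

#' @export
print.ligand_reservoir <- function(x, ...) {
  cat(sprintf("<ligand_reservoir> mu_excess = %.3g kcal/mol, c = %.4g mM (%.4g A^-3)\n",
              x$excess_mu, x$concentration, x$number_density))
  invisible(x)
}

.as_reservoir <- function(res) {
  if (inherits(res, "ligand_reservoir")) return(res)
  stop("`reservoir` must be a ligand_reservoir (see ligand_reservoir())",
       call. = FALSE)
}

# Dilute-theory caution threshold: warn at and above 1 M.
.check_concentration <- function(concentration) {
  if (any(concentration >= 1000)) {
    warning("concentration >= 1 M: the dilute-reservoir model is a caution zone here",
            call. = FALSE)
  }
  invisible(concentration)
}
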