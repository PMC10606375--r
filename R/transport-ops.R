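#' Series permeability of a two-film composite
#'
#' Combines two diffusion films meeting at a partitioning interface into a
#' single interface permeability,
#' \deqn{P = \frac{1}{\delta_A K_p / D_A + \delta_B / D_B}}
#' where \eqn{\delta} are the diffusion distances on each side, \eqn{D} the
#' phase diffusivities and \eqn{K_p} the partition coefficient carried by the
#' link (see [interface_flux()] for the sign/equilibrium convention).
#'
#' @param delta_a,delta_b diffusion distance on side A / B (m).
#' @param diff_a,diff_b diffusivity in phase A / B (m^2/s).
#' @param kp_ab partition coefficient of the link; at equilibrium
#'   `conc_a == conc_b / kp_ab`.
#' @return permeability (m/s).
#' @examples
#' series_permeability(1e-5, 1e-10, 1e-5, 1e-10, 1)  # 5e-6 m/s
#' @export
series_permeability <- function(delta_a, diff_a, delta_b, diff_b, kp_ab) {
  check_positive(delta_a, "delta_a")
  check_positive(diff_a, "diff_a")
  check_positive(delta_b, "delta_b")
  check_positive(diff_b, "diff_b")
  check_positive(kp_ab, "kp_ab")
  1 / (delta_a * kp_ab / diff_a + delta_b / diff_b)
}

#' Diffusive flux across a compartment interface
#'
#' The elementary transport law of the compartment network:
#' \deqn{J_{A \to B} = P \, SA \, (C_A - C_B / K_p)}
#' Flux is positive from A to B and vanishes exactly at partition equilibrium
#' `conc_a == conc_b / kp_ab`, i.e. `kp_ab` is the equilibrium concentration
#' ratio of the B phase over the A phase.
#'
#' @param permeability interface permeability (m/s).
#' @param area interface surface area (m^2).
#' @param conc_a,conc_b concentrations in compartments A and B (kg/m^3).
#' @inheritParams series_permeability
#' @return flux (kg/s), positive A to B.
#' @export
interface_flux <- function(permeability, area, conc_a, conc_b, kp_ab) {
  check_positive(permeability, "permeability")
  check_positive(area, "area")
  check_positive(kp_ab, "kp_ab")
  check_positive(conc_a, "conc_a", allow_zero = TRUE)
  check_positive(conc_b, "conc_b", allow_zero = TRUE)
  permeability * area * (conc_a - conc_b / kp_ab)
}

#' Mackie-Meares obstruction correction for a porous membrane
#'
#' Reduces the free (aqueous) diffusivity of a solute to its effective value
#' inside a water-swollen porous membrane,
#' \deqn{D_{eff} = D \left( \frac{\varepsilon}{2 - \varepsilon} \right)^2}
#' with \eqn{\varepsilon} the membrane porosity.
#'
#' @param free_diffusivity aqueous diffusivity of the solute (m^2/s).
#' @param porosity membrane porosity, in (0, 1].
#' @return effective diffusivity (m^2/s), `<= free_diffusivity`.
#' @examples
#' mackie_meares_diffusivity(9e-10, 0.5)  # 1e-10
#' @export
mackie_meares_diffusivity <- function(free_diffusivity, porosity) {
  check_positive(free_diffusivity, "free_diffusivity")
  if (!is.numeric(porosity) || anyNA(porosity) ||
      any(porosity <= 0) || any(porosity > 1)) {
    stop("`porosity` must lie in (0, 1]", call. = FALSE)
  }
  free_diffusivity * (porosity / (2 - porosity))^2
}

#' Exact two-film composite permeability at a partitioned interface
#'
#' Solves the steady two-film problem (flux continuity with partition
#' equilibrium `C_B = kp_ab * C_A` at the phase boundary) under the flux
#' convention of [interface_flux()]:
#' \deqn{P = \frac{1}{\delta_A / D_A + \delta_B / (K_p D_B)}}
#' This reduces to [series_permeability()] when `kp_ab = 1`; at `kp_ab != 1`
#' it weights each film in consistent concentration units, which is required
#' for composite barriers to reproduce the closed-form slab limits. Used by
#' the network assembly wherever two diffusion films meet across a partition.
#'
#' @inheritParams series_permeability
#' @return permeability (m/s), referenced to the A-side driving force
#'   `C_A - C_B / kp_ab`.
#' @export
interface_permeability <- function(delta_a, diff_a, delta_b, diff_b, kp_ab) {
  check_positive(delta_a, "delta_a")
  check_positive(diff_a, "diff_a")
  check_positive(delta_b, "delta_b")
  check_positive(diff_b, "diff_b")
  check_positive(kp_ab, "kp_ab")
  1 / (delta_a / diff_a + delta_b / (kp_ab * diff_b))
}

#' Aqueous diffusivity estimate from molecular weight
#'
#' Log-linear molecular-weight correlation for small-molecule aqueous
#' diffusivities, `D = 10^(-4.113 - 0.4609 log10(MW)) cm^2/s`, converted to
#' m^2/s. Used as the default free diffusivity for inert-membrane transport
#' when no measured value is supplied.
#'
#' @param molecular_weight g/mol.
#' @return diffusivity (m^2/s).
#' @export
aqueous_diffusivity <- function(molecular_weight) {
  check_positive(molecular_weight, "molecular_weight")
  1e-4 * 10^(-4.113 - 0.4609 * log10(molecular_weight))
}
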