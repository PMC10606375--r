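#' Physicochemical record of the permeant
#'
#' Carried as metadata by every simulation. `pka` and `vehicle_ph` are stored
#' but not used in any transport law (no ionisation correction is applied; for
#' desoximetasone, pKa 13.44 against pH 7.4 leaves the molecule un-ionised
#' anyway).
#'
#' @param molecular_weight g/mol.
#' @param log_p octanol/water log10 partition coefficient.
#' @param pka acid dissociation constant (metadata only).
#' @param vehicle_ph pH of the vehicle/receptor system (metadata only).
#' @param name optional display name.
#' @return a `compound_props` object.
#' @export
compound_props <- function(molecular_weight, log_p, pka = NA_real_,
                           vehicle_ph = NA_real_, name = "compound") {
  check_positive(molecular_weight, "molecular_weight")
  if (!is.finite(log_p)) stop("`log_p` must be finite", call. = FALSE)
  structure(
    list(
      name = name,
      molecular_weight = molecular_weight,
      log_p = log_p,
      pka = pka,
      vehicle_ph = vehicle_ph
    ),
    class = "compound_props"
  )
}

#' @export
print.compound_props <- function(x, ...) {
  cat(sprintf("<compound_props> %s: MW %.1f g/mol, logP %.2f, pKa %s, pH %s\n",
              x$name, x$molecular_weight, x$log_p,
              format(x$pka), format(x$vehicle_ph)))
  invisible(x)
}

#' Desoximetasone reference compound
#'
#' The corticosteroid used throughout the worked examples and presets
#' (MW 376.5 g/mol, logP 2.35, pKa 13.44, vehicle pH 7.4).
#'
#' @return a [compound_props()] object.
#' @export
desoximetasone <- function() {
  compound_props(376.5, 2.35, pka = 13.44, vehicle_ph = 7.4,
                 name = "desoximetasone")
}

#' QSPR estimates of skin phase partition coefficients
#'
#' The printed transport parameter set covers the vehicle-facing and
#' receptor-facing interfaces; partitioning between the internal skin phases
#' (SC lipid, corneocyte, viable epidermis) must be filled in. These defaults
#' are computed once from logP using standard quantitative
#' structure-permeation forms: lipid/water `Kow^0.69`; keratin/water
#' `5.6 Kow^0.27`; the corneocyte as a hydrated keratin mixture
#' (45 % keratin by volume). The viable epidermis and dermis are treated as
#' aqueous tissue (unit partition against water).
#'
#' @param log_p octanol/water log10 partition coefficient.
#' @param keratin_fraction corneocyte keratin volume fraction.
#' @return named list with `lipid_water`, `corneocyte_water`,
#'   `corneocyte_lipid` and `lipid_ve` equilibrium concentration ratios.
#' @export
qspr_partitions <- function(log_p, keratin_fraction = 0.45) {
  kow <- 10^log_p
  lipid_water <- kow^0.69
  keratin_water <- 5.6 * kow^0.27
  corneocyte_water <- keratin_fraction * keratin_water + (1 - keratin_fraction)
  list(
    lipid_water = lipid_water,
    corneocyte_water = corneocyte_water,
    corneocyte_lipid = corneocyte_water / lipid_water,
    lipid_ve = lipid_water
  )
}
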