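# Internal state is strict SI (m, s, kg, kg/m^3). User-facing interfaces use
# the conventional Franz-cell units (ug, mL, cm^2, h); conversion happens here
# and only here.

HOUR <- 3600

#' Unit conversion helpers
#'
#' Small, explicit converters between the SI units used internally and the
#' conventional units of Franz-cell work. All are trivially vectorised.
#'
#' @param x numeric vector.
#' @return numeric vector in the target unit.
#' @name units
#' @keywords internal
NULL

ug_to_kg <- function(x) x * 1e-9
kg_to_ug <- function(x) x * 1e9
mg_to_kg <- function(x) x * 1e-6
ml_to_m3 <- function(x) x * 1e-6
ul_to_m3 <- function(x) x * 1e-9
m3_to_ml <- function(x) x * 1e6
cm2_to_m2 <- function(x) x * 1e-4
m2_to_cm2 <- function(x) x * 1e4
um_to_m <- function(x) x * 1e-6
mm_to_m <- function(x) x * 1e-3
cm_to_m <- function(x) x * 1e-2
h_to_s <- function(x) x * HOUR
s_to_h <- function(x) x / HOUR
# ug/mL == mg/mL * 1e-3; 1 mg/mL == 1 kg/m^3
ug_ml_to_si <- function(x) x * 1e-3
si_to_ug_ml <- function(x) x * 1e3

# kg over m^2 -> ug over cm^2
si_area_dose_to_ug_cm2 <- function(x) kg_to_ug(x) / 1e4

check_positive <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite and numeric", name), call. = FALSE)
  }
  if (allow_zero) {
    if (any(x < 0)) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  } else if (any(x <= 0)) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
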