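# broom-style tidiers for the fitted/simulated objects.

#' Tidy a calibration result
#'
#' One row per calibrated parameter with its start, bounds and estimate.
#'
#' @param x a `calibration_result`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.calibration_result <- function(x, ...) {
  free <- x$spec$free
  if (nrow(free) == 0) {
    return(tibble::tibble(parameter = character(), start = numeric(),
                          lower = numeric(), upper = numeric(),
                          estimate = numeric(), scale = character()))
  }
  tibble::tibble(
    parameter = free$name,
    start = free$init,
    lower = free$lower,
    upper = free$upper,
    estimate = unname(x$estimates[free$name]),
    scale = free$scale
  )
}

#' One-line summary of a calibration result
#'
#' @inheritParams tidy.calibration_result
#' @return a one-row tibble.
#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(
    stage = x$spec$stage,
    objective = x$objective_value,
    initial_objective = x$initial_objective,
    n_parameters = nrow(x$spec$free),
    n_eval = x$n_eval,
    converged = x$converged
  )
}

#' Tidy a simulated Franz-cell run
#'
#' Long per-compartment-group amount trajectories; equivalent to
#' [as_tibble.franz_simulation()].
#'
#' @param x a `franz_simulation`.
#' @param ... unused.
#' @return a tibble with `time_h`, `group`, `amount_ug`.
#' @export
tidy.franz_simulation <- function(x, ...) {
  as_tibble(x)
}

#' One-line summary of a simulated Franz-cell run
#'
#' @inheritParams tidy.franz_simulation
#' @return a one-row tibble with the headline outputs.
#' @export
glance.franz_simulation <- function(x, ...) {
  mb <- mass_balance_report(x)
  q <- cumulative_per_area(x)
  tibble::tibble(
    mode = x$mode,
    duration_h = s_to_h(max(x$times)),
    n_states = x$settings$n_states,
    final_q_ug_per_cm2 = q$q_ug_per_cm2[nrow(q)],
    receptor_ug = mb$receptor_ug,
    sampled_ug = mb$sampled_ug,
    donor_residual_ug = mb$donor_residual_ug,
    recovery_pct = mb$recovery_pct
  )
}
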