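# Coarse, fast experiment builders shared across tests. Resolution is reduced
# relative to the package defaults; the convergence tests cover the gap.

fast_ivrt <- function(vehicle = "cream", duration_h = 24,
                      times_h = c(0.5, 1, 2, 4, 6, 8, 24), n_cells = 12) {
  ivrt_experiment(
    vehicle,
    config = franz_cell_config(duration_h = duration_h,
                               sampling = sampling_schedule(times_h = times_h)),
    membrane = membrane_spec(n_cells = 4),
    n_cells = n_cells
  )
}

fast_ivpt <- function(vehicle = "cream", times_h = c(12, 18, 24, 36)) {
  ivpt_experiment(
    vehicle,
    config = franz_cell_config(duration_h = 36,
                               sampling = sampling_schedule(times_h = times_h)),
    n_cells = 10, lateral_cells = 1, ve_cells = 4, dm_cells = 6
  )
}

final_q <- function(sim) {
  q <- cumulative_per_area(sim)
  q$q_ug_per_cm2[nrow(q)]
}
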