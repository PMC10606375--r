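# Two-stage calibration: stage 1 fits release-model (vehicle/membrane)
# parameters to IVRT data; stage 2 fixes those and fits the skin transport
# parameters to IVPT data.

RELEASE_PARAMETERS <- c("diff_vehicle", "kp_vehicle_receptor", "kp_cont_disp",
                        "droplet_diameter", "particle_diameter", "solubility",
                        "dispersed_volume_fraction", "membrane_porosity",
                        "membrane_thickness")
SKIN_PARAMETERS <- c("kp_lipid_vehicle", "perm_lc_horizontal",
                     "perm_lc_vertical", "diff_ve_dm", "diff_ve",
                     "diff_dermis", "perm_dermis_receptor",
                     "kp_corneocyte_lipid", "kp_lipid_ve")

#' Rebuild an experiment with overridden model parameters
#'
#' Applies a named set of release- and/or skin-parameter values (SI units)
#' to an experiment template, rebuilding the donor vehicle, membrane or skin
#' transport as needed. `diff_vehicle` maps onto the continuous-phase
#' diffusivity of whichever vehicle kind the template holds; `diff_ve_dm`
#' sets the viable epidermis and dermis diffusivities jointly (the two are
#' tied by default).
#'
#' @param experiment a [franz_experiment()] template.
#' @param values named numeric vector of parameter overrides.
#' @return a new `franz_experiment`.
#' @export
apply_parameters <- function(experiment, values) {
  stopifnot(inherits(experiment, "franz_experiment"))
  if (length(values) == 0) return(experiment)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("`values` must be a named vector", call. = FALSE)
  }
  unknown <- setdiff(names(values), c(RELEASE_PARAMETERS, SKIN_PARAMETERS))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  veh <- experiment$vehicle
  params <- veh$params
  touched_vehicle <- FALSE
  for (nm in intersect(names(values), RELEASE_PARAMETERS)) {
    v <- unname(values[[nm]])
    if (nm %in% c("membrane_porosity", "membrane_thickness")) next
    touched_vehicle <- TRUE
    if (nm == "diff_vehicle") {
      key <- switch(veh$kind, solution = "diffusivity",
                    emulsion = "diff_continuous", suspension = "diff_vehicle")
      params[[key]] <- v
      if (veh$kind == "emulsion") params$droplet_diffusivity <- v
    } else if (nm == "droplet_diameter" || nm == "particle_diameter") {
      key <- if (veh$kind == "emulsion") "droplet_radius" else "particle_radius"
      params[[key]] <- v / 2
    } else if (nm %in% names(params)) {
      params[[nm]] <- v
    } else {
      stop(sprintf("parameter `%s` does not apply to a %s vehicle",
                   nm, veh$kind), call. = FALSE)
    }
  }
  if (touched_vehicle) {
    experiment$vehicle <- build_vehicle_model(veh$kind, veh$geometry, params)
  }
  if (experiment$mode == "ivrt") {
    mem <- experiment$barrier
    redo <- FALSE
    if ("membrane_porosity" %in% names(values)) {
      mem$porosity <- unname(values[["membrane_porosity"]]); redo <- TRUE
    }
    if ("membrane_thickness" %in% names(values)) {
      mem$thickness <- unname(values[["membrane_thickness"]]); redo <- TRUE
    }
    if (redo) {
      experiment$barrier <- membrane_spec(
        thickness_um = mem$thickness * 1e6, porosity = mem$porosity,
        free_diffusivity = mem$free_diffusivity, n_cells = mem$n_cells)
    }
  } else {
    tr <- experiment$barrier$transport
    for (nm in intersect(names(values), SKIN_PARAMETERS)) {
      v <- unname(values[[nm]])
      if (nm == "diff_ve_dm") {
        tr$diff_ve <- v
        tr$diff_dermis <- v
      } else {
        tr[[nm]] <- v
      }
    }
    experiment$barrier$transport <- tr
  }
  experiment
}

#' Calibration stage specification
#'
#' @param stage `"release"` (stage 1, IVRT) or `"skin"` (stage 2, IVPT).
#' @param free tibble/data.frame with columns `name`, `init`, `lower`,
#'   `upper` and optionally `scale` (`"log"` default for transport
#'   parameters, `"linear"` otherwise). May have zero rows.
#' @param fixed named numeric vector of parameters held fixed.
#' @param objective `"rmse"` (default) or `"sse"` on the cumulative
#'   per-area series.
#' @param weighting `"mean_profile"` (fit the replicate mean, default) or
#'   `"pooled"` (fit all replicate points).
#' @param layer_weight stage-skin only: relative weight of the terminal
#'   layer-deposition residuals next to the permeation series.
#' @param seed integer seed controlling multi-start draws.
#' @param n_starts number of optimizer starts (first one at `init`).
#' @param maxit,reltol optimizer control.
#' @return a `calibration_spec` object.
#' @export
calibration_spec <- function(stage = c("release", "skin"), free,
                             fixed = c(), objective = c("rmse", "sse"),
                             weighting = c("mean_profile", "pooled"),
                             layer_weight = 0, seed = 1, n_starts = 1,
                             maxit = 300, reltol = 1e-8) {
  stage <- match.arg(stage)
  objective <- match.arg(objective)
  weighting <- match.arg(weighting)
  free <- tibble::as_tibble(free)
  required <- c("name", "init", "lower", "upper")
  if (nrow(free) > 0 && !all(required %in% names(free))) {
    stop("`free` needs columns name, init, lower, upper", call. = FALSE)
  }
  if (!"scale" %in% names(free)) {
    free$scale <- rep("log", nrow(free))
  }
  if (nrow(free) > 0) {
    bad <- free$lower > free$init | free$init > free$upper
    if (any(bad)) {
      stop("bounds must bracket the initial values: ",
           paste(free$name[bad], collapse = ", "), call. = FALSE)
    }
    allowed <- if (stage == "release") RELEASE_PARAMETERS else SKIN_PARAMETERS
    unknown <- setdiff(free$name, allowed)
    if (length(unknown)) {
      stop(sprintf("free parameter(s) not in the %s stage set: %s", stage,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  structure(
    list(stage = stage, free = free, fixed = fixed, objective = objective,
         weighting = weighting, layer_weight = layer_weight, seed = seed,
         n_starts = n_starts, maxit = maxit, reltol = reltol),
    class = "calibration_spec"
  )
}

# observed target series from a dataset, per the weighting mode
observed_series <- function(dataset, weighting) {
  p <- dataset_permeation(dataset)
  if (weighting == "mean_profile") {
    agg <- dplyr::summarise(dplyr::group_by(p, .data$time_h),
                            q = mean(.data$q_ug_per_cm2), .groups = "drop")
    list(times_h = agg$time_h, q = agg$q, weights = rep(1, nrow(agg)))
  } else {
    p <- p[order(p$time_h, p$replicate), ]
    list(times_h = p$time_h, q = p$q_ug_per_cm2, weights = rep(1, nrow(p)))
  }
}

observed_layers <- function(dataset) {
  ly <- dataset_layers(dataset)
  if (is.null(ly) || nrow(ly) == 0) return(NULL)
  dplyr::summarise(dplyr::group_by(ly, .data$layer),
                   deposition = mean(.data$amount_ug / .data$mass_mg),
                   .groups = "drop")
}

calibration_objective <- function(spec, dataset, template) {
  obs <- observed_series(dataset, spec$weighting)
  grid_h <- sort(unique(obs$times_h))
  out_times <- h_to_s(grid_h)
  lay_obs <- if (spec$stage == "skin" && spec$layer_weight > 0) {
    observed_layers(dataset)
  } else {
    NULL
  }
  function(values) {
    ex <- apply_parameters(template, c(spec$fixed, values))
    sim <- run_franz(ex, output_times = out_times)
    q <- cumulative_per_area(sim)
    sim_q <- q$q_ug_per_cm2[match(round(grid_h, 9), round(q$time_h, 9))]
    model <- sim_q[match(round(obs$times_h, 9), round(grid_h, 9))]
    resid <- model - obs$q
    val <- if (spec$objective == "rmse") sqrt(mean(resid^2)) else sum(resid^2)
    if (!is.null(lay_obs)) {
      sim_dep <- vapply(lay_obs$layer, function(l)
        layer_accumulation(sim, layer = l), numeric(1))
      lr <- sim_dep - lay_obs$deposition
      lval <- if (spec$objective == "rmse") sqrt(mean(lr^2)) else sum(lr^2)
      val <- val + spec$layer_weight * lval
    }
    attr(val, "residuals") <- tibble::tibble(
      time_h = obs$times_h, observed = obs$q, simulated = model,
      residual = resid)
    val
  }
}

to_internal <- function(x, scale) ifelse(scale == "log", log(x), x)
from_internal <- function(u, scale) ifelse(scale == "log", exp(u), u)

run_calibration <- function(spec, dataset, template) {
  objective <- calibration_objective(spec, dataset, template)
  free <- spec$free
  trace <- list()
  n_eval <- 0L

  eval_values <- function(values) {
    val <- objective(values)
    n_eval <<- n_eval + 1L
    trace[[n_eval]] <<- tibble::as_tibble(c(
      list(eval = n_eval), as.list(values), list(objective = as.numeric(val))))
    val
  }

  if (nrow(free) == 0) {
    values <- stats::setNames(numeric(), character())
    val <- eval_values(values)
    best <- list(values = values, objective = as.numeric(val),
                 residuals = attr(val, "residuals"), converged = TRUE)
    init_obj <- as.numeric(val)
  } else {
    lo <- to_internal(free$lower, free$scale)
    hi <- to_internal(free$upper, free$scale)
    u0 <- to_internal(free$init, free$scale)
    penalised <- function(u) {
      uc <- pmin(pmax(u, lo), hi)
      values <- stats::setNames(from_internal(uc, free$scale), free$name)
      as.numeric(eval_values(values)) +
        1e3 * sum(((u - uc) / (hi - lo))^2)
    }
    init_obj <- penalised(u0)
    starts <- list(u0)
    if (spec$n_starts > 1) {
      old_seed <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
      set.seed(spec$seed)
      for (k in seq_len(spec$n_starts - 1)) {
        starts[[k + 1]] <- lo + stats::runif(length(lo)) * (hi - lo)
      }
    }
    best <- NULL
    for (u_start in starts) {
      if (length(u0) == 1) {
        # golden section on the transformed scale; 1e-3 log-units resolves
        # the parameter to ~0.1 %, well below the solver noise floor
        opt <- stats::optimize(penalised, interval = c(lo, hi),
                               tol = max(1e-3, spec$reltol))
        cand <- list(u = opt$minimum, value = opt$objective, conv = TRUE)
      } else {
        opt <- stats::optim(u_start, penalised, method = "Nelder-Mead",
                            control = list(maxit = spec$maxit,
                                           reltol = spec$reltol))
        cand <- list(u = opt$par, value = opt$value,
                     conv = opt$convergence == 0)
      }
      if (is.null(best) || cand$value < best$value) best <- cand
    }
    # keep the better of optimum and start (objective never worse than init)
    if (init_obj < best$value) {
      best <- list(u = u0, value = init_obj, conv = FALSE)
    }
    uc <- pmin(pmax(best$u, lo), hi)
    values <- stats::setNames(from_internal(uc, free$scale), free$name)
    final <- objective(values)
    best <- list(values = values, objective = as.numeric(final),
                 residuals = attr(final, "residuals"),
                 converged = isTRUE(best$conv))
  }

  trace <- dplyr::bind_rows(trace)
  trace$best_so_far <- cummin(trace$objective)

  sensitivity <- NULL
  if (length(best$values) > 0) {
    sensitivity <- purrr::map_dfr(names(best$values), function(nm) {
      step <- 0.02
      up <- best$values; up[nm] <- up[nm] * (1 + step)
      dn <- best$values; dn[nm] <- dn[nm] * (1 - step)
      tibble::tibble(
        parameter = nm, rel_step = step,
        dobj_up = as.numeric(objective(up)) - best$objective,
        dobj_down = as.numeric(objective(dn)) - best$objective)
    })
  }

  structure(
    list(spec = spec, estimates = best$values,
         objective_value = best$objective, initial_objective = init_obj,
         converged = best$converged, trace = trace,
         residuals = best$residuals, sensitivity = sensitivity,
         n_eval = n_eval),
    class = "calibration_result"
  )
}

#' Stage-1 calibration: fit release parameters to IVRT data
#'
#' Bounded derivative-free minimisation (Nelder-Mead, or golden-section for a
#' single parameter, on log-scaled transport parameters) of the discrepancy
#' between the simulated and observed cumulative-per-area release series.
#' Deterministic given the spec's seed.
#'
#' @param spec a [calibration_spec()] with `stage = "release"`.
#' @param ivrt_data a `franz_dataset` (or tidy tibble) of observed release.
#' @param experiment_template an ivrt [franz_experiment()] defining
#'   everything not being calibrated.
#' @return a `calibration_result`.
#' @export
calibrate_release <- function(spec, ivrt_data, experiment_template) {
  stopifnot(inherits(spec, "calibration_spec"))
  if (spec$stage != "release") stop("spec stage must be 'release'",
                                    call. = FALSE)
  if (experiment_template$mode != "ivrt") {
    stop("experiment template must be an ivrt experiment", call. = FALSE)
  }
  res <- run_calibration(spec, ivrt_data, experiment_template)
  if (!is.finite(res$initial_objective)) {
    stop("objective not finite at the initial point", call. = FALSE)
  }
  res
}

#' Stage-2 calibration: fit skin parameters to IVPT data
#'
#' Fixes the release parameters at their stage-1 estimates and fits the
#' free skin transport parameters to the observed permeation series (plus,
#' optionally, terminal layer depositions weighted by `layer_weight`).
#'
#' @param spec a [calibration_spec()] with `stage = "skin"`.
#' @param ivpt_data a `franz_dataset` of observed permeation.
#' @param release_result a stage-1 `calibration_result` (or `NULL` when the
#'   release parameters are supplied through `spec$fixed`).
#' @param experiment_template an ivpt [franz_experiment()].
#' @return a `calibration_result`.
#' @export
calibrate_skin <- function(spec, ivpt_data, release_result,
                           experiment_template) {
  stopifnot(inherits(spec, "calibration_spec"))
  if (spec$stage != "skin") stop("spec stage must be 'skin'", call. = FALSE)
  if (experiment_template$mode != "ivpt") {
    stop("experiment template must be an ivpt experiment", call. = FALSE)
  }
  if (!is.null(release_result)) {
    stopifnot(inherits(release_result, "calibration_result"))
    rel <- release_result$estimates
    rel <- rel[intersect(names(rel), RELEASE_PARAMETERS)]
    rel <- rel[setdiff(names(rel), c("membrane_porosity",
                                     "membrane_thickness"))]
    spec$fixed <- c(spec$fixed[setdiff(names(spec$fixed), names(rel))], rel)
  }
  res <- run_calibration(spec, ivpt_data, experiment_template)
  if (!is.finite(res$initial_objective)) {
    stop("objective not finite at the initial point", call. = FALSE)
  }
  res
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> stage %s: %d evaluations, objective %.4g\n",
              x$spec$stage, x$n_eval, x$objective_value))
  if (length(x$estimates)) {
    for (nm in names(x$estimates)) {
      cat(sprintf("  %s = %.6g\n", nm, x$estimates[[nm]]))
    }
  } else {
    cat("  (no free parameters; fixed-point evaluation)\n")
  }
  invisible(x)
}
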