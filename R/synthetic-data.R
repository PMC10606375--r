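# Seeded generator of replicate Franz-cell datasets. No raw replicate data
# accompany the reference study, so tests, examples and the calibration
# pipeline run against synthetic datasets whose statistical structure mimics
# the experiments: n = 5-6 replicates, multiplicative lognormal replicate
# noise growing with the mean, terminal layer depositions for permeation
# runs.

#' Replicate noise model
#'
#' Multiplicative lognormal noise applied independently per replicate and
#' time point. The log-scale spread is chosen so that the coefficient of
#' variation equals `replicate_cv` and the median equals the noiseless
#' trace (median-unbiased).
#'
#' @param replicate_cv coefficient of variation of the multiplicative noise.
#' @param n_replicates number of replicates (6 for release, 5 for
#'   permeation studies by convention).
#' @param seed integer seed.
#' @return a `noise_model` object.
#' @export
noise_model <- function(replicate_cv = 0.15, n_replicates = 6, seed = 1) {
  check_positive(replicate_cv, "replicate_cv", allow_zero = TRUE)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  structure(
    list(replicate_cv = replicate_cv,
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "noise_model"
  )
}

#' A replicate Franz-cell dataset
#'
#' Container for observed (or synthetic) replicate cumulative-permeation
#' series plus optional terminal layer amounts.
#'
#' @param permeation tibble with `replicate`, `time_h`, `q_ug_per_cm2`.
#' @param layers optional tibble with `replicate`, `layer`, `amount_ug`,
#'   `mass_mg`.
#' @param group label (e.g. `"cream"`).
#' @param metadata free-form list (truth parameters, seeds, ...).
#' @return a `franz_dataset`.
#' @export
franz_dataset <- function(permeation, layers = NULL, group = "group",
                          metadata = list()) {
  permeation <- tibble::as_tibble(permeation)
  req <- c("replicate", "time_h", "q_ug_per_cm2")
  if (!all(req %in% names(permeation))) {
    stop("`permeation` needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(permeation$q_ug_per_cm2 < 0)) {
    stop("cumulative amounts must be non-negative", call. = FALSE)
  }
  if (!is.null(layers)) layers <- tibble::as_tibble(layers)
  structure(
    list(permeation = permeation, layers = layers, group = group,
         metadata = metadata),
    class = "franz_dataset"
  )
}

#' @export
print.franz_dataset <- function(x, ...) {
  cat(sprintf(
    "<franz_dataset> '%s': %d replicates x %d times%s\n", x$group,
    length(unique(x$permeation$replicate)),
    length(unique(x$permeation$time_h)),
    if (!is.null(x$layers)) sprintf(", %d layer records", nrow(x$layers))
    else ""))
  invisible(x)
}

# accessors tolerated on bare tibbles too
dataset_permeation <- function(x) {
  if (inherits(x, "franz_dataset")) return(x$permeation)
  tibble::as_tibble(x)
}
dataset_layers <- function(x) {
  if (inherits(x, "franz_dataset")) return(x$layers)
  NULL
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic replicate dataset from a virtual experiment
#'
#' Simulates the ground-truth model (optionally with parameter overrides),
#' evaluates the cumulative amount per area at the experiment's sampling
#' schedule, and applies i.i.d. multiplicative lognormal noise per replicate
#' and time point. Permeation experiments also receive terminal epidermis
#' and dermis deposition records with independent noise of the same
#' coefficient of variation. The truth parameters and seed are recorded in
#' the dataset metadata.
#'
#' @param experiment a [franz_experiment()].
#' @param truth_overrides named parameter overrides defining the ground
#'   truth (see [apply_parameters()]).
#' @param noise a [noise_model()].
#' @param group dataset label.
#' @param density_g_cm3 tissue density for the layer mass records.
#' @return a `franz_dataset`.
#' @export
generate_dataset <- function(experiment, truth_overrides = c(),
                             noise = noise_model(), group = "synthetic",
                             density_g_cm3 = 1) {
  stopifnot(inherits(experiment, "franz_experiment"),
            inherits(noise, "noise_model"))
  ex <- apply_parameters(experiment, truth_overrides)
  times <- ex$config$sampling$times
  if (!length(times)) stop("experiment has no sampling times", call. = FALSE)
  sim <- run_franz(ex, output_times = times)
  q <- cumulative_per_area(sim)
  q_true <- q$q_ug_per_cm2[match(round(s_to_h(times), 9),
                                 round(q$time_h, 9))]
  sdlog <- sqrt(log(1 + noise$replicate_cv^2))

  layers_true <- NULL
  if (ex$mode == "ivpt") {
    stack <- ex$barrier$stack
    area_cm2 <- m2_to_cm2(ex$config$diffusion_area)
    layers_true <- tibble::tibble(
      layer = c("epidermis", "dermis"),
      amount_ug = c(
        kg_to_ug(sum(group_amount(sim, c("sc_lipid", "sc_corneocyte", "ve"))
                     [length(sim$times)])),
        kg_to_ug(group_amount(sim, "dermis")[length(sim$times)])),
      mass_mg = c(
        area_cm2 * (stack$geometry$sc_thickness +
                      stack$geometry$ve_thickness) * 100 *
          density_g_cm3 * 1000,
        area_cm2 * stack$dermis_thickness * 100 * density_g_cm3 * 1000))
  }

  with_seed(noise$seed, {
    perm <- purrr::map_dfr(seq_len(noise$n_replicates), function(r) {
      eps <- if (noise$replicate_cv > 0) {
        exp(stats::rnorm(length(q_true), 0, sdlog))
      } else {
        rep(1, length(q_true))
      }
      tibble::tibble(replicate = r, time_h = s_to_h(times),
                     q_ug_per_cm2 = q_true * eps)
    })
    layers <- NULL
    if (!is.null(layers_true)) {
      layers <- purrr::map_dfr(seq_len(noise$n_replicates), function(r) {
        eps <- if (noise$replicate_cv > 0) {
          exp(stats::rnorm(nrow(layers_true), 0, sdlog))
        } else {
          rep(1, nrow(layers_true))
        }
        tibble::tibble(replicate = r, layer = layers_true$layer,
                       amount_ug = layers_true$amount_ug * eps,
                       mass_mg = layers_true$mass_mg)
      })
    }
    franz_dataset(perm, layers = layers, group = group,
                  metadata = list(truth = as.list(truth_overrides),
                                  noise = unclass(noise),
                                  mode = ex$mode,
                                  noiseless_q = q_true,
                                  times_h = s_to_h(times)))
  })
}

# resolution used for the canned reference fixtures: coarse enough to
# regenerate quickly, fine enough to preserve the qualitative release and
# permeation patterns (documented in the fixture manifest)
fixture_settings <- function() {
  list(n_cells = 20, lateral_cells = 1, ve_cells = 6, dm_cells = 10,
       seeds = c(cream_ivrt = 101, ointment_ivrt = 102,
                 cream_ivpt = 103, ointment_ivpt = 104))
}

#' Canned synthetic reference datasets
#'
#' Four synthetic datasets (cream/ointment x release/permeation) generated
#' from the published formulation, membrane and skin presets with fixed
#' documented seeds. These stand in for the undeposited raw replicate data
#' of the reference experiments and are shipped as CSVs under
#' `inst/extdata/`; regeneration from this function reproduces the shipped
#' files exactly.
#'
#' @param dir optional directory; when given, the datasets and a manifest
#'   JSON are (re)written there.
#' @return named list of four `franz_dataset` objects (invisibly when
#'   writing).
#' @export
make_reference_fixtures <- function(dir = NULL) {
  fs <- fixture_settings()
  out <- list()
  for (veh in c("cream", "ointment")) {
    ex <- ivrt_experiment(veh, n_cells = fs$n_cells)
    nm <- paste0(veh, "_ivrt")
    out[[nm]] <- generate_dataset(
      ex, noise = noise_model(n_replicates = 6, seed = fs$seeds[[nm]]),
      group = nm)
  }
  for (veh in c("cream", "ointment")) {
    ex <- ivpt_experiment(veh, n_cells = fs$n_cells,
                          lateral_cells = fs$lateral_cells,
                          ve_cells = fs$ve_cells, dm_cells = fs$dm_cells)
    nm <- paste0(veh, "_ivpt")
    out[[nm]] <- generate_dataset(
      ex, noise = noise_model(n_replicates = 5, seed = fs$seeds[[nm]]),
      group = nm)
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(out)) {
      write_franz_dataset(out[[nm]], file.path(dir, paste0(nm, ".csv")))
    }
    manifest <- list(settings = fs[c("n_cells", "lateral_cells", "ve_cells",
                                     "dm_cells")],
                     seeds = as.list(fs$seeds),
                     noise = list(replicate_cv = 0.15,
                                  n_replicates = c(ivrt = 6, ivpt = 5)),
                     synthetic = TRUE)
    jsonlite::write_json(manifest, file.path(dir, "fixture_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(out))
  }
  out
}
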