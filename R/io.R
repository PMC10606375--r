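# Tidy-CSV dataset I/O and the flat unit-suffixed config format. One CSV
# dialect is used everywhere (simulator output, fixture generator,
# calibration input): columns `replicate, time_h, q_ug_per_cm2` plus
# optional layer rows `replicate, layer, amount_ug, mass_mg`.

#' Write a replicate dataset to CSV
#'
#' @param dataset a [franz_dataset()].
#' @param path output file.
#' @param digits significant digits written (fixed so regeneration is
#'   byte-identical).
#' @return `path`, invisibly.
#' @export
write_franz_dataset <- function(dataset, path, digits = 10) {
  stopifnot(inherits(dataset, "franz_dataset"))
  fmt <- function(x) ifelse(is.na(x), "", sprintf(paste0("%.", digits, "g"), x))
  p <- dataset$permeation
  rows <- data.frame(
    replicate = p$replicate, time_h = fmt(p$time_h),
    q_ug_per_cm2 = fmt(p$q_ug_per_cm2),
    layer = "", amount_ug = "", mass_mg = "",
    stringsAsFactors = FALSE)
  if (!is.null(dataset$layers) && nrow(dataset$layers) > 0) {
    l <- dataset$layers
    rows <- rbind(rows, data.frame(
      replicate = l$replicate, time_h = "", q_ug_per_cm2 = "",
      layer = l$layer, amount_ug = fmt(l$amount_ug),
      mass_mg = fmt(l$mass_mg), stringsAsFactors = FALSE))
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a replicate dataset from CSV
#'
#' Inverse of [write_franz_dataset()]; insensitive to row order, reports
#' malformed rows with their line numbers.
#'
#' @param path CSV file in the documented dialect.
#' @param group dataset label; defaults to the file stem.
#' @return a [franz_dataset()].
#' @export
read_franz_dataset <- function(path, group = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("replicate", "time_h", "q_ug_per_cm2")
  if (!all(req %in% names(raw))) {
    stop("missing required column(s): ",
         paste(setdiff(req, names(raw)), collapse = ", "), call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  is_layer_row <- "layer" %in% names(raw) & nzchar(trimws(raw$layer))
  perm_raw <- raw[!is_layer_row, ]
  perm <- tibble::tibble(
    replicate = num(perm_raw$replicate),
    time_h = num(perm_raw$time_h),
    q_ug_per_cm2 = num(perm_raw$q_ug_per_cm2))
  bad <- which(!stats::complete.cases(perm))
  if (length(bad)) {
    stop("malformed permeation row(s) at line(s) ",
         paste(which(!is_layer_row)[bad] + 1L, collapse = ", "),
         call. = FALSE)
  }
  neg <- which(perm$q_ug_per_cm2 < 0)
  if (length(neg)) {
    stop("negative amount at line(s) ",
         paste(which(!is_layer_row)[neg] + 1L, collapse = ", "),
         call. = FALSE)
  }
  perm <- perm[order(perm$replicate, perm$time_h), ]
  mono <- dplyr::summarise(
    dplyr::group_by(perm, .data$replicate),
    ok = !anyNA(.data$time_h) && !any(duplicated(.data$time_h)),
    .groups = "drop")
  if (any(!mono$ok)) {
    stop("duplicated time points within replicate(s) ",
         paste(mono$replicate[!mono$ok], collapse = ", "), call. = FALSE)
  }
  layers <- NULL
  if (any(is_layer_row)) {
    l <- raw[is_layer_row, ]
    layers <- tibble::tibble(
      replicate = num(l$replicate), layer = l$layer,
      amount_ug = num(l$amount_ug), mass_mg = num(l$mass_mg))
    if (anyNA(layers$amount_ug) || anyNA(layers$mass_mg)) {
      stop("malformed layer row(s)", call. = FALSE)
    }
  }
  if (is.null(group)) group <- sub("\\.csv$", "", basename(path))
  franz_dataset(perm, layers = layers, group = group,
                metadata = list(source = path))
}

#' Path to a shipped reference fixture
#'
#' @param name fixture name (e.g. `"cream_ivrt"`); `NULL` lists all.
#' @return file path.
#' @export
fixture_path <- function(name = NULL) {
  dir <- system.file("extdata", package = "dermasim")
  if (is.null(name)) return(list.files(dir, pattern = "\\.csv$"))
  path <- file.path(dir, paste0(name, ".csv"))
  if (!file.exists(path)) stop("no fixture called ", name, call. = FALSE)
  path
}

# ---- config -----------------------------------------------------------------

config_unit_map <- function() {
  list(
    ml = ml_to_m3, ul = ul_to_m3, cm2 = cm2_to_m2, um = um_to_m, mm = mm_to_m,
    cm = cm_to_m, h = h_to_s, s = identity, ug = ug_to_kg, mg = mg_to_kg,
    ug_ml = ug_ml_to_si, mg_ml = identity, m2_s = identity, m_s = identity,
    kg_m3 = identity
  )
}

config_known_keys <- c(
  "mode", "vehicle", "skin_params", "receptor_volume", "diffusion_area",
  "duration", "sampling_times", "sample_volume", "replacement_concentration",
  "membrane_porosity", "membrane_thickness", "membrane_free_diffusivity",
  "vehicle_thickness", "initial_drug_mass", "n_cells", "lateral_cells",
  "ve_cells", "dm_cells", "dispersed_volume_fraction", "particle_density",
  "solubility", "diff_vehicle", "kp_vehicle_receptor", "kp_cont_disp",
  "droplet_diameter", "particle_diameter", "brick_offset",
  "specimen_thickness", "seed"
)

#' Load a flat unit-suffixed configuration file
#'
#' Reads a YAML file of flat `key_unit: value` pairs (e.g.
#' `receptor_volume_ml: 4.7`), converts every unit-suffixed value to SI and
#' returns the resolved configuration. Unknown keys and non-positive
#' physical quantities are rejected by name.
#'
#' @param path YAML config file.
#' @return named list of resolved SI values, class `dermasim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a key/value mapping", call. = FALSE)
  unit_map <- config_unit_map()
  out <- list()
  for (key in names(raw)) {
    val <- raw[[key]]
    # YAML leaves scientific notation without a decimal point ("2e-10") as
    # character; coerce numeric-looking scalars
    if (is.character(val)) {
      num <- suppressWarnings(as.numeric(val))
      if (all(!is.na(num))) val <- num
    }
    hit <- NULL
    for (suffix in names(unit_map)) {
      if (endsWith(key, paste0("_", suffix))) {
        base <- substr(key, 1, nchar(key) - nchar(suffix) - 1)
        if (base %in% config_known_keys) {
          hit <- list(base = base, conv = unit_map[[suffix]])
          break
        }
      }
    }
    if (is.null(hit)) {
      if (!key %in% config_known_keys) {
        stop("unknown config key: ", key, call. = FALSE)
      }
      hit <- list(base = key, conv = identity)
    }
    if (is.numeric(val)) {
      if (!hit$base %in% c("brick_offset") && any(val < 0)) {
        stop("non-positive value for config key ", key, call. = FALSE)
      }
      val <- hit$conv(val)
    }
    out[[hit$base]] <- val
  }
  if (!is.null(out$membrane_porosity) &&
      (out$membrane_porosity <= 0 || out$membrane_porosity > 1)) {
    stop("config key membrane_porosity must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(out$mode) && !out$mode %in% c("ivrt", "ivpt")) {
    stop("config key mode must be 'ivrt' or 'ivpt'", call. = FALSE)
  }
  if (!is.null(out$vehicle) &&
      !out$vehicle %in% c("cream", "ointment", "solution")) {
    stop("config key vehicle must be cream, ointment or solution",
         call. = FALSE)
  }
  structure(out, class = "dermasim_config")
}

#' Build a Franz experiment from a resolved configuration
#'
#' @param config a [load_config()] result (or compatible list).
#' @return a [franz_experiment()].
#' @export
build_experiment <- function(config) {
  mode <- config$mode %||% "ivrt"
  vehicle <- config$vehicle %||% "cream"
  duration_h <- s_to_h(config$duration %||%
                         h_to_s(if (mode == "ivrt") 24 else 36))
  times_h <- config$sampling_times %||%
    (if (mode == "ivrt") c(0.5, 1, 2, 4, 6, 8, 24)
     else c(12, 14, 16, 18, 20, 22, 24, 36))
  cfg <- franz_cell_config(
    diffusion_area_cm2 = m2_to_cm2(config$diffusion_area %||%
                                     cm2_to_m2(0.64)),
    receptor_volume_ml = m3_to_ml(config$receptor_volume %||% ml_to_m3(4.7)),
    duration_h = duration_h,
    sampling = sampling_schedule(
      times_h = times_h,
      sample_volume_ul = (config$sample_volume %||% ul_to_m3(400)) * 1e9))
  overrides <- intersect(names(config),
                         c(RELEASE_PARAMETERS, SKIN_PARAMETERS))
  ex <- if (mode == "ivrt") {
    ivrt_experiment(vehicle, config = cfg,
                    membrane = membrane_spec(
                      thickness_um = (config$membrane_thickness %||%
                                        um_to_m(50)) * 1e6,
                      porosity = config$membrane_porosity %||% 0.5),
                    n_cells = config$n_cells %||% 40)
  } else {
    ivpt_experiment(vehicle, config = cfg,
                    n_cells = config$n_cells %||% 40,
                    lateral_cells = config$lateral_cells %||% 2,
                    ve_cells = config$ve_cells %||% 10,
                    dm_cells = config$dm_cells %||% 20)
  }
  if (length(overrides)) {
    vals <- unlist(config[overrides])
    ex <- apply_parameters(ex, vals)
  }
  ex
}

`%||%` <- function(a, b) if (is.null(a)) b else a
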