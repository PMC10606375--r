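#' Donor vehicle geometry
#'
#' Geometry and discretisation of the semisolid donor layer sitting in the
#' Franz-cell donor chamber. The layer is thick (default 0.92 cm) relative to
#' the diffusion depth reached over a 24-36 h study, so it is discretised as a
#' 1-D finite-volume stack with cells geometrically refined toward the
#' barrier-facing side; a well-mixed donor would grossly misstate the
#' near-barrier depletion.
#'
#' @param thickness_cm vehicle layer thickness (cm).
#' @param initial_drug_mass_ug total drug dose in the applied vehicle (ug).
#' @param contact_area_cm2 diffusion area shared with the barrier (cm^2).
#' @param n_cells number of finite-volume cells (>= 1).
#' @param refine_ratio geometric growth ratio of cell widths away from the
#'   barrier face; 1 gives a uniform grid.
#' @return a `vehicle_geometry` object (SI units internally).
#' @export
vehicle_geometry <- function(thickness_cm = 0.92, initial_drug_mass_ug = 1250,
                             contact_area_cm2 = 0.64, n_cells = 40,
                             refine_ratio = 1.2) {
  check_positive(thickness_cm, "thickness_cm")
  check_positive(initial_drug_mass_ug, "initial_drug_mass_ug")
  check_positive(contact_area_cm2, "contact_area_cm2")
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  check_positive(refine_ratio, "refine_ratio")
  structure(
    list(
      thickness = cm_to_m(thickness_cm),
      initial_drug_mass = ug_to_kg(initial_drug_mass_ug),
      contact_area = cm2_to_m2(contact_area_cm2),
      n_cells = as.integer(n_cells),
      refine_ratio = refine_ratio
    ),
    class = "vehicle_geometry"
  )
}

# cell widths ordered top (away from barrier) -> barrier face; smallest last
graded_widths <- function(length_m, n, ratio) {
  if (n == 1) return(length_m)
  if (abs(ratio - 1) < 1e-12) return(rep(length_m / n, n))
  h1 <- length_m * (ratio - 1) / (ratio^n - 1)   # smallest width
  rev(h1 * ratio^(0:(n - 1)))
}

#' Cream emulsion parameters
#'
#' Two-phase oil-in-water emulsion description of a cream. The drug exchanges
#' between dispersed oil droplets and the continuous phase through the droplet
#' surface; only the continuous phase diffuses through the vehicle.
#' `kp_cont_disp` is oriented continuous/dispersed: at equilibrium
#' `C_continuous = kp_cont_disp * C_dispersed`.
#'
#' @param droplet_diameter_um droplet diameter (um).
#' @param kp_cont_disp continuous/dispersed equilibrium concentration ratio.
#' @param diff_continuous drug diffusivity in the continuous phase (m^2/s).
#' @param dispersed_volume_fraction volume fraction of the droplet phase.
#' @param kp_vehicle_receptor vehicle/receptor equilibrium concentration
#'   ratio (vehicle over receptor).
#' @param droplet_diffusivity drug diffusivity inside droplets (m^2/s);
#'   defaults to `diff_continuous`.
#' @return an `emulsion_params` object.
#' @export
emulsion_params <- function(droplet_diameter_um = 3.37, kp_cont_disp = 4.484,
                            diff_continuous = 0.85e-10,
                            dispersed_volume_fraction = 0.2,
                            kp_vehicle_receptor = 223.872,
                            droplet_diffusivity = diff_continuous) {
  check_positive(droplet_diameter_um, "droplet_diameter_um")
  check_positive(kp_cont_disp, "kp_cont_disp")
  check_positive(diff_continuous, "diff_continuous")
  check_positive(droplet_diffusivity, "droplet_diffusivity")
  check_positive(kp_vehicle_receptor, "kp_vehicle_receptor")
  if (dispersed_volume_fraction <= 0 || dispersed_volume_fraction >= 1) {
    stop("`dispersed_volume_fraction` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      droplet_radius = um_to_m(droplet_diameter_um) / 2,
      kp_cont_disp = kp_cont_disp,
      diff_continuous = diff_continuous,
      droplet_diffusivity = droplet_diffusivity,
      dispersed_volume_fraction = dispersed_volume_fraction,
      kp_vehicle_receptor = kp_vehicle_receptor
    ),
    class = "emulsion_params"
  )
}

#' Ointment suspension parameters
#'
#' Solid drug particles dispersed in a continuous (oil) base. Dissolution from
#' the particles into the base follows the Nernst-Brunner modification of the
#' Noyes-Whitney law (see [dissolution_flux()]); particles are monodisperse
#' shrinking spheres by default (particle number conserved, radius recomputed
#' from remaining solid mass).
#'
#' @param particle_diameter_um initial particle diameter (um).
#' @param solubility_mg_ml drug solubility in the continuous base (mg/mL,
#'   i.e. kg/m^3).
#' @param diff_vehicle drug diffusivity in the base, also used as the
#'   diffusivity at the particle surface (m^2/s).
#' @param particle_density solid drug density (kg/m^3).
#' @param kp_vehicle_receptor vehicle/receptor equilibrium concentration
#'   ratio (vehicle over receptor).
#' @param shrinking logical; recompute particle radius from remaining solid
#'   mass (default) or keep the initial geometry fixed.
#' @return a `suspension_params` object.
#' @export
suspension_params <- function(particle_diameter_um = 3.37,
                              solubility_mg_ml = 0.63,
                              diff_vehicle = 1e-10,
                              particle_density = 1300,
                              kp_vehicle_receptor = 223.872,
                              shrinking = TRUE) {
  check_positive(particle_diameter_um, "particle_diameter_um")
  check_positive(solubility_mg_ml, "solubility_mg_ml")
  check_positive(diff_vehicle, "diff_vehicle")
  check_positive(particle_density, "particle_density")
  check_positive(kp_vehicle_receptor, "kp_vehicle_receptor")
  structure(
    list(
      particle_radius = um_to_m(particle_diameter_um) / 2,
      solubility = solubility_mg_ml,   # mg/mL == kg/m^3
      diff_vehicle = diff_vehicle,
      particle_density = particle_density,
      kp_vehicle_receptor = kp_vehicle_receptor,
      shrinking = isTRUE(shrinking)
    ),
    class = "suspension_params"
  )
}

#' Solution vehicle parameters
#'
#' Single-phase control vehicle: all drug dissolved in one diffusing phase.
#'
#' @param diffusivity drug diffusivity in the vehicle (m^2/s).
#' @inheritParams suspension_params
#' @return a `solution_params` object.
#' @export
solution_params <- function(diffusivity = 1e-10,
                            kp_vehicle_receptor = 223.872) {
  check_positive(diffusivity, "diffusivity")
  check_positive(kp_vehicle_receptor, "kp_vehicle_receptor")
  structure(
    list(diffusivity = diffusivity,
         kp_vehicle_receptor = kp_vehicle_receptor),
    class = "solution_params"
  )
}

#' Nernst-Brunner dissolution flux from suspended particles
#'
#' \deqn{J_{P \to V} = N_p D_p SA_p (C_s - C_v) / R_p}
#' Flux is positive (dissolution) while the vehicle is undersaturated and
#' vanishes at saturation.
#'
#' @param particle_number number of particles.
#' @param diff_p diffusivity at the particle surface (m^2/s).
#' @param surface_area_p surface area per particle (m^2).
#' @param solubility saturation concentration `C_s` (kg/m^3).
#' @param conc_vehicle dissolved drug concentration in the vehicle (kg/m^3).
#' @param radius_p particle radius (m).
#' @return dissolution flux (kg/s).
#' @export
dissolution_flux <- function(particle_number, diff_p, surface_area_p,
                             solubility, conc_vehicle, radius_p) {
  check_positive(particle_number, "particle_number")
  check_positive(diff_p, "diff_p")
  check_positive(surface_area_p, "surface_area_p")
  check_positive(solubility, "solubility")
  check_positive(conc_vehicle, "conc_vehicle", allow_zero = TRUE)
  if (any(radius_p <= 0)) {
    stop("`radius_p` must be > 0 while solid mass remains (numerical guard)",
         call. = FALSE)
  }
  particle_number * diff_p * surface_area_p * (solubility - conc_vehicle) /
    radius_p
}

#' Particle radius and surface area from remaining solid mass
#'
#' Monodisperse shrinking-sphere geometry: the particle number is conserved
#' and the common radius follows the remaining solid mass,
#' `r = (3 m / (4 pi rho N))^(1/3)`. Returns `(0, 0)` once the solid phase is
#' exhausted.
#'
#' @param solid_mass remaining undissolved drug mass (kg).
#' @param particle_number number of particles (> 0).
#' @param particle_density solid drug density (kg/m^3).
#' @return list with `radius_p` (m) and `surface_area_p` (m^2 per particle).
#' @export
update_particle_geometry <- function(solid_mass, particle_number,
                                     particle_density) {
  if (any(solid_mass < 0)) stop("`solid_mass` must be >= 0", call. = FALSE)
  check_positive(particle_number, "particle_number")
  check_positive(particle_density, "particle_density")
  r <- (3 * solid_mass / (4 * pi * particle_density * particle_number))^(1 / 3)
  list(radius_p = r, surface_area_p = 4 * pi * r^2)
}

#' Build a discretised donor vehicle model
#'
#' Partitions the initial dose across phases and cells:
#' * `solution`: all drug in the single continuous phase;
#' * `suspension`: dissolved phase saturated at `min(Cs, dose/V)`, remainder
#'   as solid particles (uniform per cell);
#' * `emulsion`: drug split between continuous and dispersed phases at
#'   partition equilibrium given the dispersed volume fraction.
#'
#' Initial concentrations are uniform per cell and the per-phase mass ledger
#' sums exactly to the initial dose.
#'
#' @param kind one of `"solution"`, `"emulsion"`, `"suspension"`.
#' @param geometry a [vehicle_geometry()].
#' @param params matching parameter object ([solution_params()],
#'   [emulsion_params()] or [suspension_params()]).
#' @return a `vehicle_model` object with per-cell state.
#' @export
build_vehicle_model <- function(kind = c("solution", "emulsion", "suspension"),
                                geometry, params) {
  kind <- match.arg(kind)
  stopifnot(inherits(geometry, "vehicle_geometry"))
  expected <- switch(kind,
    solution = "solution_params",
    emulsion = "emulsion_params",
    suspension = "suspension_params"
  )
  if (!inherits(params, expected)) {
    stop(sprintf("`params` must be a <%s> for kind '%s'", expected, kind),
         call. = FALSE)
  }

  widths <- graded_widths(geometry$thickness, geometry$n_cells,
                          geometry$refine_ratio)
  vol <- widths * geometry$contact_area
  v_tot <- sum(vol)
  mass <- geometry$initial_drug_mass

  model <- structure(
    list(kind = kind, geometry = geometry, params = params,
         widths = widths, cell_volume = vol),
    class = "vehicle_model"
  )

  if (kind == "solution") {
    model$conc_cont <- rep(mass / v_tot, length(vol))
  } else if (kind == "emulsion") {
    phi <- params$dispersed_volume_fraction
    kp <- params$kp_cont_disp
    # mass = Cc (1-phi) V + (Cc/kp) phi V
    cc <- mass / (v_tot * ((1 - phi) + phi / kp))
    model$conc_cont <- rep(cc, length(vol))
    model$conc_disp <- rep(cc / kp, length(vol))
  } else {
    cs <- params$solubility
    c_sat <- min(cs, mass / v_tot)
    dissolved <- c_sat * v_tot
    solid_total <- mass - dissolved
    model$conc_cont <- rep(c_sat, length(vol))
    model$solid_mass <- solid_total * vol / v_tot
    m_particle <- params$particle_density * 4 / 3 * pi *
      params$particle_radius^3
    model$particle_number <- model$solid_mass / m_particle
  }
  model
}

#' @export
print.vehicle_model <- function(x, ...) {
  cat(sprintf(
    "<vehicle_model> %s: %d cells, %.2f mm thick, dose %.0f ug over %.2f cm^2\n",
    x$kind, length(x$cell_volume), x$geometry$thickness * 1e3,
    kg_to_ug(x$geometry$initial_drug_mass), m2_to_cm2(x$geometry$contact_area)))
  invisible(x)
}

# continuous-phase diffusivity of the vehicle, by kind
vehicle_diffusivity <- function(model) {
  switch(model$kind,
    solution = model$params$diffusivity,
    emulsion = model$params$diff_continuous,
    suspension = model$params$diff_vehicle
  )
}

# Local network block for the vehicle: components, linear links, solid specs
# and the initial state. Indices are local (1-based); the franz assembly
# offsets them into the global state vector.
vehicle_network <- function(model) {
  n <- length(model$cell_volume)
  vol <- model$cell_volume
  area <- model$geometry$contact_area
  d <- vehicle_diffusivity(model)
  w <- model$widths

  comps <- tibble::tibble(
    name = paste0("veh_cont_", seq_len(n)),
    group = "vehicle_cont",
    volume = vol,
    is_mass = FALSE
  )
  init <- model$conc_cont
  links <- NULL
  if (n > 1) {
    i <- seq_len(n - 1)
    p <- series_permeability(w[i] / 2, d, w[i + 1] / 2, d, 1)
    links <- tibble::tibble(from = i, to = i + 1, psa = p * area, kp = 1)
  }
  solids <- NULL

  if (model$kind == "emulsion") {
    pr <- model$params
    r <- pr$droplet_radius
    phi <- pr$dispersed_volume_fraction
    # continuous cell volume excludes droplets
    comps$volume <- vol * (1 - phi)
    disp <- tibble::tibble(
      name = paste0("veh_disp_", seq_len(n)),
      group = "vehicle_disp",
      volume = vol * phi,
      is_mass = FALSE
    )
    comps <- dplyr::bind_rows(comps, disp)
    init <- c(init, model$conc_disp)
    # droplet <-> continuous exchange, lumped over all droplets in the cell
    sa_tot <- 3 * phi * vol / r
    p_drop <- interface_permeability(r, pr$diff_continuous, r,
                                     pr$droplet_diffusivity,
                                     1 / pr$kp_cont_disp)
    links <- dplyr::bind_rows(
      links,
      tibble::tibble(from = seq_len(n), to = n + seq_len(n),
                     psa = p_drop * sa_tot, kp = 1 / pr$kp_cont_disp)
    )
  } else if (model$kind == "suspension") {
    pr <- model$params
    solid <- tibble::tibble(
      name = paste0("veh_solid_", seq_len(n)),
      group = "vehicle_solid",
      volume = NA_real_,
      is_mass = TRUE
    )
    comps <- dplyr::bind_rows(comps, solid)
    init <- c(init, model$solid_mass)
    solids <- tibble::tibble(
      solid = n + seq_len(n),
      liquid = seq_len(n),
      np = model$particle_number,
      dp = pr$diff_vehicle,
      cs = pr$solubility,
      rho = pr$particle_density,
      shrinking = pr$shrinking,
      r0 = pr$particle_radius
    )
  }

  list(comps = comps, links = links, solids = solids,
       init = init, barrier_comp = n)
}

#' Time derivative of the vehicle state
#'
#' Evaluates the right-hand side of the closed vehicle model (cell-to-cell
#' continuous-phase diffusion, droplet exchange or particle dissolution) with
#' a prescribed signed flux leaving the barrier-facing cell. Internal
#' exchanges conserve mass exactly, so the amount-weighted sum of the
#' derivatives equals `-boundary_flux`.
#'
#' @param model a [build_vehicle_model()] object.
#' @param boundary_flux flux leaving the barrier-facing cell (kg/s).
#' @param state optional state vector (defaults to the model's initial state,
#'   layout as in `vehicle_state(model)`).
#' @return numeric vector of state derivatives (kg/m^3/s for concentrations,
#'   kg/s for solid masses).
#' @export
vehicle_rhs <- function(model, boundary_flux = 0, state = NULL) {
  net <- vehicle_network(model)
  if (is.null(state)) state <- net$init
  op <- network_operator(net$comps, net$links)
  damt <- as.vector(op$amat %*% state)
  damt[net$barrier_comp] <- damt[net$barrier_comp] - boundary_flux
  dy <- damt * op$inv_vol
  if (!is.null(net$solids)) {
    dy <- dy + solids_rhs(net$solids, state, op$inv_vol)
  }
  stats::setNames(dy, net$comps$name)
}

#' Initial state vector of a vehicle model
#'
#' @inheritParams vehicle_rhs
#' @return named numeric vector (concentrations kg/m^3; solid masses kg).
#' @export
vehicle_state <- function(model) {
  net <- vehicle_network(model)
  stats::setNames(net$init, net$comps$name)
}

#' Table of preset donor vehicles
#'
#' Returns the reference cream (two-phase emulsion), ointment (particle
#' suspension) and solution presets used across the examples, with the
#' published formulation parameters.
#'
#' @param vehicle `"cream"`, `"ointment"` or `"solution"`.
#' @param geometry optional [vehicle_geometry()] override.
#' @param n_cells,refine_ratio forwarded to [vehicle_geometry()] when no
#'   geometry is supplied.
#' @return a `vehicle_model`.
#' @export
preset_vehicle <- function(vehicle = c("cream", "ointment", "solution"),
                           geometry = NULL, n_cells = 40, refine_ratio = 1.2) {
  vehicle <- match.arg(vehicle)
  if (is.null(geometry)) {
    geometry <- vehicle_geometry(n_cells = n_cells, refine_ratio = refine_ratio)
  }
  switch(vehicle,
    cream = build_vehicle_model("emulsion", geometry, emulsion_params()),
    ointment = build_vehicle_model("suspension", geometry, suspension_params()),
    solution = build_vehicle_model("solution", geometry, solution_params())
  )
}
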