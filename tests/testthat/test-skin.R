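test_that("brick-and-mortar grid reproduces the published layering exactly", {
  g <- build_sc_grid(skin_geometry(), lateral_cells = 2)
  expect_identical(g$n_corneocyte_layers, 16L)
  expect_identical(g$n_lipid_layers, 17L)
  # cell volumes partition the SC slab exactly
  expect_equal(sum(g$cells$vol_per_area), 14.075e-6, tolerance = 1e-12)
  expect_equal(max(g$cells$z1), 14.075e-6, tolerance = 1e-12)
  # both phases present, lipid channels inside corneocyte strata
  cor_strata <- g$cells[g$cells$stratum %% 2 == 0, ]
  expect_true(all(c("lipid", "corneocyte") %in% cor_strata$phase))
})

test_that("toy geometries and non-commensurate thicknesses are handled", {
  toy <- skin_geometry(sc_thickness_um = 3, corneocyte_thickness_um = 1,
                       lipid_thickness_um = 1)
  g <- build_sc_grid(toy, lateral_cells = 1)
  expect_identical(g$n_corneocyte_layers, 1L)
  expect_identical(g$n_lipid_layers, 2L)
  bad <- skin_geometry(sc_thickness_um = 14.5)
  expect_error(build_sc_grid(bad), "residual")
})

test_that("flux network resolves interface permeabilities by direction", {
  tr <- skin_transport("cream_optimized")
  st <- build_skin_stack(lateral_cells = 2, ve_cells = 3, dm_cells = 4)
  net <- assemble_flux_network(st, tr, contact_area = 0.64e-4)
  lc <- net$links[net$links$type == "lipid_corneocyte", ]
  expect_gt(nrow(lc), 0)
  vert <- lc[lc$direction == "vertical", ]
  horiz <- lc[lc$direction == "horizontal", ]
  expect_gt(nrow(vert), 0)
  expect_gt(nrow(horiz), 0)
  # every depth-direction lipid/corneocyte link carries the printed override:
  # psa / area must equal 5.2e-9 m/s, with the link area = width * A / w
  cells <- st$sc$cells
  w_cell <- st$sc$unit_width
  area_of <- function(id) {
    cells$width[id] * 0.64e-4 / w_cell
  }
  expect_equal(vert$psa / area_of(pmin(vert$from, vert$to)),
               rep(5.2e-9, nrow(vert)), tolerance = 1e-12)
  # lateral-direction links carry the horizontal override: psa / (t * A / w)
  h_area <- cells$thickness[horiz$from] * 0.64e-4 / w_cell
  expect_equal(horiz$psa / h_area, rep(1.04e-10, nrow(horiz)),
               tolerance = 1e-12)
  expect_error(assemble_flux_network(st, tr, contact_area = 0), "contact_area")
})

test_that("homogenised SC permeability obeys the analytic limits", {
  d <- 1e-10
  uniform <- skin_transport(
    preset = NULL, kp_lipid_vehicle = 1, perm_lc_horizontal = NA,
    perm_lc_vertical = NA, diff_ve = d, diff_dermis = d,
    perm_dermis_receptor = 1e-3, diff_lipid = d, diff_corneocyte = d,
    kp_corneocyte_lipid = 1, kp_lipid_ve = 1)
  st <- build_skin_stack(lateral_cells = 2, ve_cells = 2, dm_cells = 2)
  p_eff <- homogenized_sc_resistance(st, uniform)
  expect_equal(p_eff, d / 14.075e-6, tolerance = 0.01)
})

test_that("brick stagger, scaling and anisotropy shape the SC resistance", {
  tr <- skin_transport("cream_optimized")
  st <- build_skin_stack(lateral_cells = 4, ve_cells = 2, dm_cells = 2)
  p_stag <- homogenized_sc_resistance(st, tr)
  st0 <- build_skin_stack(skin_geometry(brick_offset = 0), lateral_cells = 4,
                          ve_cells = 2, dm_cells = 2)
  p_align <- homogenized_sc_resistance(st0, tr)
  # aligned bricks leave straight-through channels: lower resistance
  expect_gt(p_align, p_stag)
  # monotone in the vertical interface permeability
  tr_slow <- skin_transport("cream_optimized", perm_lc_vertical = 5.2e-10)
  expect_lt(homogenized_sc_resistance(st, tr_slow), p_stag)
  # linearity: scaling every permeability and diffusivity by k scales P_eff
  k <- 3.7
  tr_k <- skin_transport(
    preset = NULL, kp_lipid_vehicle = tr$kp_lipid_vehicle,
    perm_lc_horizontal = tr$perm_lc_horizontal * k,
    perm_lc_vertical = tr$perm_lc_vertical * k,
    diff_ve = tr$diff_ve * k, diff_dermis = tr$diff_dermis * k,
    perm_dermis_receptor = tr$perm_dermis_receptor * k,
    diff_lipid = tr$diff_lipid * k, diff_corneocyte = tr$diff_corneocyte * k)
  expect_equal(homogenized_sc_resistance(st, tr_k), k * p_stag,
               tolerance = 1e-9)
})

test_that("SC permeability is grid-converged at the default resolution", {
  tr <- skin_transport("cream_optimized")
  p8 <- homogenized_sc_resistance(build_skin_stack(ve_cells = 2, dm_cells = 2),
                                  tr)
  p16 <- homogenized_sc_resistance(
    build_skin_stack(lateral_cells = 16, ve_cells = 2, dm_cells = 2), tr)
  expect_lt(abs(p16 / p8 - 1), 0.02)
})

test_that("the two SC pathways respond to their own diffusivities", {
  st <- build_skin_stack(lateral_cells = 4, ve_cells = 2, dm_cells = 2)
  p_base <- homogenized_sc_resistance(st, skin_transport("cream_optimized"))
  # corneocyte interior diffusion is a negligible series resistance: an
  # order of magnitude either way barely moves the effective permeability
  p_cor <- homogenized_sc_resistance(
    st, skin_transport("cream_optimized", diff_corneocyte = 1e-11))
  expect_lt(abs(p_cor / p_base - 1), 0.05)
  # the continuous lipid channel is a parallel pathway: raising the lipid
  # diffusivity strictly increases transport, choking it leaves the
  # transcellular interface chain as a floor
  p_lip_up <- homogenized_sc_resistance(
    st, skin_transport("cream_optimized", diff_lipid = 1e-10))
  p_lip_dn <- homogenized_sc_resistance(
    st, skin_transport("cream_optimized", diff_lipid = 1e-13))
  expect_gt(p_lip_up, p_base)
  expect_lt(p_lip_dn, p_base)
  expect_gt(p_lip_dn, 0)
})

test_that("full stack reproduces the series-resistance steady state", {
  tr <- skin_transport("cream_optimized")
  st <- build_skin_stack(lateral_cells = 4, ve_cells = 6, dm_cells = 8)
  p_sc <- homogenized_sc_resistance(st, tr)
  geom <- skin_geometry()
  kl <- tr$kp_lipid_vehicle
  kv <- kl / tr$kp_lipid_ve
  kdm <- kv / tr$kp_ve_dermis
  r_series <- 1 / (p_sc * kl) + geom$ve_thickness / (tr$diff_ve * kv) +
    geom$dermis_thickness / (tr$diff_dermis * kdm) +
    1 / (tr$perm_dermis_receptor * kdm)
  cfg <- franz_cell_config(duration_h = 48,
                           sampling = sampling_schedule(times_h = numeric(0)))
  vg <- vehicle_geometry(contact_area_cm2 = 0.64, n_cells = 4,
                         thickness_cm = 0.05)
  veh <- build_vehicle_model("solution", vg, solution_params())
  ex <- franz_experiment(cfg, veh, list(stack = st, transport = tr),
                         mode = "ivpt")
  s <- run_franz(ex, output_times = seq(0, 48 * 3600, length.out = 49),
                 donor = "constant", receptor_mode = "sink")
  q <- cumulative_per_area(s)
  fit <- stats::lm(q_ug_per_cm2 ~ time_h, q[q$time_h > 30, ])
  j_sim <- unname(stats::coef(fit)[2])
  j_analytic <- veh$conc_cont[1] / r_series * 1e9 / 1e4 * 3600
  expect_equal(j_sim, j_analytic, tolerance = 0.025)
})

test_that("specimen thickness override rescales the dermis", {
  expect_message(
    st <- build_skin_stack(lateral_cells = 1, ve_cells = 2, dm_cells = 2,
                           specimen_thickness_um = 500),
    "rescaled")
  expect_equal(st$dermis_thickness, 500e-6 - 14.075e-6 - 56e-6)
  expect_error(build_skin_stack(specimen_thickness_um = 50),
               "no room")
})
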