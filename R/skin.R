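#' Layered skin geometry
#'
#' Geometric description of the barrier used in virtual permeation testing:
#' a brick-and-mortar stratum corneum (corneocyte "bricks" in continuous
#' lipid "mortar"), a viable epidermis and a dermis, stacked between donor
#' and receptor.
#'
#' @param sc_thickness_um stratum corneum thickness (um). Must be commensurate
#'   with the corneocyte/lipid layering (see [build_sc_grid()]).
#' @param corneocyte_diameter_um lateral corneocyte width (um).
#' @param corneocyte_thickness_um corneocyte (brick) thickness (um).
#' @param lipid_thickness_um lipid (mortar) layer thickness (um).
#' @param ve_thickness_um viable epidermis thickness (um).
#' @param dermis_thickness_mm dermis thickness (mm). Reduce (or use
#'   `specimen_thickness_um` in [build_skin_stack()]) to match dermatomed
#'   specimens.
#' @param brick_offset lateral stagger between successive corneocyte layers,
#'   as a fraction of the unit-cell width.
#' @param channel_width_um width of the vertical lipid channel between
#'   laterally adjacent corneocytes; defaults to the lipid layer thickness.
#' @return a `skin_geometry` object (SI internally).
#' @export
skin_geometry <- function(sc_thickness_um = 14.075,
                          corneocyte_diameter_um = 40,
                          corneocyte_thickness_um = 0.8,
                          lipid_thickness_um = 0.075,
                          ve_thickness_um = 56,
                          dermis_thickness_mm = 1.2,
                          brick_offset = 0.5,
                          channel_width_um = lipid_thickness_um) {
  for (v in c("sc_thickness_um", "corneocyte_diameter_um",
              "corneocyte_thickness_um", "lipid_thickness_um",
              "ve_thickness_um", "dermis_thickness_mm", "channel_width_um")) {
    check_positive(get(v), v)
  }
  if (brick_offset < 0 || brick_offset >= 1) {
    stop("`brick_offset` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      sc_thickness = um_to_m(sc_thickness_um),
      corneocyte_diameter = um_to_m(corneocyte_diameter_um),
      corneocyte_thickness = um_to_m(corneocyte_thickness_um),
      lipid_thickness = um_to_m(lipid_thickness_um),
      ve_thickness = um_to_m(ve_thickness_um),
      dermis_thickness = mm_to_m(dermis_thickness_mm),
      brick_offset = brick_offset,
      channel_width = um_to_m(channel_width_um)
    ),
    class = "skin_geometry"
  )
}

#' Skin transport parameter set
#'
#' Transport parameters of the layered barrier. The six published parameters
#' (vehicle-facing lipid partition, directional lipid/corneocyte interface
#' permeabilities, viable epidermis and dermis diffusivities,
#' dermis/receptor permeability) are available as named presets; the
#' remaining phase-level parameters (SC phase diffusivities and internal
#' partition coefficients) are filled with defaults: partition coefficients
#' from logP-based QSPR forms (see [qspr_partitions()]) and phase
#' diffusivities at literature-typical orders. With these defaults the
#' transcellular lipid/corneocyte interface chain carries most of the SC
#' resistance, with the continuous lipid channel acting as a secondary
#' parallel pathway; the corneocyte interior is never rate-limiting.
#'
#' All partition coefficients are equilibrium concentration ratios oriented
#' first-phase over second-phase (e.g. `kp_lipid_vehicle = 18.8` means the SC
#' lipid holds 18.8x the vehicle concentration at equilibrium).
#'
#' @param preset `"cream_optimized"`, `"ointment_optimized"` or
#'   `"mechanistic"`; or `NULL` when all six core values are given explicitly.
#' @param kp_lipid_vehicle SC-lipid/vehicle partition coefficient.
#' @param perm_lc_horizontal,perm_lc_vertical lipid/corneocyte interface
#'   permeability for lateral / depth-direction links (m/s). `NA` falls back
#'   to a two-film series permeability from the phase diffusivities.
#' @param diff_ve,diff_dermis viable epidermis / dermis diffusivity (m^2/s).
#' @param perm_dermis_receptor dermis-to-receptor interface permeability (m/s).
#' @param diff_lipid,diff_corneocyte SC phase diffusivities (m^2/s).
#' @param kp_corneocyte_lipid,kp_lipid_ve,kp_ve_dermis,kp_dermis_receptor
#'   internal partition coefficients (first phase over second).
#' @param compound compound used for the QSPR partition defaults.
#' @return a `skin_transport` object.
#' @export
skin_transport <- function(preset = c("cream_optimized", "ointment_optimized",
                                      "mechanistic"),
                           kp_lipid_vehicle = NULL,
                           perm_lc_horizontal = NULL,
                           perm_lc_vertical = NULL,
                           diff_ve = NULL,
                           diff_dermis = NULL,
                           perm_dermis_receptor = NULL,
                           diff_lipid = 1e-11,
                           diff_corneocyte = 1e-12,
                           kp_corneocyte_lipid = NULL,
                           kp_lipid_ve = NULL,
                           kp_ve_dermis = 1,
                           kp_dermis_receptor = 1,
                           compound = desoximetasone()) {
  presets <- list(
    mechanistic = list(kp_lipid_vehicle = 18.8,
                       perm_lc_horizontal = 4.15e-11,
                       perm_lc_vertical = 2.07e-9,
                       diff_ve = 3.65e-11, diff_dermis = 3.65e-11,
                       perm_dermis_receptor = 7.02e-9),
    cream_optimized = list(kp_lipid_vehicle = 18.8,
                           perm_lc_horizontal = 1.04e-10,
                           perm_lc_vertical = 5.2e-9,
                           diff_ve = 1.1e-9, diff_dermis = 1.1e-9,
                           perm_dermis_receptor = 3.5e-7),
    ointment_optimized = list(kp_lipid_vehicle = 11.6,
                              perm_lc_horizontal = 0.87e-10,
                              perm_lc_vertical = 4.35e-9,
                              diff_ve = 1.1e-9, diff_dermis = 1.1e-9,
                              perm_dermis_receptor = 3.5e-7)
  )
  base <- if (!is.null(preset)) {
    presets[[match.arg(preset)]]
  } else {
    list()
  }
  take <- function(explicit, key) if (!is.null(explicit)) explicit else base[[key]]
  out <- list(
    kp_lipid_vehicle = take(kp_lipid_vehicle, "kp_lipid_vehicle"),
    perm_lc_horizontal = take(perm_lc_horizontal, "perm_lc_horizontal"),
    perm_lc_vertical = take(perm_lc_vertical, "perm_lc_vertical"),
    diff_ve = take(diff_ve, "diff_ve"),
    diff_dermis = take(diff_dermis, "diff_dermis"),
    perm_dermis_receptor = take(perm_dermis_receptor, "perm_dermis_receptor"),
    diff_lipid = diff_lipid,
    diff_corneocyte = diff_corneocyte,
    kp_ve_dermis = kp_ve_dermis,
    kp_dermis_receptor = kp_dermis_receptor
  )
  qp <- qspr_partitions(compound$log_p)
  out$kp_corneocyte_lipid <- if (is.null(kp_corneocyte_lipid)) {
    qp$corneocyte_lipid
  } else {
    kp_corneocyte_lipid
  }
  out$kp_lipid_ve <- if (is.null(kp_lipid_ve)) qp$lipid_ve else kp_lipid_ve
  for (key in c("kp_lipid_vehicle", "diff_ve", "diff_dermis",
                "perm_dermis_receptor")) {
    if (is.null(out[[key]])) {
      stop(sprintf("missing skin transport parameter `%s`", key), call. = FALSE)
    }
    check_positive(out[[key]], key)
  }
  structure(out, class = "skin_transport")
}

#' Build the brick-and-mortar stratum corneum grid
#'
#' Constructs the 2-D unit cell of the stratum corneum: alternating lipid and
#' corneocyte strata (n corneocyte layers interleaved between n+1 lipid
#' layers), with corneocytes staggered between successive layers by
#' `brick_offset` and separated laterally by vertical lipid channels. The
#' lateral boundary is periodic. The layer count must reproduce the SC
#' thickness exactly: `n * t_cor + (n+1) * t_lip = sc_thickness`.
#'
#' @param geometry a [skin_geometry()].
#' @param lateral_cells lateral resolution: number of sub-cells each
#'   corneocyte segment is split into.
#' @return an `sc_grid` object with a `cells` tibble (stratum, segment, phase,
#'   lateral extent, depth extent, volume per unit skin area) and layer
#'   counts.
#' @export
build_sc_grid <- function(geometry, lateral_cells = 8) {
  stopifnot(inherits(geometry, "skin_geometry"))
  tc <- geometry$corneocyte_thickness
  tl <- geometry$lipid_thickness
  tt <- geometry$sc_thickness
  n <- round((tt - tl) / (tc + tl))
  residual <- n * tc + (n + 1) * tl - tt
  if (n < 1 || abs(residual) > 1e-9) {
    stop(sprintf(
      paste0("SC thickness is not commensurate with the layering: ",
             "n * %.4g + (n+1) * %.4g != %.4g (residual %.3g m)"),
      tc, tl, tt, residual), call. = FALSE)
  }

  w_cell <- geometry$corneocyte_diameter + geometry$channel_width
  g <- geometry$channel_width
  # channel intervals per corneocyte layer (staggered); may wrap around
  centers <- (geometry$corneocyte_diameter + g / 2 +
                (0:(n - 1)) * geometry$brick_offset * w_cell) %% w_cell
  channel_intervals <- lapply(centers, function(ctr) {
    lo <- ctr - g / 2
    hi <- ctr + g / 2
    if (lo < 0) {
      list(c(lo + w_cell, w_cell), c(0, hi))
    } else if (hi > w_cell) {
      list(c(lo, w_cell), c(0, hi - w_cell))
    } else {
      list(c(lo, hi))
    }
  })

  cuts <- sort(unique(round(
    c(0, w_cell, unlist(channel_intervals)), 15)))
  cuts <- cuts[cuts >= 0 & cuts <= w_cell]
  cuts <- cuts[!duplicated(round(cuts / w_cell, 12))]
  if (max(cuts) < w_cell) cuts <- c(cuts, w_cell)
  # subdivide wide segments for lateral resolution
  target <- geometry$corneocyte_diameter / lateral_cells
  xs <- unlist(lapply(seq_len(length(cuts) - 1), function(i) {
    a <- cuts[i]; b <- cuts[i + 1]
    k <- max(1L, ceiling((b - a) / target - 1e-9))
    seq(a, b, length.out = k + 1)[-(k + 1)]
  }))
  xs <- c(xs, w_cell)
  seg_x0 <- xs[-length(xs)]
  seg_x1 <- xs[-1]
  seg_mid <- (seg_x0 + seg_x1) / 2

  in_channel <- function(layer_k, x) {
    any(vapply(channel_intervals[[layer_k]],
               function(iv) x > iv[1] - 1e-15 && x < iv[2] + 1e-15,
               logical(1)))
  }

  n_strata <- 2L * n + 1L
  z_top <- cumsum(c(0, rep(c(tl, tc), n)))[seq_len(n_strata)]
  stratum_thickness <- rep(c(tl, tc), length.out = n_strata)
  cells <- purrr::map_dfr(seq_len(n_strata), function(i) {
    is_lipid_stratum <- i %% 2L == 1L
    layer_k <- i %/% 2L  # corneocyte layer index for even strata
    phase <- if (is_lipid_stratum) {
      rep("lipid", length(seg_mid))
    } else {
      ifelse(vapply(seg_mid, function(x) in_channel(layer_k, x), logical(1)),
             "lipid", "corneocyte")
    }
    tibble::tibble(
      stratum = i, segment = seq_along(seg_mid), phase = phase,
      x0 = seg_x0, x1 = seg_x1,
      z0 = z_top[i], z1 = z_top[i] + stratum_thickness[i],
      width = seg_x1 - seg_x0, thickness = stratum_thickness[i],
      vol_per_area = (seg_x1 - seg_x0) * stratum_thickness[i] / w_cell
    )
  })

  structure(
    list(
      cells = cells,
      n_corneocyte_layers = as.integer(n),
      n_lipid_layers = as.integer(n + 1L),
      n_strata = n_strata,
      n_segments = length(seg_mid),
      unit_width = w_cell,
      geometry = geometry
    ),
    class = "sc_grid"
  )
}

#' @export
print.sc_grid <- function(x, ...) {
  cat(sprintf(
    "<sc_grid> %d corneocyte + %d lipid layers, %d lateral segments, %d cells\n",
    x$n_corneocyte_layers, x$n_lipid_layers, x$n_segments, nrow(x$cells)))
  invisible(x)
}

#' Assemble the discretised skin stack
#'
#' Builds the full barrier: brick-and-mortar SC grid on top, 1-D viable
#' epidermis and dermis cell chains below, with cell widths refined toward
#' the upstream interface of each layer.
#'
#' @inheritParams build_sc_grid
#' @param ve_cells,dm_cells number of viable epidermis / dermis cells.
#' @param refine_ratio geometric width ratio within VE and dermis.
#' @param specimen_thickness_um optional total specimen thickness (um); when
#'   given, the dermis is rescaled so SC + VE + dermis matches it (as for
#'   dermatomed skin), with a message.
#' @return a `skin_stack` object.
#' @export
build_skin_stack <- function(geometry = skin_geometry(), lateral_cells = 8,
                             ve_cells = 10, dm_cells = 20, refine_ratio = 1.3,
                             specimen_thickness_um = NULL) {
  sc <- build_sc_grid(geometry, lateral_cells = lateral_cells)
  dermis_thickness <- geometry$dermis_thickness
  if (!is.null(specimen_thickness_um)) {
    dermis_thickness <- um_to_m(specimen_thickness_um) -
      geometry$sc_thickness - geometry$ve_thickness
    if (dermis_thickness <= 0) {
      stop("`specimen_thickness_um` leaves no room for the dermis",
           call. = FALSE)
    }
    message(sprintf(
      "dermis thickness rescaled to %.1f um to match specimen thickness",
      dermis_thickness * 1e6))
  }
  ve_widths <- rev(graded_widths(geometry$ve_thickness, ve_cells, refine_ratio))
  dm_widths <- rev(graded_widths(dermis_thickness, dm_cells, refine_ratio))
  structure(
    list(sc = sc, geometry = geometry,
         ve_widths = ve_widths, dm_widths = dm_widths,
         dermis_thickness = dermis_thickness,
         total_thickness = geometry$sc_thickness + geometry$ve_thickness +
           dermis_thickness),
    class = "skin_stack"
  )
}

# orientation helper: spec-form kp for a link from phase a to phase b,
# given the first-over-second partition table
link_kp <- function(phase_from, phase_to, transport) {
  kcl <- transport$kp_corneocyte_lipid
  if (phase_from == phase_to) return(1)
  if (phase_from == "lipid" && phase_to == "corneocyte") return(kcl)
  if (phase_from == "corneocyte" && phase_to == "lipid") return(1 / kcl)
  stop("unknown phase pair", call. = FALSE)
}

phase_diffusivity <- function(phase, transport) {
  switch(phase, lipid = transport$diff_lipid,
         corneocyte = transport$diff_corneocyte)
}

#' Assemble the interface-flux network of the skin stack
#'
#' Resolves every cell-to-cell interface of the stack to a permeability,
#' area, and partition coefficient. Lipid/corneocyte contacts use the
#' directional interface permeabilities (`perm_lc_horizontal` for lateral
#' links, `perm_lc_vertical` for depth links) as overrides; same-phase
#' contacts use two-film series permeabilities from the phase diffusivities;
#' the dermis/receptor exit uses `perm_dermis_receptor`. Partition
#' coefficients enter with the flux convention of [interface_flux()].
#'
#' @param stack a [build_skin_stack()] object.
#' @param transport a [skin_transport()] object.
#' @param contact_area diffusion area (m^2).
#' @return list with `comps` (component tibble), `links` (link tibble with
#'   direction and type tags), `top_cells` (component ids facing the
#'   vehicle), `bottom_cell` (dermis cell facing the receptor).
#' @export
assemble_flux_network <- function(stack, transport, contact_area) {
  stopifnot(inherits(stack, "skin_stack"), inherits(transport, "skin_transport"))
  check_positive(contact_area, "contact_area")
  sc <- stack$sc
  cells <- sc$cells
  nseg <- sc$n_segments
  nstr <- sc$n_strata
  w_cell <- sc$unit_width
  cid <- function(stratum, segment) (stratum - 1L) * nseg + segment

  comps <- tibble::tibble(
    name = sprintf("sc_%d_%d", cells$stratum, cells$segment),
    group = ifelse(cells$phase == "lipid", "sc_lipid", "sc_corneocyte"),
    volume = cells$vol_per_area * contact_area,
    is_mass = FALSE
  )

  phase_m <- matrix(cells$phase, nrow = nseg)  # [segment, stratum]
  width <- matrix(cells$width, nrow = nseg)
  thick_s <- cells$thickness[match(seq_len(nstr), cells$stratum)]

  links <- list()
  add <- function(from, to, p, sa, kp, direction, type) {
    links[[length(links) + 1L]] <<- tibble::tibble(
      from = from, to = to, psa = p * sa, kp = kp,
      direction = direction, type = type)
  }

  lc_perm <- function(direction, pa, pb, da, db, da_dist, db_dist, kp) {
    ov <- if (direction == "horizontal") transport$perm_lc_horizontal
          else transport$perm_lc_vertical
    if (!is.null(ov) && !is.na(ov)) ov
    else interface_permeability(da_dist, da, db_dist, db, kp)
  }

  for (i in seq_len(nstr)) {
    ti <- thick_s[i]
    # horizontal links within stratum (periodic wrap)
    for (j in seq_len(nseg)) {
      j2 <- if (j == nseg) 1L else j + 1L
      pa <- phase_m[j, i]; pb <- phase_m[j2, i]
      kp <- link_kp(pa, pb, transport)
      da <- phase_diffusivity(pa, transport)
      db <- phase_diffusivity(pb, transport)
      sa <- ti * contact_area / w_cell
      if (pa == pb) {
        p <- series_permeability(width[j, i] / 2, da, width[j2, i] / 2, db, kp)
        type <- paste0(pa, "_", pb)
      } else {
        p <- lc_perm("horizontal", pa, pb, da, db,
                     width[j, i] / 2, width[j2, i] / 2, kp)
        type <- "lipid_corneocyte"
      }
      if (nseg > 1L) add(cid(i, j), cid(i, j2), p, sa, kp, "horizontal", type)
    }
    # vertical links to next stratum
    if (i < nstr) {
      ti2 <- thick_s[i + 1]
      for (j in seq_len(nseg)) {
        pa <- phase_m[j, i]; pb <- phase_m[j, i + 1]
        kp <- link_kp(pa, pb, transport)
        da <- phase_diffusivity(pa, transport)
        db <- phase_diffusivity(pb, transport)
        sa <- width[j, i] * contact_area / w_cell
        if (pa == pb) {
          p <- series_permeability(ti / 2, da, ti2 / 2, db, kp)
          type <- paste0(pa, "_", pb)
        } else {
          p <- lc_perm("vertical", pa, pb, da, db, ti / 2, ti2 / 2, kp)
          type <- "lipid_corneocyte"
        }
        add(cid(i, j), cid(i + 1, j), p, sa, kp, "vertical", type)
      }
    }
  }

  n_sc <- nrow(comps)
  # viable epidermis chain
  nve <- length(stack$ve_widths)
  comps <- dplyr::bind_rows(comps, tibble::tibble(
    name = paste0("ve_", seq_len(nve)), group = "ve",
    volume = stack$ve_widths * contact_area, is_mass = FALSE))
  # dermis chain
  ndm <- length(stack$dm_widths)
  comps <- dplyr::bind_rows(comps, tibble::tibble(
    name = paste0("dermis_", seq_len(ndm)), group = "dermis",
    volume = stack$dm_widths * contact_area, is_mass = FALSE))
  ve_id <- n_sc + seq_len(nve)
  dm_id <- n_sc + nve + seq_len(ndm)

  # SC bottom lipid layer -> first VE cell (per segment)
  tl <- thick_s[nstr]
  for (j in seq_len(nseg)) {
    kp <- 1 / transport$kp_lipid_ve
    p <- interface_permeability(tl / 2, transport$diff_lipid,
                                stack$ve_widths[1] / 2, transport$diff_ve, kp)
    add(cid(nstr, j), ve_id[1], p, width[j, nstr] * contact_area / w_cell,
        kp, "vertical", "lipid_ve")
  }
  # VE internal
  if (nve > 1) {
    for (k in seq_len(nve - 1)) {
      p <- series_permeability(stack$ve_widths[k] / 2, transport$diff_ve,
                               stack$ve_widths[k + 1] / 2, transport$diff_ve, 1)
      add(ve_id[k], ve_id[k + 1], p, contact_area, 1, "vertical", "ve_ve")
    }
  }
  # VE -> dermis
  kp_vd <- 1 / transport$kp_ve_dermis
  p <- interface_permeability(stack$ve_widths[nve] / 2, transport$diff_ve,
                              stack$dm_widths[1] / 2, transport$diff_dermis,
                              kp_vd)
  add(ve_id[nve], dm_id[1], p, contact_area, kp_vd, "vertical", "ve_dermis")
  # dermis internal
  if (ndm > 1) {
    for (k in seq_len(ndm - 1)) {
      p <- series_permeability(stack$dm_widths[k] / 2, transport$diff_dermis,
                               stack$dm_widths[k + 1] / 2,
                               transport$diff_dermis, 1)
      add(dm_id[k], dm_id[k + 1], p, contact_area, 1, "vertical",
          "dermis_dermis")
    }
  }

  links <- dplyr::bind_rows(links)
  list(
    comps = comps,
    links = links,
    top_cells = tibble::tibble(
      id = cid(1L, seq_len(nseg)),
      area = width[, 1] * contact_area / w_cell,
      half_thickness = thick_s[1] / 2),
    bottom_cell = dm_id[ndm],
    n_sc = n_sc
  )
}

#' Effective (homogenised) stratum corneum permeability
#'
#' Diagnostic: solves the steady-state flux network of the SC alone with a
#' unit concentration drop between the top and bottom lipid layers and
#' returns the effective permeability `flux / (area * dC)` (m/s). Useful for
#' closed-form limit checks and for reporting how the brick-and-mortar
#' geometry obstructs transport.
#'
#' @inheritParams assemble_flux_network
#' @return effective SC permeability (m/s).
#' @export
homogenized_sc_resistance <- function(stack, transport,
                                      contact_area = cm2_to_m2(0.64)) {
  net <- assemble_flux_network(stack, transport, contact_area)
  sc_ids <- seq_len(net$n_sc)
  nseg <- stack$sc$n_segments
  nstr <- stack$sc$n_strata
  top <- seq_len(nseg)
  bottom <- (nstr - 1L) * nseg + seq_len(nseg)
  sc_links <- net$links[net$links$from %in% sc_ids & net$links$to %in% sc_ids, ]
  pinned <- stats::setNames(c(rep(1, length(top)), rep(0, length(bottom))),
                            c(top, bottom))
  conc <- network_steady_state(net$comps[sc_ids, ], sc_links, pinned)
  flux <- network_boundary_flux(sc_links, conc, top)
  flux / (contact_area * 1)
}
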