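#' Cumulative receptor amount per diffusion area
#'
#' The primary Franz-cell readout: receptor content plus everything removed
#' in sampling aliquots, normalised by the diffusion area. Invariant to the
#' sampling schedule (removed mass is added back), hence non-decreasing.
#'
#' @param result a `franz_simulation`.
#' @param area diffusion area (m^2); defaults to the experiment's.
#' @return tibble with `time_h` and `q_ug_per_cm2`.
#' @export
cumulative_per_area <- function(result, area = NULL) {
  stopifnot(inherits(result, "franz_simulation"))
  if (is.null(area)) area <- result$experiment$config$diffusion_area
  check_positive(area, "area")
  tibble::tibble(
    time_h = s_to_h(result$times),
    q_ug_per_cm2 = kg_to_ug(result$cumulative_receptor) / m2_to_cm2(area)
  )
}

#' Steady-state flux and lag time from a cumulative-permeation series
#'
#' Ordinary least squares on the (pseudo-)linear late portion of the
#' cumulative amount-per-area curve: the slope is the steady-state flux and
#' the extrapolated x-intercept (`-intercept/slope`) the lag time. The lag is
#' only reported for a positive slope.
#'
#' @param q data frame with columns `time_h` and `q_ug_per_cm2`.
#' @param fit_window numeric length-2 time interval (h) to fit over; default
#'   is the last 40 % of time points with positive cumulative amount.
#' @return one-row tibble: `flux_ug_cm2_h`, `lag_h` (NA when undefined),
#'   `lag_defined`, `r_squared`, `n_points`, `window_start_h`,
#'   `window_end_h`.
#' @export
steady_state_flux_and_lag <- function(q, fit_window = NULL) {
  stopifnot(is.data.frame(q), all(c("time_h", "q_ug_per_cm2") %in% names(q)))
  q <- q[order(q$time_h), ]
  if (is.null(fit_window)) {
    pos <- q$time_h[q$q_ug_per_cm2 > 0]
    if (length(pos) < 3) {
      fit_window <- range(q$time_h)
    } else {
      fit_window <- c(pos[ceiling(0.6 * length(pos))], max(pos))
    }
  }
  sel <- q$time_h >= fit_window[1] - 1e-9 & q$time_h <= fit_window[2] + 1e-9
  if (sum(sel) < 3) {
    stop("need at least 3 points inside the fit window", call. = FALSE)
  }
  fit <- stats::lm(q_ug_per_cm2 ~ time_h, data = q[sel, ])
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact lines fit perfectly
  lag_ok <- is.finite(slope) && slope > 0
  tibble::tibble(
    flux_ug_cm2_h = slope,
    lag_h = if (lag_ok) -intercept / slope else NA_real_,
    lag_defined = lag_ok,
    r_squared = r2,
    n_points = sum(sel),
    window_start_h = fit_window[1],
    window_end_h = fit_window[2]
  )
}

#' Permeability coefficient from steady-state flux
#'
#' `kp = flux / donor concentration`, in cm/h.
#'
#' @param flux_ug_cm2_h steady-state flux (ug/cm^2/h).
#' @param donor_conc_ug_ml donor concentration (ug/mL).
#' @return permeability coefficient (cm/h).
#' @export
permeability_coefficient <- function(flux_ug_cm2_h, donor_conc_ug_ml) {
  check_positive(flux_ug_cm2_h, "flux_ug_cm2_h", allow_zero = TRUE)
  check_positive(donor_conc_ug_ml, "donor_conc_ug_ml")
  # ug/mL == ug/cm^3, so flux/conc is cm/h directly
  flux_ug_cm2_h / donor_conc_ug_ml
}

#' Drug deposition per wet skin-layer mass
#'
#' Converts a drug amount in a layer to the experimentally reported unit,
#' ug drug per mg of layer tissue.
#'
#' @param amount_ug drug amount in the layer (ug).
#' @param volume_cm3 layer volume (cm^3).
#' @param density_g_cm3 layer density (g/cm^3).
#' @return deposition (ug/mg).
#' @export
deposition_per_mass <- function(amount_ug, volume_cm3, density_g_cm3 = 1) {
  check_positive(amount_ug, "amount_ug", allow_zero = TRUE)
  check_positive(volume_cm3, "volume_cm3")
  check_positive(density_g_cm3, "density_g_cm3")
  amount_ug / (volume_cm3 * density_g_cm3 * 1000)
}

#' Skin-layer drug accumulation of a permeation simulation
#'
#' Terminal (or any-time) drug deposition in the epidermis or dermis,
#' normalised per layer mass. Forceps separation of permeation specimens
#' leaves the stratum corneum attached to the epidermis, so the epidermis
#' aggregates SC + viable epidermis by default.
#'
#' @param result an ivpt `franz_simulation`.
#' @param layer `"epidermis"` or `"dermis"`.
#' @param density_g_cm3 tissue density (g/cm^3).
#' @param include_sc_in_epidermis aggregate the SC with the viable epidermis.
#' @param at_time_h report time (h); defaults to end of run.
#' @return deposition (ug/mg).
#' @export
layer_accumulation <- function(result, layer = c("epidermis", "dermis"),
                               density_g_cm3 = 1,
                               include_sc_in_epidermis = TRUE,
                               at_time_h = NULL) {
  stopifnot(inherits(result, "franz_simulation"))
  if (result$mode != "ivpt") {
    stop("layer accumulation requires an ivpt simulation", call. = FALSE)
  }
  layer <- match.arg(layer)
  i <- if (is.null(at_time_h)) length(result$times) else
    which.min(abs(result$times - h_to_s(at_time_h)))
  stack <- result$experiment$barrier$stack
  area_cm2 <- m2_to_cm2(result$experiment$config$diffusion_area)
  if (layer == "epidermis") {
    groups <- if (include_sc_in_epidermis) {
      c("sc_lipid", "sc_corneocyte", "ve")
    } else {
      "ve"
    }
    thick_cm <- (stack$geometry$ve_thickness +
                   if (include_sc_in_epidermis) stack$geometry$sc_thickness
                   else 0) * 100
  } else {
    groups <- "dermis"
    thick_cm <- stack$dermis_thickness * 100
  }
  sel <- result$comps$group %in% groups
  amount_ug <- kg_to_ug(sum(result$amounts[i, sel]))
  deposition_per_mass(amount_ug, area_cm2 * thick_cm, density_g_cm3)
}

#' Percentage recovery of the applied dose
#'
#' `100 (donor + receptor + sum(layers)) / dose`, the experimental
#' mass-balance check.
#'
#' @param donor_residual residual drug in the donor (any consistent unit).
#' @param receptor_total receptor content plus sampled aliquots.
#' @param layer_amounts numeric vector of barrier/skin layer amounts.
#' @param dose applied dose (same unit).
#' @return recovery (%).
#' @export
recovery_percent <- function(donor_residual, receptor_total,
                             layer_amounts = numeric(), dose) {
  check_positive(donor_residual, "donor_residual", allow_zero = TRUE)
  check_positive(receptor_total, "receptor_total", allow_zero = TRUE)
  check_positive(layer_amounts, "layer_amounts", allow_zero = TRUE)
  check_positive(dose, "dose")
  100 * (donor_residual + receptor_total + sum(layer_amounts)) / dose
}

#' Classical one-way ANOVA across groups
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return one-row tibble: `f_stat`, `p_value`, `df_between`, `df_within`.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 ||
      any(vapply(groups, length, integer(1)) < 2)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  values <- unlist(groups)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  df_b <- length(groups) - 1L
  df_w <- length(values) - length(groups)
  tab <- stats::anova(stats::lm(values ~ fac))
  f <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  if (!is.finite(f)) {
    # degenerate: no variance anywhere -> no evidence of a difference
    if (tab$`Sum Sq`[1] < .Machine$double.eps * sum(values^2 + 1)) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0
    }
  }
  tibble::tibble(f_stat = f, p_value = p, df_between = df_b, df_within = df_w)
}

#' Per-timepoint one-way ANOVA between two replicate datasets
#'
#' Applies [oneway_anova()] at each shared time point to the per-replicate
#' cumulative amounts (or per-interval fluxes) of two groups, flagging
#' p < 0.05.
#'
#' @param dataset_a,dataset_b `franz_dataset` objects (or tibbles with
#'   `replicate`, `time_h`, `q_ug_per_cm2`) on identical time grids.
#' @param quantity `"cumulative"` amounts (default) or per-interval `"flux"`.
#' @param alpha significance level for the flag.
#' @return tibble with `time_h`, `f_stat`, `p_value`, `significant`.
#' @export
compare_groups_per_timepoint <- function(dataset_a, dataset_b,
                                         quantity = c("cumulative", "flux"),
                                         alpha = 0.05) {
  quantity <- match.arg(quantity)
  pa <- dataset_permeation(dataset_a)
  pb <- dataset_permeation(dataset_b)
  if (any(vapply(list(pa, pb), function(p)
    length(unique(table(p$replicate))) != 1, logical(1)))) {
    stop("replicates must share a common time grid", call. = FALSE)
  }
  ta <- sort(unique(pa$time_h)); tb <- sort(unique(pb$time_h))
  if (length(ta) != length(tb) || any(abs(ta - tb) > 1e-9)) {
    stop("datasets are on different time grids", call. = FALSE)
  }
  if (min(table(pa$replicate)) < 1 || length(unique(pa$replicate)) < 2 ||
      length(unique(pb$replicate)) < 2) {
    stop("need >= 2 replicates per group", call. = FALSE)
  }
  value_of <- function(p) {
    p <- p[order(p$replicate, p$time_h), ]
    if (quantity == "flux") {
      p <- dplyr::group_by(p, .data$replicate)
      p <- dplyr::mutate(p, value = c(NA_real_,
                                      diff(.data$q_ug_per_cm2) /
                                        diff(.data$time_h)))
      dplyr::ungroup(p)
    } else {
      dplyr::mutate(p, value = .data$q_ug_per_cm2)
    }
  }
  va <- value_of(pa); vb <- value_of(pb)
  purrr::map_dfr(ta, function(t) {
    ga <- va$value[abs(va$time_h - t) < 1e-9]
    gb <- vb$value[abs(vb$time_h - t) < 1e-9]
    if (anyNA(c(ga, gb))) {
      return(tibble::tibble(time_h = t, f_stat = NA_real_,
                            p_value = NA_real_, significant = NA))
    }
    res <- oneway_anova(list(ga, gb))
    tibble::tibble(time_h = t, f_stat = res$f_stat, p_value = res$p_value,
                   significant = res$p_value < alpha)
  })
}
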