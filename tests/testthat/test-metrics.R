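test_that("cumulative per area normalises the receptor ledger", {
  # 1 ug/mL in 4.7 mL over 0.64 cm^2, nothing sampled
  fake <- structure(
    list(times = c(0, 3600),
         amounts = matrix(c(0, 0, 0, 4.7e-9), 2, 2),
         comps = tibble::tibble(name = c("veh", "receptor"),
                                group = c("vehicle_cont", "receptor"),
                                volume = c(1e-6, 4.7e-6),
                                is_mass = c(FALSE, FALSE)),
         removed = tibble::tibble(time = numeric(), mass_removed = numeric()),
         cumulative_receptor = c(0, 4.7e-9),
         receptor_index = 2L,
         experiment = list(config = list(diffusion_area = 0.64e-4)),
         mode = "ivrt",
         settings = list(receptor_mode = "finite", n_states = 2)),
    class = "franz_simulation")
  q <- cumulative_per_area(fake)
  expect_equal(q$q_ug_per_cm2, c(0, 7.34375))
  expect_error(cumulative_per_area(fake, area = 0), "area")
})

test_that("sampling does not distort the cumulative ledger in sink regimes", {
  # far from receptor equilibrium the ledger telescopes: with and without
  # sampling events the cumulative amount agrees closely
  ex1 <- fast_ivrt("solution", duration_h = 4, times_h = c(1, 2, 3))
  ex1$vehicle$conc_cont[] <- ex1$vehicle$conc_cont * 0.01
  ex2 <- fast_ivrt("solution", duration_h = 4, times_h = numeric(0))
  ex2$vehicle$conc_cont[] <- ex2$vehicle$conc_cont * 0.01
  q1 <- final_q(run_ivrt(ex1))
  q2 <- final_q(run_ivrt(ex2))
  expect_equal(q1, q2, tolerance = 0.02)
})

test_that("flux/lag regression recovers exact and noisy lines", {
  t <- seq(10, 20, by = 1)
  q <- tibble::tibble(time_h = t, q_ug_per_cm2 = 2 * (t - 5))
  fit <- steady_state_flux_and_lag(q, fit_window = c(10, 20))
  expect_equal(fit$flux_ug_cm2_h, 2)
  expect_equal(fit$lag_h, 5)
  expect_equal(fit$r_squared, 1)
  # flat series: zero flux, lag undefined but flagged
  qf <- tibble::tibble(time_h = t, q_ug_per_cm2 = rep(3, length(t)))
  ff <- steady_state_flux_and_lag(qf, fit_window = c(10, 20))
  expect_equal(ff$flux_ug_cm2_h, 0)
  expect_false(ff$lag_defined)
  expect_true(is.na(ff$lag_h))
  # Monte-Carlo: noisy known generator, estimates unbiased within 3 SE
  set.seed(99)
  est <- t(replicate(300, {
    qn <- tibble::tibble(time_h = t,
                         q_ug_per_cm2 = 2 * (t - 5) + rnorm(length(t), 0, 0.1))
    unlist(steady_state_flux_and_lag(qn, c(10, 20))[c("flux_ug_cm2_h",
                                                      "lag_h")])
  }))
  se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - 2), 3 * se[1])
  expect_lt(abs(mean(est[, 2]) - 5), 3 * se[2])
  expect_error(steady_state_flux_and_lag(q, fit_window = c(19, 20)),
               "3 points")
})

test_that("flux and lag transform exactly under a time-unit change", {
  t <- seq(6, 30, by = 2)
  q <- tibble::tibble(time_h = t, q_ug_per_cm2 = 1.3 * (t - 4) + sin(t) * 0.2)
  f_h <- steady_state_flux_and_lag(q, fit_window = c(6, 30))
  q_min <- tibble::tibble(time_h = t * 60, q_ug_per_cm2 = q$q_ug_per_cm2)
  f_min <- steady_state_flux_and_lag(q_min, fit_window = c(360, 1800))
  expect_equal(f_min$flux_ug_cm2_h, f_h$flux_ug_cm2_h / 60, tolerance = 1e-12)
  expect_equal(f_min$lag_h, f_h$lag_h * 60, tolerance = 1e-9)
})

test_that("permeability coefficient and deposition arithmetic are exact", {
  expect_equal(permeability_coefficient(2, 2120), 9.434e-4, tolerance = 1e-4)
  expect_equal(permeability_coefficient(0, 2120), 0)
  expect_equal(permeability_coefficient(4, 2120),
               2 * permeability_coefficient(2, 2120))
  expect_error(permeability_coefficient(2, 0), "donor")
  # 1.79 ug in 0.64 cm^2 x 56 um at 1 g/cm^3 (3.584 mg of tissue)
  expect_equal(deposition_per_mass(1.79, 0.64 * 56e-4, 1), 0.4994,
               tolerance = 1e-4)
  expect_equal(deposition_per_mass(0, 1, 1), 0)
  expect_equal(deposition_per_mass(1, 1, 2), deposition_per_mass(1, 1, 1) / 2)
})

test_that("recovery percentage reproduces the experimental ledger", {
  expect_equal(recovery_percent(1000, 200, c(40, 10), 1250), 100)
  expect_equal(recovery_percent(900, 200, c(40, 10), 1250), 92)
  expect_equal(recovery_percent(625, 625, numeric(), 1250), 100)
  expect_error(recovery_percent(1, 1, 1, 0), "dose")
})

test_that("simulator results close their own recovery ledger", {
  s <- run_ivpt(fast_ivpt("ointment"))
  mb <- mass_balance_report(s)
  rec <- recovery_percent(mb$donor_residual_ug,
                          mb$receptor_ug + mb$sampled_ug,
                          mb$barrier_ug, mb$dose_ug)
  expect_lt(abs(rec - 100), 1e-4)
  # epidermis aggregation switches with the SC flag
  dep_with <- layer_accumulation(s, "epidermis", include_sc_in_epidermis = TRUE)
  dep_without <- layer_accumulation(s, "epidermis",
                                    include_sc_in_epidermis = FALSE)
  expect_gt(dep_with, 0)
  expect_true(dep_with != dep_without)
  expect_equal(layer_accumulation(s, "dermis", density_g_cm3 = 2),
               layer_accumulation(s, "dermis") / 2)
  expect_error(layer_accumulation(run_ivrt(fast_ivrt("cream")), "dermis"),
               "ivpt")
})

test_that("one-way ANOVA matches its classical identities", {
  # identical groups: no between-group variance at all
  res <- oneway_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res$f_stat, 0)
  expect_equal(res$p_value, 1)
  # hand-computed three-group case: MSB = 3, MSW = 1
  res3 <- oneway_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res3$f_stat, 3)
  expect_identical(res3$df_between, 2L)
  expect_identical(res3$df_within, 6L)
  expect_equal(res3$p_value, 1 - stats::pf(3, 2, 6))
  # F = t^2 identity for two groups, to near machine precision
  set.seed(123)
  for (i in 1:100) {
    a <- rnorm(5); b <- rnorm(5, mean = runif(1, -2, 2))
    f <- oneway_anova(list(a, b))$f_stat
    t2 <- stats::t.test(a, b, var.equal = TRUE)$statistic^2
    expect_equal(f, unname(t2), tolerance = 1e-10)
  }
  expect_error(oneway_anova(list(1:3)), "2 groups")
  expect_error(oneway_anova(list(1, 1:3)), "2 values")
})

test_that("per-timepoint comparison flags real offsets and nothing else", {
  base <- tidyr::expand_grid(replicate = 1:5, time_h = c(6, 12, 24))
  set.seed(21)
  da <- franz_dataset(dplyr::mutate(base,
                                    q_ug_per_cm2 = time_h + rnorm(15, 0, 1)))
  # dataset against itself: no between-group signal beyond round-off
  self <- compare_groups_per_timepoint(da, da)
  expect_true(all(self$f_stat < 1e-12))
  expect_true(all(self$p_value > 1 - 1e-9))
  # a 3-pooled-SD offset at one time point is flagged nearly always
  hits <- 0L
  n_rep <- 20L
  for (seed in seq_len(n_rep)) {
    set.seed(seed)
    qa <- dplyr::mutate(base, q_ug_per_cm2 = 10 + rnorm(15, 0, 1))
    qb <- dplyr::mutate(base, q_ug_per_cm2 = 10 + rnorm(15, 0, 1) +
                          ifelse(time_h == 12, 3, 0))
    cmp <- compare_groups_per_timepoint(franz_dataset(qa), franz_dataset(qb))
    if (cmp$significant[cmp$time_h == 12]) hits <- hits + 1L
  }
  expect_gte(hits, round(0.9 * n_rep))
  # mismatched grids and single replicates are rejected
  db <- franz_dataset(dplyr::mutate(tidyr::expand_grid(replicate = 1:5,
                                                       time_h = c(6, 12, 30)),
                                    q_ug_per_cm2 = 1))
  expect_error(compare_groups_per_timepoint(da, db), "grids")
  d1 <- franz_dataset(tibble::tibble(replicate = 1, time_h = c(6, 12, 24),
                                     q_ug_per_cm2 = 1:3))
  expect_error(compare_groups_per_timepoint(da, d1), "replicates")
})
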