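test_that("state fractions are Boltzmann populations", {
  # full symmetry: all states equal at every concentration
  tm0 <- thermo_model(c("A", "B", "C"), dg0 = c(B = 0, C = 0),
                      m = c(B = 0, C = 0))
  fr <- state_fractions(tm0, c(0, 1, 5))
  expect_true(all(abs(fr$fraction - 1 / 3) < 1e-12))

  # two-state landmark: half-populated at the midpoint
  tm2 <- thermo_model(c("U", "F"), dg0 = c(F = -5.2), m = c(F = 5.2 / 2.06))
  p <- state_fractions(tm2, 2.06)
  expect_equal(p$fraction[p$state == "F"], 0.5, tolerance = 1e-9)

  # three-state model equals an independent Boltzmann-sum oracle
  tm3 <- thermo_model(c("U", "I", "F"), dg0 = c(I = -5.6, F = -8.3),
                      m = c(I = 3.0, F = 4.15))
  for (conc in c(0, 0.7, 1.9, 3.3, 6)) {
    got <- state_fractions(tm3, conc)$fraction
    ref <- oracle_fractions(c(0, -5.6, -8.3), c(0, 3.0, 4.15), conc)
    expect_equal(got, unname(ref), tolerance = 1e-12)
  }
})

test_that("fractions stay on the simplex and the intermediate is non-monotone", {
  tm3 <- thermo_model(c("U", "I", "F"), dg0 = c(I = -5.6, F = -8.3),
                      m = c(I = 3.0, F = 4.15))
  conc <- seq(0, 7, by = 0.1)
  fr <- tidyr::pivot_wider(state_fractions(tm3, conc),
                           names_from = "state", values_from = "fraction")
  expect_true(all(abs(rowSums(fr[, c("U", "I", "F")]) - 1) < 1e-12))
  expect_true(all(as.matrix(fr[, -1]) >= 0))
  # U rises monotonically (least denaturant-sensitive ordering)
  expect_true(all(diff(fr$U) > 0))
  # intermediate rises then falls because its m lies between U's and F's
  i_peak <- which.max(fr$I)
  expect_gt(i_peak, 1)
  expect_lt(i_peak, length(conc))
  expect_gt(fr$I[i_peak], fr$I[1])
  expect_gt(fr$I[i_peak], fr$I[length(conc)])
})

test_that("midpoints follow the closed form and degenerate cases signal", {
  tm2 <- thermo_model(c("U", "F"), dg0 = c(F = -5.2), m = c(F = 5.2 / 2.06))
  expect_equal(midpoint(tm2, c("U", "F")), 2.06, tolerance = 1e-9)
  # the two states are equally populated at the returned midpoint
  withr::with_seed(41, {
    for (i in 1:10) {
      dg <- runif(1, -9, -1); mm <- runif(1, 1, 5)
      tm <- thermo_model(c("U", "F"), dg0 = c(F = dg), m = c(F = mm))
      ch <- midpoint(tm, c("U", "F"))
      p <- state_fractions(tm, ch)
      expect_equal(p$fraction[1], p$fraction[2], tolerance = 1e-9)
    }
  })
  tm_zero <- thermo_model(c("U", "F"), dg0 = c(F = 0), m = c(F = 2))
  expect_equal(midpoint(tm_zero, c("U", "F")), 0)
  tm_flat <- thermo_model(c("U", "F"), dg0 = c(F = -3), m = c(F = 0))
  expect_error(midpoint(tm_flat, c("U", "F")), "no midpoint")
})

test_that("free-energy differences from fractions are log-ratios and antisymmetric", {
  expect_equal(delta_g_from_fractions(0.5, 0.5), 0)
  expect_equal(delta_g_from_fractions(0.6, 0.4), log(0.6 / 0.4))
  expect_equal(delta_g_from_fractions(0.6, 0.4), 0.405, tolerance = 2e-3)
  withr::with_seed(42, {
    p <- runif(10, 0.05, 0.95); q <- runif(10, 0.05, 0.95)
    expect_equal(delta_g_from_fractions(p, q),
                 -delta_g_from_fractions(q, p))
  })
  expect_error(delta_g_from_fractions(0, 0.5), "unbounded")
})

test_that("a noiseless titration is recovered exactly and relabeling is equivariant", {
  tm3 <- thermo_model(c("U", "I", "F"), dg0 = c(I = -5.6, F = -8.3),
                      m = c(I = 3.0, F = 4.15))
  conc <- seq(0, 6, length.out = 16)
  series <- make_titration_dataset(tm3, conc, noise_sd = 0, seed = 1)
  fit <- fit_titration(series)
  expect_equal(unname(fit$model$dg0[-1]), c(-5.6, -8.3), tolerance = 1e-4)
  expect_equal(unname(fit$model$m[-1]), c(3.0, 4.15), tolerance = 1e-4)

  # relabeling the non-reference states permutes the estimates
  fit_swapped <- fit_titration(series, states = c("U", "F", "I"))
  expect_equal(unname(fit_swapped$model$dg0["I"]),
               unname(fit$model$dg0["I"]), tolerance = 1e-4)
  expect_equal(unname(fit_swapped$model$dg0["F"]),
               unname(fit$model$dg0["F"]), tolerance = 1e-4)
})

test_that("fitting refuses under-determined designs and flags weak states", {
  tm2 <- thermo_model(c("U", "F"), dg0 = c(F = -5.2), m = c(F = 2.5))
  single <- make_titration_dataset(tm2, 1.0, noise_sd = 0, seed = 1)
  expect_error(fit_titration(single), "concentrations")

  # an intermediate that never exceeds 10% anywhere is weakly identified
  tm_weak <- thermo_model(c("U", "I", "F"), dg0 = c(I = 2.5, F = -8),
                          m = c(I = 2, F = 4))
  series <- make_titration_dataset(tm_weak, seq(0, 6, length.out = 16),
                                   noise_sd = 0.01, seed = 2)
  fit <- fit_titration(series)
  expect_true("I" %in% fit$weakly_identified)
})

test_that("a two-state fit to three-state data leaves structured residuals", {
  tm3 <- thermo_model(c("U", "I", "F"), dg0 = c(I = -5.6, F = -8.3),
                      m = c(I = 3.0, F = 4.15))
  conc <- seq(0, 6, length.out = 16)
  # a high-precision series makes the lumped-state mismatch visible
  series3 <- make_titration_dataset(tm3, conc, noise_sd = 0.003, seed = 3)
  # lump the intermediate with the unfolded state: the lumped fraction
  # keeps the intermediate hump, which no two-state curve can produce
  series2 <- series3 |>
    dplyr::mutate(state = ifelse(.data$state == "F", "F", "U")) |>
    dplyr::group_by(.data$conc_m, .data$state) |>
    dplyr::summarise(fraction = sum(.data$fraction), sd = 0.003,
                     .groups = "drop")
  fit2 <- fit_titration(series2, states = c("U", "F"))
  # chi-square per df far exceeds 1: the two-state model misses the shape
  expect_gt(fit2$chisq / fit2$df, 3)
  # and the lack of fit is structured: residuals run in signed stretches
  pred <- state_fractions(fit2$model, conc)
  obs_f <- series2[series2$state == "F", ]
  res <- obs_f$fraction - pred$fraction[pred$state == "F"]
  runs <- rle(as.vector(sign(res)))
  expect_lt(length(runs$lengths), 0.6 * length(res))
})

test_that("bootstrap intervals bracket the point estimates", {
  tm2 <- thermo_model(c("U", "F"), dg0 = c(F = -5.2), m = c(F = 2.5))
  series <- make_titration_dataset(tm2, seq(0, 5, length.out = 12),
                                   noise_sd = 0.02, seed = 4)
  fit <- fit_titration(series, n_boot = 50, seed = 5)
  expect_true(all(fit$estimates$conf_low <= fit$estimates$estimate + 1e-6))
  expect_true(all(fit$estimates$conf_high >= fit$estimates$estimate - 1e-6))
})
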