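test_that("markov_model validates its inputs and finds the stationary vector", {
  t2 <- matrix(c(0.9, 0.1, 0.05, 0.95), 2, byrow = TRUE)
  m <- markov_model(t2, efficiencies = c(0.2, 0.8))
  expect_equal(as.vector(m$populations %*% m$t_matrix), m$populations,
               tolerance = 1e-9)
  expect_equal(m$populations, c(1, 2) / 3, tolerance = 1e-9)
  expect_error(markov_model(matrix(c(0.5, 0.4, 0.1, 0.9), 2, byrow = TRUE),
                            efficiencies = c(0.2, 0.8)), "row-stochastic")
  expect_error(markov_model(t2), "exactly one")
  expect_error(markov_model(t2, efficiencies = c(0.2, 0.8), rescale = 0))
})

test_that("a one-state simulation is pure shot noise", {
  m1 <- markov_model(matrix(1), efficiencies = 0.5)
  sim <- simulate_photons(m1, fret_setup(),
                          sim_config(photon_rate = 1e5, burst_duration_s = 1e-3,
                                     n_bursts = 100, seed = 51))
  de <- sim$photons[sim$photons$excitation == "donor_pulse", ]
  frac_a <- mean(de$channel == "acceptor")
  n <- nrow(de)
  expect_equal(frac_a, 0.5, tolerance = 3 * sqrt(0.25 / n) / 0.5)
})

test_that("one-state burst efficiencies obey the binomial shot-noise law", {
  for (n in c(25, 50, 100)) {
    sim <- make_burst_dataset(tibble::tibble(mean_e = 0.5, weight = 1),
                              n_bursts = 3000, size_meanlog = log(n),
                              size_sdlog = 0, seed = 52 + n)
    b <- burst_metrics(detect_bursts(sim$photons, threshold = n), fret_setup())
    v <- var(b$e)
    expect_equal(v, 0.5 * 0.5 / n, tolerance = 0.1)
  }
})

test_that("slow exchange gives one peak per state, fast exchange the weighted mean", {
  t2 <- matrix(c(0.995, 0.005, 0.005, 0.995), 2, byrow = TRUE)
  # slow: dwell = lag*rescale/0.005 = 0.45 s >> 1 ms burst
  slow <- markov_model(t2, efficiencies = c(0.2, 0.8), lag_ns = 10, rescale = 225000)
  h_slow <- predict_histogram(slow, cfg = sim_config(n_bursts = 400, seed = 53))
  td <- tidy(h_slow)
  # two separated modes at the state efficiencies
  lo <- td[td$bin_mid < 0.5, ]; hi <- td[td$bin_mid >= 0.5, ]
  expect_lt(abs(lo$bin_mid[which.max(lo$count)] - 0.2), 0.06)
  expect_lt(abs(hi$bin_mid[which.max(hi$count)] - 0.8), 0.06)
  # the valley between them is deep: genuinely bimodal
  valley <- min(td$count[td$bin_mid > 0.35 & td$bin_mid < 0.65])
  expect_lt(valley, 0.25 * max(td$count))

  # fast: dwell = 0.45 us << 1 ms burst; unimodal at the population mean
  fast <- markov_model(t2, efficiencies = c(0.2, 0.8), lag_ns = 10, rescale = 22.5)
  h_fast <- predict_histogram(fast, cfg = sim_config(n_bursts = 400, seed = 53))
  tdf <- tidy(h_fast)
  expect_lt(abs(tdf$bin_mid[which.max(tdf$count)] - 0.5), 0.05)
  expect_lt(max(abs(h_fast$bursts$e - 0.5)), 0.3)
})

test_that("identity dynamics reproduce the static mixture and rescale leaves slow peaks put", {
  t_id <- diag(2)
  msm_id <- markov_model(t_id, efficiencies = c(0.25, 0.85),
                         populations = NULL)
  # identity transition matrix: stationary vector defaults to uniform
  h_id <- predict_histogram(msm_id, cfg = sim_config(n_bursts = 500, seed = 54))
  frac_low <- sum(h_id$bursts$e < 0.55) / h_id$n_bursts
  expect_equal(frac_low, 0.5, tolerance = 0.08)

  t2 <- matrix(c(0.999, 0.001, 0.001, 0.999), 2, byrow = TRUE)
  h_a <- predict_histogram(markov_model(t2, efficiencies = c(0.25, 0.85),
                                        rescale = 225000),
                           cfg = sim_config(n_bursts = 300, seed = 55))
  h_b <- predict_histogram(markov_model(t2, efficiencies = c(0.25, 0.85),
                                        rescale = 450000),
                           cfg = sim_config(n_bursts = 300, seed = 55))
  mode_of <- function(h) { td <- tidy(h); td$bin_mid[which.max(td$count)] }
  expect_equal(mode_of(h_a), mode_of(h_b), tolerance = 0.05)
})

test_that("photon simulation is reproducible under a fixed seed", {
  m <- markov_model(matrix(c(0.99, 0.01, 0.02, 0.98), 2, byrow = TRUE),
                    efficiencies = c(0.3, 0.7))
  s1 <- simulate_photons(m, cfg = sim_config(n_bursts = 20, seed = 7))
  s2 <- simulate_photons(m, cfg = sim_config(n_bursts = 20, seed = 7))
  expect_identical(s1$photons, s2$photons)
  s3 <- simulate_photons(m, cfg = sim_config(n_bursts = 20, seed = 8))
  expect_false(identical(s1$photons, s3$photons))
})

test_that("estimate_msm recovers a known transition matrix and detailed balance", {
  mk <- make_msm(3, dwell_ns = c(100, 200, 300), lag_ns = 10,
                 n_traj = 5, traj_length = 20000, seed = 56)
  est <- estimate_msm(mk$trajectories)
  expect_lt(max(abs(est$t_matrix - mk$model$t_matrix)), 0.02)
  # symmetrised counts enforce detailed balance
  flux <- est$populations * est$t_matrix
  expect_equal(flux, t(flux), tolerance = 1e-9)
})

test_that("estimate_msm handles degenerate and disconnected inputs", {
  expect_equal(estimate_msm(rep(1L, 50))$t_matrix, matrix(1, 1, 1))
  expect_error(estimate_msm(list()), "no trajectory")
  two_blocks <- list(c(1, 2, 1, 2, 1, 2), c(3, 4, 3, 4, 3, 4))
  expect_warning(est <- estimate_msm(two_blocks), "reducible")
  expect_equal(est$t_matrix[1:2, 3:4], matrix(0, 2, 2))
})

test_that("estimation closes the loop on simulated ground-truth state paths", {
  t2 <- matrix(c(0.95, 0.05, 0.1, 0.9), 2, byrow = TRUE)
  m <- markov_model(t2, efficiencies = c(0.2, 0.8))
  sim <- simulate_photons(m, cfg = sim_config(n_bursts = 60,
                                              burst_duration_s = 5e-3,
                                              seed = 57))
  est <- estimate_msm(sim$state_paths)
  expect_lt(max(abs(est$t_matrix - t2)), 0.03)
})

test_that("histogram comparison is a bounded symmetric distance", {
  sim <- make_burst_dataset(tibble::tibble(mean_e = 0.4, weight = 1),
                            n_bursts = 500, seed = 58)
  h <- sim$photons |> detect_bursts() |> build_histogram()
  expect_equal(compare_histograms(h, h), 0)

  mk_hist <- function(e) {
    b <- tibble::tibble(burst_id = 1, start_s = 0, stop_s = 1e-3,
                        n_d = round(100 * (1 - e)), n_a = round(100 * e),
                        n_aa = 100)
    build_histogram(b, s_window = c(0, 1))
  }
  expect_equal(compare_histograms(mk_hist(0.1), mk_hist(0.9)), 2)

  # bootstrap self-distance of a large histogram is a small baseline
  sim2 <- make_burst_dataset(tibble::tibble(mean_e = 0.4, weight = 1),
                             n_bursts = 500, seed = 59)
  h2 <- sim2$photons |> detect_bursts() |> build_histogram()
  d <- compare_histograms(h, h2)
  expect_lt(d, 0.3)
  expect_equal(d, compare_histograms(h2, h))

  h_rebinned <- build_histogram(h$bursts, bins = 25)
  expect_error(compare_histograms(h, h_rebinned), "binning")
})

test_that("markov model bundles round-trip through JSON", {
  m <- markov_model(matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
                    lag_ns = 10, rescale = 225, distances = c(6.5, 3.9))
  f <- withr::local_tempfile(fileext = ".json")
  write_markov_model(m, f)
  m2 <- read_markov_model(f)
  expect_equal(m2$t_matrix, m$t_matrix, ignore_attr = TRUE)
  expect_equal(m2$distances, m$distances)
  expect_equal(m2$rescale, m$rescale)
})
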