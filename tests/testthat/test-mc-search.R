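test_that("pairs starting within the capture radius meet at time zero", {
  # tiny segment: a substantial fraction of uniform pairs start captured
  cfg <- mc_search_config(L_um = 0.1, N_occupancy = 2, n_reps = 1000,
                          max_time_s = 50, seed = 41)
  r <- simulate_search_time(cfg)
  p0 <- mean(r$times$time_s == 0)
  # P(initial ring separation <= a) = 2a / segment
  p_true <- 2 * 0.01 / 0.05
  expect_lt(abs(p0 - p_true), 4 * sqrt(p_true * (1 - p_true) / 1000))
})

test_that("identical deterministic motion never meets and trips the censor error", {
  cfg <- mc_search_config(L_um = 2, N_occupancy = 2, D = 0,
                          drift_v = 0.127, n_reps = 50, max_time_s = 2,
                          seed = 42)
  expect_error(simulate_search_time(cfg), "censored")
})

test_that("simulated mean search time agrees with the ring MFPT oracle", {
  cfg <- mc_search_config(L_um = 2, N_occupancy = 2, n_reps = 400,
                          seed = 43)
  r <- simulate_search_time(cfg)
  an <- analytic_pair_mfpt(1, 0.026, 0.01)
  expect_lt(abs(mean(r$times$time_s) / an - 1), 0.15)
})

test_that("the analytic MFPT has the right value, scaling and limits", {
  expect_equal(analytic_pair_mfpt(1, 0.026), 1 / (24 * 0.026),
               tolerance = 1e-12)
  expect_equal(analytic_pair_mfpt(2, 0.026) / analytic_pair_mfpt(1, 0.026),
               4, tolerance = 1e-12)
  expect_lt(analytic_pair_mfpt(1, 1e6), 1e-6)
  # capture radius shortens the effective ring
  expect_equal(analytic_pair_mfpt(1, 0.026, 0.01),
               0.98^2 / (24 * 0.026), tolerance = 1e-12)
})

test_that("common advection leaves capture times exactly invariant on matched seeds", {
  base <- mc_search_config(L_um = 4, N_occupancy = 10, n_reps = 400,
                           seed = 44)
  fe <- flow_effect(base, c(0, 0.127))
  expect_equal(fe$ratio_vs_zero, c(1, 1), tolerance = 1e-12)
  # exact invariance at the level of individual replicates
  with_v <- mc_search_config(L_um = 4, N_occupancy = 10, drift_v = 0.127,
                             n_reps = 400, seed = 44)
  expect_identical(simulate_search_time(base)$times$time_s,
                   simulate_search_time(with_v)$times$time_s)
})

test_that("single-walker advection accelerates the search at high drift", {
  cfg0 <- mc_search_config(L_um = 1, N_occupancy = 2, dt = 1e-4,
                           advection = "single", n_reps = 300,
                           max_time_s = 50, seed = 45)
  cfgv <- mc_search_config(L_um = 1, N_occupancy = 2, dt = 1e-4,
                           drift_v = 10, advection = "single",
                           n_reps = 300, max_time_s = 50, seed = 45)
  m0 <- simulate_search_time(cfg0)$median_s
  mv <- simulate_search_time(cfgv)$median_s
  expect_lt(mv / m0, 0.8)
})

test_that("configurations with equal segment length are equivalent", {
  a <- mc_search_config(L_um = 4, N_occupancy = 4, n_reps = 200, seed = 46)
  b <- mc_search_config(L_um = 2, N_occupancy = 2, n_reps = 200, seed = 46)
  expect_identical(simulate_search_time(a)$times,
                   simulate_search_time(b)$times)
})

test_that("occupancy sweep declines monotonically on lambda DNA", {
  cfg <- mc_search_config(n_reps = 300, seed = 47)
  sw <- occupancy_sweep(cfg, c(10, 50, 100))
  expect_true(all(diff(sw$median_s) < 0))
  expect_equal(sw$segment_um, lambda_L_um / c(10, 50, 100))
})

test_that("heavy censoring flags the median as unreliable", {
  # horizon well below the typical search time
  cfg <- mc_search_config(L_um = 2, N_occupancy = 2, n_reps = 200,
                          max_time_s = 0.1, seed = 48)
  r <- simulate_search_time(cfg)
  expect_true(r$median_flagged)
  expect_true(any(r$times$censored))
})

test_that("halving dt barely moves the median (matched-path check)", {
  cfg <- mc_search_config(L_um = 2, N_occupancy = 2, n_reps = 2000,
                          seed = 49)
  chk <- dt_convergence_check(cfg)
  expect_lt(abs(chk$median_ratio - 1), 0.05)
})
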