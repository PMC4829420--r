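test_that("with all motion terms off every trajectory is constant", {
  cfg <- make_cfg(D = 0, drift_v = 0, localization_sigma_um = 0,
                  n_particles = 5, mean_dwell_s = Inf, max_time_s = 2,
                  seed = 1)
  tr <- simulate_trajectories(cfg, lambda_sub())
  per <- dplyr::summarise(dplyr::group_by(tr, particle_id),
                          spread = diff(range(position_um)))
  expect_true(all(per$spread == 0))
})

test_that("deterministic drift advances 0.01 um per 0.1 s step, then sticks at the tip", {
  cfg <- make_cfg(D = 0, drift_v = 0.1, dt = 0.1, localization_sigma_um = 0,
                  n_particles = 3, mean_dwell_s = Inf, max_time_s = 200,
                  seed = 2)
  sub <- lambda_sub(anchoring = "single_tethered")
  tr <- simulate_trajectories(cfg, sub, flow_on = TRUE)
  for (id in unique(tr$particle_id)) {
    x <- tr$position_um[tr$particle_id == id]
    steps <- diff(x)
    pre_tip <- which(x < sub$length_um)
    if (length(pre_tip) > 1) {
      expect_equal(steps[head(pre_tip, -1)],
                   rep(0.01, length(pre_tip) - 1), tolerance = 1e-12)
    }
    # once at the tip, it stays
    at_tip <- which(x == sub$length_um)
    if (length(at_tip)) {
      expect_true(all(x[min(at_tip):length(x)] == sub$length_um))
    }
  }
  # drift must not apply without flow or on double-tethered DNA
  tr_noflow <- simulate_trajectories(cfg, sub, flow_on = FALSE)
  expect_equal(diff(range(tr_noflow$position_um[tr_noflow$particle_id == 1])),
               0)
})

test_that("per-step displacement variance matches 2*D*dt", {
  cfg <- make_cfg(D = 0.026, dt = 0.01, localization_sigma_um = 0,
                  n_particles = 1, mean_dwell_s = Inf, max_time_s = 100,
                  seed = 3)
  tr <- simulate_trajectories(cfg, lambda_sub())
  expect_gte(nrow(tr), 1e4)
  v <- var(diff(tr$position_um))
  expect_lt(abs(v / (2 * 0.026 * 0.01) - 1), 0.05)
})

test_that("identical seeds reproduce identical trajectory sets bit for bit", {
  cfg <- make_cfg(D = 0.026, n_particles = 10, seed = 99)
  sub <- lambda_sub(barriers_bp = c(10000, 30000))
  t1 <- simulate_trajectories(cfg, sub)
  t2 <- simulate_trajectories(cfg, sub)
  expect_identical(t1, t2)
  t3 <- simulate_trajectories(make_cfg(D = 0.026, n_particles = 10,
                                       seed = 100), sub)
  expect_false(identical(t1$position_um, t3$position_um))
})

test_that("reflecting barriers confine every position to the enclosing segment", {
  sub <- lambda_sub(barriers_bp = c(15000, 35000))
  cfg <- make_cfg(D = 0.1, localization_sigma_um = 0, n_particles = 30,
                  mean_dwell_s = Inf, max_time_s = 20, seed = 4)
  tr <- simulate_trajectories(cfg, sub)
  edges <- c(0, sub$barriers_um, sub$length_um)
  for (id in unique(tr$particle_id)) {
    x <- tr$position_um[tr$particle_id == id]
    seg <- findInterval(x[1], edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    expect_true(all(x >= edges[seg] & x <= edges[seg + 1]))
  }
})

test_that("ensemble MSD matches 2*D*tau + 2*sigma^2 for barrier-free, drift-free motion", {
  D <- 0.05
  sigma <- 0.03
  cfg <- make_cfg(D = D, localization_sigma_um = sigma, n_particles = 250,
                  mean_dwell_s = Inf, max_time_s = 3, seed = 5)
  tr <- simulate_trajectories(cfg, lambda_sub())
  em <- compute_msd_ensemble(tr, max_lags = 10)
  expected <- 2 * D * em$lag_s + 2 * sigma^2
  # each lag within 3 standard errors (chi-squared spread of squared steps)
  se <- sqrt(2 / em$n_pairs) * expected
  expect_true(all(abs(em$msd_um2 - expected) < 3 * se))
})

test_that("dwell times are exponential with the configured mean", {
  cfg <- make_cfg(D = 0.01, n_particles = 400, mean_dwell_s = 2,
                  max_time_s = 60, seed = 6)
  tr <- simulate_trajectories(cfg, lambda_sub())
  dw <- dwell_summary(tr)
  expect_equal(attr(dw, "n"), 400)
  # sample mean within 4 SE of the configured mean
  expect_lt(abs(mean(dw$duration_s) - 2), 4 * 2 / sqrt(400))
})

test_that("tip behavior 'unbind' truncates tracks at the free tip", {
  cfg <- make_cfg(D = 0, drift_v = 0.2, dt = 0.1, localization_sigma_um = 0,
                  n_particles = 5, mean_dwell_s = Inf, max_time_s = 500,
                  tip_behavior = "unbind", seed = 7)
  sub <- lambda_sub(anchoring = "single_tethered")
  tr <- simulate_trajectories(cfg, sub, flow_on = TRUE)
  expect_true(all(tr$position_um < sub$length_um))
  # deterministic drift: every track ends just short of the tip
  last <- dplyr::summarise(dplyr::group_by(tr, particle_id),
                           x_end = dplyr::last(position_um))
  expect_true(all(last$x_end > sub$length_um - 0.021))
})
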