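test_that("noiseless first-order traces are recovered to high precision", {
  tr <- simulate_fret_trace(0.005, 1.2, 0.25, seq(0, 1200, 6))
  fit <- fit_first_order(tr)
  expect_equal(fit$k_per_s, 0.005, tolerance = 1e-4)
  expect_equal(fit$amplitude, 1.2, tolerance = 1e-4)
  expect_equal(fit$baseline, 0.25, tolerance = 1e-4)
  expect_lt(fit$rmse, 1e-8)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "k_per_s"], 0.005, tolerance = 1e-4)
})

test_that("a constant trace yields k = 0 with an unidentifiability flag", {
  tr <- tibble::tibble(time_s = seq(0, 100, 5), value = 0.4)
  expect_warning(fit <- fit_first_order(tr), "constant")
  expect_equal(fit$k_per_s, 0)
  expect_true(fit$flagged)
})

test_that("the dead-time option shifts the fitted time origin", {
  tt <- seq(20, 1000, 10)  # first reading after mixing dead time
  mu <- 0.2 + 0.9 * (1 - exp(-0.004 * (tt - 17.5)))
  fit <- fit_first_order(tibble::tibble(time_s = tt, value = mu),
                         dead_time = 17.5)
  expect_equal(fit$k_per_s, 0.004, tolerance = 1e-6)
})

test_that("rates spanning two decades are recovered within 10% at 2% noise", {
  for (s in 1:10) {
    set.seed(s)
    k <- 10^stats::runif(1, -4, -2)
    tt <- seq(0, 5 / k, length.out = 100)
    tr <- simulate_fret_trace(k, 1, 0.2, tt, noise_sd = 0.02, seed = s)
    fit <- fit_first_order(tr)
    expect_lt(abs(fit$k_per_s / k - 1), 0.1)
  }
})

test_that("exponential-fit residuals on generator data are mean zero", {
  means <- sapply(1:100, function(s) {
    tr <- simulate_fret_trace(0.005, 1, 0.2, seq(0, 1000, 10),
                              noise_sd = 0.02, seed = 1000 + s)
    fit <- fit_first_order(tr)
    mean(fit$data$value - fit$data$fitted)
  })
  expect_gt(stats::t.test(means)$p.value, 0.01)
})

test_that("assembly rate scales linearly with protein concentration", {
  # generator traces with k proportional to concentration (25 vs 50 nM)
  k25 <- 0.002
  fits <- lapply(c(1, 2), function(mult) {
    tr <- simulate_fret_trace(k25 * mult, 1, 0.2,
                              seq(0, 2500, length.out = 120),
                              noise_sd = 0.02, seed = 70 + mult)
    fit_first_order(tr)
  })
  expect_lt(abs(fits[[2]]$k_per_s / fits[[1]]$k_per_s / 2 - 1), 0.1)
})

test_that("noiseless competition curves are recovered to high precision", {
  conc <- c(0, 10^seq(-1, 3, length.out = 12))
  fit <- fit_competition(simulate_competition_curve(10, 2, conc))
  expect_equal(fit$ic50, 10, tolerance = 1e-6)
  expect_equal(fit$hill, 2, tolerance = 1e-6)
  expect_equal(tidy(fit)$estimate, c(10, 2), tolerance = 1e-6)
})

test_that("unit-scale invariance: IC50 scales with concentrations, hill does not", {
  conc <- c(0, 10^seq(-1, 3, length.out = 12))
  cc <- simulate_competition_curve(10, 1.6, conc, noise_sd = 0.02,
                                   seed = 71)
  f1 <- fit_competition(cc)
  for (c_scale in c(0.001, 50)) {
    cc2 <- cc
    cc2$concentration <- cc2$concentration * c_scale
    f2 <- fit_competition(cc2)
    expect_equal(f2$ic50 / c_scale, f1$ic50, tolerance = 1e-6)
    expect_equal(f2$hill, f1$hill, tolerance = 1e-6)
  }
})

test_that("hill = 1 data fit back to hill = 1 within 10% at 2% noise", {
  conc <- c(0, 10^seq(-1.5, 1.5, length.out = 12)) * 10
  fit <- fit_competition(simulate_competition_curve(10, 1, conc,
                                                    noise_sd = 0.02,
                                                    seed = 72))
  expect_lt(abs(fit$hill - 1), 0.1)
})

test_that("degenerate competition curves take the error/warning paths", {
  # flat curve: no signal at all, unidentifiable
  flat <- tibble::tibble(concentration = c(0, 1, 3, 10, 30),
                         fraction_bound = rep(1, 5))
  expect_error(fit_competition(flat), "unidentifiable")
  # weak competitor: real decline that never reaches 0.5
  weak <- simulate_competition_curve(1000, 1, c(0, 1, 3, 10, 30, 100))
  expect_warning(fit <- fit_competition(weak), "0.5")
  expect_gt(fit$ic50, 100)
})

test_that("protomer capacity gates assembly by footprint", {
  expect_equal(protomer_capacity(60), 4L)
  expect_equal(protomer_capacity(150), 10L)
  expect_equal(protomer_capacity(14), 0L)
  expect_equal(protomer_capacity(c(60, 150, 600), 15), c(4L, 10L, 40L))
  expect_error(protomer_capacity(-10), "positive")
})

test_that("rate-vs-length summary reports fold changes and saturation", {
  tab <- rate_vs_length_summary(
    tibble::tibble(length_bp = c(60, 200), k_per_s = c(1e-4, 5e-3)))
  expect_equal(tab$fold_vs_first[2], 50)

  flat <- rate_vs_length_summary(
    tibble::tibble(length_bp = c(100, 200, 400),
                   k_per_s = c(2e-3, 2.05e-3, 1.98e-3)))
  expect_true(all(flat$saturated[-1]))

  rise <- rate_vs_length_summary(
    tibble::tibble(length_bp = c(60, 200, 600),
                   k_per_s = c(1e-4, 5e-3, 5.1e-3)))
  expect_false(rise$saturated[2])  # still rising 60 -> 200
  expect_true(rise$saturated[3])   # flat 200 -> 600
  expect_equal(rise$protomers, c(4L, 13L, 40L))
})
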