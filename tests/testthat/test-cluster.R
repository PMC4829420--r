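test_that("unit intensity is the robust center of the singles distribution", {
  expect_equal(unit_intensity(rep(120, 30))$unit_au, 120)
  draws <- simulate_cluster_intensities(rep(1, 500), 100, 0.3,
                                        seed = 51)$intensity_au
  u <- unit_intensity(draws)
  expect_lt(abs(u$unit_au / 100 - 1), 0.05)
  expect_false(u$bimodal)
  expect_error(unit_intensity(rnorm(10, 100, 10)), "20")
})

test_that("a singles+doubles mixture triggers the bimodality warning", {
  set.seed(52)
  mixed <- c(rnorm(300, 100, 12), rnorm(200, 200, 15))
  expect_warning(u <- unit_intensity(mixed), "bimodal")
  expect_true(u$bimodal)
})

test_that("intensity-to-count conversion rounds and floors correctly", {
  expect_equal(cluster_sizes(100, 100), 1L)
  expect_equal(cluster_sizes(820, 100), 8L)
  expect_equal(cluster_sizes(30, 100), 1L)  # floor at one molecule
  expect_warning(out <- cluster_sizes(c(100, -5, 300), 100), "skipped")
  expect_equal(out, c(1L, 3L))
})

test_that("size-8 clusters are recovered with mean size in [7, 9]", {
  intens <- simulate_cluster_intensities(rep(8, 300), 100, 0.3,
                                         seed = 53)$intensity_au
  unit <- unit_intensity(simulate_cluster_intensities(
    rep(1, 500), 100, 0.3, seed = 54)$intensity_au)
  sizes <- cluster_sizes(intens, unit)
  expect_gte(mean(sizes), 7)
  expect_lte(mean(sizes), 9)
})

test_that("counts are invariant under joint intensity rescaling", {
  intens <- simulate_cluster_intensities(2:40 %/% 5 + 1, 100, 0.25,
                                         seed = 55)$intensity_au
  for (c_scale in c(0.01, 3.7, 1e4)) {
    expect_identical(cluster_sizes(intens, 100),
                     cluster_sizes(intens * c_scale, 100 * c_scale))
  }
})

test_that("size-independent growth shows no rate-size correlation", {
  recs <- simulate_cluster_growth(100, t_max_s = 60, dt = 2,
                                  addition_rate = 0.15,
                                  rate_size_exponent = 0,
                                  start_size = rep(1:5, each = 20),
                                  seed = 56)
  gm <- growth_and_mobility(recs)
  expect_lt(abs(gm$rate_vs_size$rho), 0.2)
  # positive control: size-promoted growth shows a clear correlation
  recs2 <- simulate_cluster_growth(100, t_max_s = 60, dt = 2,
                                   addition_rate = 0.05,
                                   rate_size_exponent = 1,
                                   start_size = rep(1:5, each = 20),
                                   seed = 57)
  gm2 <- growth_and_mobility(recs2)
  expect_gt(gm2$rate_vs_size$rho, 0.5)
})

test_that("mobility falls with cluster size as D ~ 1/n", {
  mk <- function(sz, seed) {
    simulate_cluster_growth(50, t_max_s = 60, dt = 0.5, addition_rate = 0,
                            D_mono = 0.026, size_exponent = 1,
                            start_size = sz, unit_cv = 0, seed = seed)
  }
  recs <- dplyr::bind_rows(
    mk(1, 58),
    dplyr::mutate(mk(2, 59), cluster_id = cluster_id + 50L))
  gm <- growth_and_mobility(recs)
  d1 <- gm$D_vs_size$median_D_um2_per_s[gm$D_vs_size$size == 1]
  d2 <- gm$D_vs_size$median_D_um2_per_s[gm$D_vs_size$size == 2]
  expect_lt(abs(d2 / d1 - 0.5), 0.2)
})

test_that("a static cluster has zero addition rate", {
  recs <- simulate_cluster_growth(1, t_max_s = 30, dt = 1,
                                  addition_rate = 0, seed = 60)
  gm <- growth_and_mobility(recs)
  expect_equal(gm$per_cluster$addition_rate_per_s, 0)
})

test_that("colocalization fraction matches its closed forms", {
  expect_equal(colocalization_fraction(c(1, 2, 3), c(1, 2, 3), 0.2)$fraction,
               1)
  expect_equal(colocalization_fraction(c(1, 2), c(10, 20), 0.2)$fraction, 0)
  expect_error(colocalization_fraction(numeric(), 1:3, 0.2), "non-empty")

  # uniform marks at density rho: expected hit fraction 1 - exp(-2*rho*thr)
  set.seed(61)
  rho <- 2
  thr <- 0.2
  b <- runif(rho * 50, 0, 50)
  a <- runif(200, 5, 45)
  p_true <- 1 - exp(-2 * rho * thr)
  frac <- colocalization_fraction(a, b, thr)$fraction
  expect_lt(abs(frac - p_true), 3 * sqrt(p_true * (1 - p_true) / 200))
})
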