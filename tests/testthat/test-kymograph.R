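empty_trajs <- function() {
  tr <- tibble::tibble(particle_id = integer(), frame = integer(),
                       time_s = numeric(), position_um = numeric(),
                       intensity_au = numeric())
  class(tr) <- c("trajectory_set", class(tr))
  tr
}

test_that("an empty field renders to pure background", {
  st <- render_kymograph(empty_trajs(), pixel_size_um = 0.1,
                         background = 20, n_pixels = 2000, seed = 1)
  m <- mean(st$frames)
  # Poisson mean-of-2000 pixels: SE = sqrt(20/2000)
  expect_lt(abs(m - 20), 4 * sqrt(20 / 2000))
})

test_that("an immobile particle peaks at the same pixel in every frame", {
  tr <- manual_traj(times = (0:19) * 0.1, positions = rep(3.14, 20),
                    substrate = dna_substrate(length_bp = 25000))
  st <- render_kymograph(tr, pixel_size_um = 0.1, psf_sigma_um = 0.2,
                         photons_per_frame = 2e4, background = 2, seed = 2)
  km <- as_kymograph(st)
  peaks <- apply(km, 1, which.max)
  expect_true(all(peaks == peaks[1]))
  expect_equal(peaks[1], 32)  # 3.14 um / 0.1 um per px
})

test_that("Gaussian centroids recover the input positions within 0.2 px", {
  pos <- 0.68 + 0.002 * (0:49)
  tr <- manual_traj(times = (0:49) * 0.1, positions = pos,
                    substrate = dna_substrate(length_bp = 5000))
  st <- render_kymograph(tr, pixel_size_um = 0.1, psf_sigma_um = 0.2,
                         photons_per_frame = 1e4, background = 5, seed = 3)
  km <- as_kymograph(st)
  # independent centroid refit: background-subtracted first moment
  cents <- apply(km, 1, function(row) {
    r <- row - 5
    sum(r * (seq_along(r) - 0.5)) / sum(r)
  })
  expect_true(all(abs(cents - pos / 0.1) < 0.2))
})

test_that("total photon count scales linearly with photons_per_frame", {
  tr <- manual_traj(times = (0:29) * 0.1, positions = rep(5, 30),
                    substrate = dna_substrate(length_bp = 40000))
  lo <- render_kymograph(tr, photons_per_frame = 2000, background = 0,
                         seed = 4)
  hi <- render_kymograph(tr, photons_per_frame = 10000, background = 0,
                         seed = 5)
  tot_lo <- sum(lo$frames)
  tot_hi <- sum(hi$frames)
  ratio <- tot_hi / tot_lo
  # Poisson relative error on each total ~ 1/sqrt(total)
  rel_se <- sqrt(1 / tot_lo + 1 / tot_hi)
  expect_lt(abs(ratio - 5), 5 * 4 * rel_se)
})

test_that("image stacks survive the TIFF + JSON round trip", {
  tr <- manual_traj(times = (0:9) * 0.5, positions = rep(1.5, 10),
                    substrate = dna_substrate(length_bp = 10000))
  st <- render_kymograph(tr, pixel_size_um = 0.1, photons_per_frame = 3000,
                         background = 3, seed = 6)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(st, path)
  back <- read_image_stack(path)
  expect_equal(back$frames, st$frames)
  expect_equal(back$pixel_size_um, 0.1)
  expect_equal(back$frame_interval_s, 0.5)
})

test_that("renderer and container reject invalid geometry", {
  tr <- manual_traj(times = 0:5, positions = rep(1, 6))
  expect_error(render_kymograph(tr, pixel_size_um = 0), "pixel_size_um")
  expect_error(image_stack(array(-1, c(1, 1, 4)), 0.1, 1), "non-negative")
  expect_error(image_stack(matrix(0, 2, 2), 0.1, 1), "3D")
})
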