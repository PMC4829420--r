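#' Image stacks
#'
#' Minimal container for synthetic multi-frame grayscale image data: a 3D
#' array of non-negative photon counts indexed `(frame, row, column)` plus
#' the pixel size and frame interval. Kymograph stacks have one row per
#' frame; [as_kymograph()] collapses them to a frames-by-pixels matrix.
#'
#' @param frames 3D numeric array `(frame, row, column)` of counts >= 0.
#' @param pixel_size_um Pixel size, um (> 0).
#' @param frame_interval_s Frame interval, s (> 0).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size_um, frame_interval_s) {
  if (!(is.array(frames) && length(dim(frames)) == 3)) {
    abort("`frames` must be a 3D array (frame, row, column)")
  }
  if (any(frames < 0)) abort("image counts must be non-negative")
  check_number(pixel_size_um, "pixel_size_um", lower = 1e-12)
  check_number(frame_interval_s, "frame_interval_s", lower = 1e-12)
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<image_stack> %d frame(s) of %d x %d px (%.3f um/px, %.3f s/frame)\n",
    d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' @rdname image_stack
#' @param stack An `image_stack` whose frames have a single row.
#' @export
as_kymograph <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  if (d[2] != 1) abort("as_kymograph() expects single-row frames")
  matrix(stack$frames, nrow = d[1], ncol = d[3])
}

#' Render trajectories into a synthetic kymograph stack
#'
#' Produces the raw-data analogue of a TIRF kymograph: for each frame, every
#' particle contributes a diffraction-limited 1D Gaussian profile along the
#' DNA axis carrying `photons_per_frame` expected photons, profiles are
#' summed, a uniform background expectation is added, and independent
#' Poisson shot noise is applied per pixel. Expected per-pixel photon counts
#' use the exact Gaussian integral over each pixel, so total signal is
#' conserved regardless of pixel size.
#'
#' @param trajs A `trajectory_set` tibble (positions in um).
#' @param pixel_size_um Pixel size along the DNA axis, um.
#' @param psf_sigma_um Gaussian PSF width, um (> 0).
#' @param photons_per_frame Expected photons emitted per particle per frame
#'   (> 0).
#' @param background Expected background photons per pixel per frame (>= 0).
#' @param n_pixels Number of pixels; defaults to covering the substrate (or
#'   the data extent) plus a 3-sigma margin.
#' @param seed Optional integer seed for the shot noise.
#'
#' @return An [image_stack()] with one single-row frame per trajectory frame.
#' @examples
#' cfg <- sim_config(D = 0.026, n_particles = 2, max_time_s = 2, seed = 3)
#' trajs <- simulate_trajectories(cfg, dna_substrate())
#' stack <- render_kymograph(trajs, seed = 4)
#' dim(stack$frames)
#' @export
render_kymograph <- function(trajs,
                             pixel_size_um = 0.1,
                             psf_sigma_um = 0.2,
                             photons_per_frame = 5000,
                             background = 5,
                             n_pixels = NULL,
                             seed = NULL) {
  check_number(pixel_size_um, "pixel_size_um", lower = 1e-12)
  check_number(psf_sigma_um, "psf_sigma_um", lower = 1e-12)
  check_number(photons_per_frame, "photons_per_frame", lower = 1e-12)
  check_number(background, "background", lower = 0)
  substrate <- attr(trajs, "substrate")
  if (is.null(n_pixels)) {
    extent <- if (!is.null(substrate)) {
      substrate$length_um
    } else if (nrow(trajs)) {
      max(trajs$position_um, 0)
    } else {
      1
    }
    n_pixels <- ceiling((extent + 3 * psf_sigma_um) / pixel_size_um)
  }
  check_number(n_pixels, "n_pixels", lower = 1)
  frames_idx <- if (nrow(trajs)) sort(unique(trajs$frame)) else 0L
  n_frames <- length(frames_idx)
  frame_interval <- if (nrow(trajs) && length(unique(trajs$time_s)) > 1) {
    stats::median(diff(sort(unique(trajs$time_s))))
  } else {
    1
  }
  seed_rng(seed)
  edges <- (0:n_pixels) * pixel_size_um
  arr <- array(0, dim = c(n_frames, 1, n_pixels))
  for (f in seq_len(n_frames)) {
    mu <- rep(background, n_pixels)
    pos <- trajs$position_um[trajs$frame == frames_idx[f]]
    for (p in pos) {
      frac <- diff(pnorm(edges, mean = p, sd = psf_sigma_um))
      mu <- mu + photons_per_frame * frac
    }
    arr[f, 1, ] <- rpois(n_pixels, mu)
  }
  image_stack(arr, pixel_size_um, frame_interval)
}

#' Write / read an image stack as TIFF plus JSON sidecar
#'
#' Frames are written as 16-bit grayscale TIFF pages; pixel size and frame
#' interval go to `<path>.json`. Counts above 65535 are clipped with a
#' warning.
#'
#' @param stack An [image_stack()].
#' @param path TIFF file path; the sidecar is `paste0(path, ".json")`.
#' @return `write_image_stack()` returns `path` invisibly;
#'   `read_image_stack()` returns an [image_stack()].
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  mx <- 65535
  if (any(stack$frames > mx)) {
    warn("counts above 65535 clipped for 16-bit TIFF output")
  }
  pages <- lapply(seq_len(d[1]), function(f) {
    m <- matrix(stack$frames[f, , ], nrow = d[2], ncol = d[3])
    pmin(m, mx) / mx
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um,
         frame_interval_s = stack$frame_interval_s),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  arr <- array(0, dim = c(length(pages), d2[1], d2[2]))
  for (f in seq_along(pages)) arr[f, , ] <- round(pages[[f]] * 65535)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  image_stack(arr, meta$pixel_size_um, meta$frame_interval_s)
}
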