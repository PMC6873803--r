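#' Optics and camera configuration
#'
#' Describes the TIRF optics and EMCCD camera used to render trajectories
#' into an image stack. Defaults follow a typical ImFCS setup: a 24 um
#' camera pixel behind a 100x objective gives a 0.24 um pixel in the sample
#' plane, and the PSF 1/e^2 radius is taken equal to one pixel (0.24 um) --
#' a package choice, since calibrated values are instrument-specific.
#'
#' @param omega0 PSF 1/e^2 radius in the sample plane (um).
#' @param a pixel side in the sample plane (um).
#' @param roi integer \code{c(H, W)} region of interest in pixels.
#' @param exposure frame exposure time (s); also the frame time (no dead
#'   time).
#' @param n_frames number of frames to render (>= 2).
#' @param counts_per_molecule_per_frame expected photons a molecule
#'   contributes per frame when fully inside a pixel's acceptance.
#' @param background_per_pixel_per_frame expected background photons.
#' @param em_gain EM amplification factor; 1 disables the gamma gain stage
#'   so counts are pure shot noise.
#' @param read_noise_sd Gaussian read noise standard deviation (counts).
#' @param seed integer seed for the photon-noise draws; \code{NULL} leaves
#'   the RNG state untouched.
#' @return an object of class \code{optics_config}.
#' @export
optics_config <- function(omega0 = 0.24, a = 0.24, roi = c(16L, 16L),
                          exposure = 0.003, n_frames = 5000,
                          counts_per_molecule_per_frame = 300,
                          background_per_pixel_per_frame = 10,
                          em_gain = 1, read_noise_sd = 0, seed = NULL) {
  chk_pos(omega0, "omega0")
  chk_pos(a, "a")
  if (length(roi) != 2L || any(roi < 1) || any(roi != round(roi)))
    stop("'roi' must be two positive integers (H, W)", call. = FALSE)
  chk_pos(exposure, "exposure")
  chk_count(n_frames, "n_frames", min = 2L)
  chk_num(counts_per_molecule_per_frame, "counts_per_molecule_per_frame",
          lo = 0)
  chk_num(background_per_pixel_per_frame, "background_per_pixel_per_frame",
          lo = 0)
  chk_num(em_gain, "em_gain", lo = 1)
  chk_num(read_noise_sd, "read_noise_sd", lo = 0)
  if (!is.null(seed)) seed <- chk_count(seed, "seed", min = 0L)
  structure(list(omega0 = omega0, a = a, roi = as.integer(roi),
                 exposure = exposure, n_frames = as.integer(n_frames),
                 counts_per_molecule_per_frame = counts_per_molecule_per_frame,
                 background_per_pixel_per_frame = background_per_pixel_per_frame,
                 em_gain = em_gain, read_noise_sd = read_noise_sd,
                 seed = seed),
            class = "optics_config")
}

#' Render trajectories into a camera image stack
#'
#' Images a [trajectory_set] through a Gaussian PSF onto a pixel grid with
#' an EMCCD noise cascade. Per frame, each particle deposits an expected
#' photon count equal to \code{counts_per_molecule_per_frame} times the
#' integral of the normalized 2D Gaussian PSF (1/e^2 radius \code{omega0},
#' truncated at \code{4 * omega0}) over each pixel; background is added;
#' realized counts are Poisson, then (for \code{em_gain > 1})
#' gamma-amplified (shape = photons, scale = \code{em_gain}), then Gaussian
#' read noise is added and counts are rounded to non-negative integers.
#' When the simulation step is shorter than the exposure, each frame
#' averages the deposits of \code{exposure / dt} consecutive sub-steps.
#'
#' @param traj a \code{trajectory_set}; its step \code{dt} must divide the
#'   exposure.
#' @param optics an [optics_config()].
#' @param noise logical; \code{FALSE} returns expected counts (no Poisson /
#'   gain / read noise), useful for exact tests.
#' @return an object of class \code{fcs_stack}: list with \code{counts}
#'   (array \code{n_frames x H x W}), \code{a}, \code{omega0},
#'   \code{exposure}, \code{optics}, \code{sim_config} and
#'   \code{config_hash}.
#' @export
render_stack <- function(traj, optics, noise = TRUE) {
  stopifnot(inherits(traj, "trajectory_set"),
            inherits(optics, "optics_config"))
  H <- optics$roi[1]; W <- optics$roi[2]
  ext <- max(H, W) * optics$a
  if (ext > traj$box_side)
    stop(sprintf(
      "geometry error: ROI extent %.3g um exceeds simulation box %.3g um",
      ext, traj$box_side), call. = FALSE)
  ns <- optics$exposure / traj$dt
  if (abs(ns - round(ns)) > 1e-9 || ns < 1 - 1e-9)
    stop("trajectory step interval must divide (or equal) the exposure",
         call. = FALSE)
  ns <- as.integer(round(ns))
  avail <- dim(traj$positions)[1] - 1L   # drop the initial state
  if (avail < optics$n_frames * ns)
    stop(sprintf("trajectory too short: %d samples needed, %d available",
                 optics$n_frames * ns, avail), call. = FALSE)
  # centre the ROI in the box
  x0 <- (traj$box_side - W * optics$a) / 2
  y0 <- (traj$box_side - H * optics$a) / 2
  pos <- traj$positions[-1, , , drop = FALSE]
  expected <- cpp_expected_counts(pos, optics$n_frames, ns, H, W, x0, y0,
                                  optics$a, optics$omega0,
                                  optics$counts_per_molecule_per_frame)
  expected <- expected + optics$background_per_pixel_per_frame
  if (noise) {
    if (!is.null(optics$seed)) set.seed(optics$seed)
    counts <- rpois(length(expected), expected)
    if (optics$em_gain > 1) {
      pos_idx <- counts > 0
      amplified <- numeric(length(counts))
      amplified[pos_idx] <- rgamma(sum(pos_idx), shape = counts[pos_idx],
                                   scale = optics$em_gain)
      counts <- amplified
    }
    if (optics$read_noise_sd > 0)
      counts <- counts + rnorm(length(counts), sd = optics$read_noise_sd)
    counts <- pmax(0, round(counts))
    dim(counts) <- dim(expected)
  } else {
    counts <- expected
  }
  structure(list(counts = counts, a = optics$a, omega0 = optics$omega0,
                 exposure = optics$exposure, optics = optics,
                 sim_config = traj$config,
                 config_hash = config_hash(list(sim = unclass(traj$config),
                                                optics = unclass(optics)))),
            class = "fcs_stack")
}

#' @export
print.fcs_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "fcs_stack: %d frames of %dx%d px (a = %g um, omega0 = %g um, %g ms exposure)\n",
    d[1], d[2], d[3], x$a, x$omega0, 1000 * x$exposure))
  cat(sprintf("  mean count %.2f / pixel / frame\n", mean(x$counts)))
  invisible(x)
}

#' Write an image stack as multi-page TIFF plus JSON sidecar
#'
#' Counts are written as 16-bit unsigned TIFF pages; optics metadata
#' (\code{a}, \code{omega0}, \code{exposure}, seed, config hash) goes to
#' \code{<path>.json}.
#'
#' @param stack an \code{fcs_stack}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "fcs_stack"))
  counts <- pmin(stack$counts, 65535)
  pages <- lapply(seq_len(dim(counts)[1]),
                  function(f) counts[f, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(a_um = stack$a, omega0_um = stack$omega0,
               exposure_s = stack$exposure,
               n_frames = dim(counts)[1], roi = dim(counts)[2:3],
               seed = stack$optics$seed, config_hash = stack$config_hash)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path; metadata is read from \code{<path>.json} when
#'   present, otherwise \code{a}, \code{omega0} and \code{exposure} must be
#'   supplied.
#' @param a,omega0,exposure optics metadata overrides (um, um, s).
#' @return an \code{fcs_stack} (without simulation provenance).
#' @export
read_stack <- function(path, a = NULL, omega0 = NULL, exposure = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  a <- a %||% meta$a_um
  omega0 <- omega0 %||% meta$omega0_um
  exposure <- exposure %||% meta$exposure_s
  if (is.null(a) || is.null(omega0) || is.null(exposure))
    stop("no JSON sidecar found; supply 'a', 'omega0' and 'exposure'",
         call. = FALSE)
  counts <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages)) counts[f, , ] <- pages[[f]]
  structure(list(counts = counts, a = as.numeric(a),
                 omega0 = as.numeric(omega0),
                 exposure = as.numeric(exposure), optics = NULL,
                 sim_config = NULL,
                 config_hash = meta$config_hash %||% NA_character_),
            class = "fcs_stack")
}
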