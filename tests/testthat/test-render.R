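test_that("dark emitters leave only background", {
  sim <- sim_config("free", n_particles = 10, n_steps = 200, seed = 21)
  opt <- optics_config(roi = c(8L, 8L), n_frames = 200,
                       counts_per_molecule_per_frame = 0,
                       background_per_pixel_per_frame = 5, seed = 22)
  st <- render_stack(simulate_trajectories(sim), opt)
  n <- length(st$counts)
  se <- sqrt(5 / n)
  expect_lt(abs(mean(st$counts) - 5), 3 * se)
})

test_that("a stationary emitter reproduces the analytic pixel integrals", {
  sim <- sim_config("free", box_side = 6, n_particles = 1, D_out = 0,
                    n_steps = 3, seed = 1)
  trj <- simulate_trajectories(sim)
  trj$positions[, 1, ] <- 3.05  # off pixel-centre, inside ROI
  opt <- optics_config(roi = c(16L, 16L), n_frames = 2,
                       counts_per_molecule_per_frame = 1000,
                       background_per_pixel_per_frame = 0)
  st <- render_stack(trj, opt, noise = FALSE)
  # independent quadrature: product of 1D Gaussian integrals, sd = omega0/2
  a <- 0.24; s <- 0.12; x0 <- (6 - 16 * a) / 2
  g1 <- function(lo, hi) pnorm((hi - 3.05) / s) - pnorm((lo - 3.05) / s)
  ana <- outer(1:16, 1:16, function(r, c)
    1000 * g1(x0 + (r - 1) * a, x0 + r * a) *
      g1(x0 + (c - 1) * a, x0 + c * a))
  idx <- ana > 1e-9
  expect_lt(max(abs(st$counts[1, , ][idx] - ana[idx]) / ana[idx]), 1e-6)
})

test_that("expected photons are conserved and linear in brightness", {
  sim <- sim_config("free", box_side = 6, n_particles = 4, D_out = 0.1,
                    n_steps = 20, seed = 31)
  trj <- simulate_trajectories(sim)
  # pin particles well inside the ROI so their PSF mass is fully captured
  trj$positions[, , 1] <- matrix(c(2.2, 2.8, 3.3, 3.9),
                                 nrow = dim(trj$positions)[1], ncol = 4,
                                 byrow = TRUE)
  trj$positions[, , 2] <- matrix(c(3.1, 2.4, 3.6, 2.9),
                                 nrow = dim(trj$positions)[1], ncol = 4,
                                 byrow = TRUE)
  opt <- optics_config(roi = c(16L, 16L), n_frames = 10,
                       counts_per_molecule_per_frame = 200,
                       background_per_pixel_per_frame = 2)
  st <- render_stack(trj, opt, noise = FALSE)
  per_frame <- apply(st$counts, 1, sum)
  expect_equal(per_frame, rep(4 * 200 + 16 * 16 * 2, 10),
               tolerance = 1e-6)
  # doubling the brightness doubles (mean - background)
  opt2 <- optics_config(roi = c(16L, 16L), n_frames = 10,
                        counts_per_molecule_per_frame = 400,
                        background_per_pixel_per_frame = 2)
  st2 <- render_stack(trj, opt2, noise = FALSE)
  expect_equal(mean(st2$counts) - 2, 2 * (mean(st$counts) - 2),
               tolerance = 0.01)
})

test_that("EMCCD cascade preserves the mean and em_gain = 1 stays Poisson", {
  sim <- sim_config("free", n_particles = 0 + 5, n_steps = 600, seed = 41)
  trj <- simulate_trajectories(sim)
  base <- optics_config(roi = c(8L, 8L), n_frames = 600,
                        counts_per_molecule_per_frame = 0,
                        background_per_pixel_per_frame = 20, seed = 5)
  st1 <- render_stack(trj, base)
  # pure shot noise: integer counts with var ~ mean
  expect_true(all(st1$counts == round(st1$counts)))
  expect_equal(var(as.numeric(st1$counts)) / mean(st1$counts), 1,
               tolerance = 0.05)
  gain <- optics_config(roi = c(8L, 8L), n_frames = 600,
                        counts_per_molecule_per_frame = 0,
                        background_per_pixel_per_frame = 20, em_gain = 30,
                        seed = 5)
  st2 <- render_stack(trj, gain)
  expect_equal(mean(st2$counts) / (30 * 20), 1, tolerance = 0.02)
  # gamma amplification roughly doubles the relative variance
  expect_gt(var(as.numeric(st2$counts)) / (30^2 * 20), 1.5)
})

test_that("geometry and timing preconditions are enforced", {
  sim <- sim_config("free", box_side = 3, n_particles = 2, n_steps = 50,
                    seed = 1)
  trj <- simulate_trajectories(sim)
  expect_error(render_stack(trj, optics_config(roi = c(16L, 16L),
                                               n_frames = 10)),
               "geometry")
  sim2 <- sim_config("free", n_particles = 2, n_steps = 50, dt = 0.002,
                     seed = 1)
  expect_error(render_stack(simulate_trajectories(sim2),
                            optics_config(roi = c(4L, 4L), n_frames = 10,
                                          exposure = 0.003)),
               "divide")
})

test_that("sub-step integration averages deposits within a frame", {
  # dt = exposure / 3: three sub-steps per frame; a static emitter must give
  # the same expected image as single-step rendering
  sim <- sim_config("free", box_side = 6, n_particles = 1, D_out = 0,
                    dt = 0.001, n_steps = 30, seed = 3)
  trj <- simulate_trajectories(sim)
  trj$positions[, 1, ] <- 3
  opt <- optics_config(roi = c(8L, 8L), n_frames = 10, exposure = 0.003,
                       background_per_pixel_per_frame = 0)
  st <- render_stack(trj, opt, noise = FALSE)
  sim1 <- sim_config("free", box_side = 6, n_particles = 1, D_out = 0,
                     dt = 0.003, n_steps = 10, seed = 3)
  trj1 <- simulate_trajectories(sim1)
  trj1$positions[, 1, ] <- 3
  st1 <- render_stack(trj1, opt, noise = FALSE)
  expect_equal(st$counts, st1$counts, tolerance = 1e-12)
})

test_that("TIFF + sidecar round trip preserves counts and metadata", {
  sim <- sim_config("free", n_particles = 5, n_steps = 40, seed = 51)
  opt <- optics_config(roi = c(6L, 6L), n_frames = 40, seed = 52)
  st <- render_stack(simulate_trajectories(sim), opt)
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  write_stack(st, path)
  back <- read_stack(path)
  expect_equal(back$counts, st$counts)
  expect_equal(back$a, st$a)
  expect_equal(back$omega0, st$omega0)
  expect_equal(back$exposure, st$exposure)
  expect_equal(back$config_hash, st$config_hash)
  # sidecar-less read requires explicit optics
  unlink(paste0(path, ".json"))
  expect_error(read_stack(path), "sidecar")
  back2 <- read_stack(path, a = 0.24, omega0 = 0.24, exposure = 0.003)
  expect_equal(back2$counts, st$counts)
})
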