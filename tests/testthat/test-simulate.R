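test_that("zero diffusivity gives exactly zero displacement", {
  trj <- simulate_trajectories(sim_config("free", D_out = 0,
                                          n_particles = 5, n_steps = 50,
                                          seed = 1))
  expect_equal(max(abs(apply(trj$positions, c(2, 3), diff))), 0)
})

test_that("free-mode MSD matches the Brownian closed form", {
  # time-averaged MSD(lag)/lag -> 4 D, closed form for 2D Brownian motion
  D <- 1
  trj <- simulate_trajectories(sim_config("free", box_side = 10,
                                          n_particles = 20, D_out = D,
                                          dt = 0.001, n_steps = 100000,
                                          seed = 42))
  m <- msd(trj, lags = c(1, 10, 50))
  expect_true(all(abs(m$msd_um2 / (4 * D * m$dt_s) - 1) < 0.05))
})

test_that("free-mode MSD is linear in lag", {
  trj <- simulate_trajectories(sim_config("free", n_particles = 30,
                                          D_out = 0.5, n_steps = 5000,
                                          seed = 7))
  m <- msd(trj, lags = seq(10, 500, by = 10))  # lags <= 10% of trace
  expect_gt(summary(lm(msd_um2 ~ dt_s, m))$r.squared, 0.99)
})

test_that("domain mode with D_in = D_out and open boundaries reduces to free", {
  n <- 4000
  mk <- function(mode) {
    cfg <- sim_config(mode, n_particles = 30, D_out = 1, D_in = 1,
                      P_enter = 1, P_exit = 1, domain_radius = 0.2,
                      domain_area_fraction = 0.2, dt = 0.001, n_steps = n,
                      seed = 5)
    trj <- simulate_trajectories(cfg)
    d <- sqrt(diff(trj$positions[, , 1])^2 + diff(trj$positions[, , 2])^2)
    d[d < 1]  # drop periodic-wrap jumps
  }
  ks <- suppressWarnings(ks.test(mk("domain"), mk("free")))
  expect_gt(ks$p.value, 0.01)
})

test_that("confined domain mode is sub-linear in lag at long times", {
  # hard confinement: immobile inside, particles accumulate in domains
  cfg <- sim_config("domain", n_particles = 50, D_out = 0.5, D_in = 0,
                    P_enter = 0.5, P_exit = 0.05, domain_radius = 0.3,
                    domain_area_fraction = 0.3, dt = 0.003,
                    n_steps = 20000, seed = 11)
  m <- msd(simulate_trajectories(cfg), lags = c(1, 2000))
  # apparent D at long lags clearly below short-lag apparent D
  d_short <- m$msd_um2[1] / (4 * m$dt_s[1])
  d_long <- m$msd_um2[2] / (4 * m$dt_s[2])
  expect_lt(d_long, 0.6 * d_short)
})

test_that("hop mode slows long-range transport but not local steps", {
  cfg <- sim_config("hop", n_particles = 50, D_out = 0.5, mesh_side = 1,
                    P_hop = 0.05, dt = 0.003, n_steps = 20000, seed = 13)
  m <- msd(simulate_trajectories(cfg), lags = c(1, 2000))
  expect_equal(m$msd_um2[1] / (4 * 0.5 * m$dt_s[1]), 1, tolerance = 0.1)
  expect_lt(m$msd_um2[2] / (4 * 0.5 * m$dt_s[2]), 0.7)
})

test_that("trajectories stay in the box and are seed-reproducible", {
  for (mode in c("free", "domain", "hop")) {
    cfg <- sim_config(mode, n_particles = 10, n_steps = 500, seed = 99)
    a <- simulate_trajectories(cfg)
    b <- simulate_trajectories(cfg)
    expect_identical(a$positions, b$positions)
    expect_true(all(a$positions >= 0 & a$positions < cfg$box_side))
  }
})

test_that("non-physical configurations fail naming the offending field", {
  expect_error(sim_config("free", D_out = -1), "D_out")
  expect_error(sim_config("free", dt = 0), "dt")
  expect_error(sim_config("domain", P_exit = 1.5), "P_exit")
  expect_error(sim_config("hop", mesh_side = -2), "mesh_side")
  expect_error(sim_config("free", n_steps = 0.5), "n_steps")
})
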