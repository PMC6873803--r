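test_that("self-superposition is exact and proper", {
  conf <- generate_conformers(conformer_spec(
    dihedral_model = "rotamer_sampled", n_conformers = 1, seed = 81))[[1]]
  sp <- superpose_carbons(conf, conf)
  expect_lt(sp$rmsd, 1e-12)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_equal(sp$n_matched, 16L)
  expect_false(sp$common_subset)
})

test_that("rigid motions are removed exactly", {
  ref <- generate_conformers(conformer_spec(
    dihedral_model = "continuous", n_conformers = 1, seed = 82))[[1]]
  moved <- rigid_move(ref, rotation_about(c(1, 2, 3), 73 * pi / 180),
                      c(4, -7, 2))
  expect_lt(superpose_carbons(moved, ref)$rmsd, 1e-9)
})

test_that("RMSD is invariant under rigid motions of either side", {
  set.seed(83)
  ens <- generate_conformers(conformer_spec(
    dihedral_model = "rotamer_sampled", n_conformers = 2, seed = 83))
  base <- superpose_carbons(ens[[1]], ens[[2]])$rmsd
  for (i in 1:5) {
    R <- rotation_about(rnorm(3), runif(1, 0, 2 * pi))
    sh <- rnorm(3, sd = 5)
    r1 <- superpose_carbons(rigid_move(ens[[1]], R, sh), ens[[2]])$rmsd
    r2 <- superpose_carbons(ens[[1]], rigid_move(ens[[2]], R, sh))$rmsd
    expect_lt(abs(r1 - base), 1e-9)
    expect_lt(abs(r2 - base), 1e-9)
  }
})

test_that("RMSD is symmetric between mobile and reference", {
  ens <- generate_conformers(conformer_spec(
    dihedral_model = "continuous", n_conformers = 4, seed = 84))
  for (i in 2:4) {
    ab <- superpose_carbons(ens[[1]], ens[[i]])$rmsd
    ba <- superpose_carbons(ens[[i]], ens[[1]])$rmsd
    expect_lt(abs(ab - ba), 1e-9)
  }
})

test_that("the SVD solution matches a brute-force rotation grid on toys", {
  # planar 4-atom toys: any proper 3D rotation restricted to the plane acts
  # as an in-plane rotation, possibly composed with a flip (rotation by pi
  # about an in-plane axis), so a 1-degree sweep over both branches after
  # centroid alignment bounds the true minimum
  set.seed(85)
  for (rep in 1:3) {
    ref_xyz <- cbind(matrix(rnorm(8, sd = 2), 4, 2), 0)
    mob_xyz <- cbind(matrix(rnorm(8, sd = 2), 4, 2), 0)
    fit <- superpose_carbons(toy_conformer(mob_xyz, "mob"),
                             toy_conformer(ref_xyz, "ref"))$rmsd
    pc <- sweep(mob_xyz, 2, colMeans(mob_xyz))[, 1:2]
    qc <- sweep(ref_xyz, 2, colMeans(ref_xyz))[, 1:2]
    flipped <- pc %*% diag(c(1, -1))
    grid <- sapply(seq(0, 359, by = 1) * pi / 180, function(th) {
      R2 <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
      min(sqrt(mean(rowSums((pc %*% t(R2) - qc)^2))),
          sqrt(mean(rowSums((flipped %*% t(R2) - qc)^2))))
    })
    # resolution bound: rotating by up to 0.5 deg moves each atom at most
    # r_max * sin(0.5 deg)
    bound <- max(sqrt(rowSums(pc^2))) * sin(0.5 * pi / 180)
    expect_lte(fit, min(grid) + 1e-12)
    expect_lte(min(grid) - fit, bound)
  }
})

test_that("reflections are never used even when they would fit better", {
  # a chiral 4-point set and its mirror image: proper superposition must
  # leave a residual, and the returned rotation stays proper
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1.4, 0), c(1.5, 1.4, 1.3))
  mirror <- xyz %*% diag(c(1, 1, -1))
  sp <- superpose_carbons(toy_conformer(mirror), toy_conformer(xyz))
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_gt(sp$rmsd, 0.1)
})

test_that("missing carbons fall back to the common subset or error", {
  ref <- generate_conformers(conformer_spec(n_conformers = 1))[[1]]
  mob <- ref
  mob$atoms <- mob$atoms[1:15, ]         # drop C16
  sp <- superpose_carbons(mob, ref)
  expect_equal(sp$n_matched, 15L)
  expect_true(sp$common_subset)
  tiny <- ref
  tiny$atoms <- tiny$atoms[1:2, ]
  expect_error(superpose_carbons(tiny, ref), "fewer than 2 carbon|3 matched")
  named <- ref
  named$atoms$name <- paste0("X", 1:16)  # no shared names
  expect_error(superpose_carbons(named, ref), "unmatched")
})
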