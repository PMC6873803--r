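test_that("identical conformers put all mass in the first bin", {
  ref <- generate_conformers(conformer_spec(n_conformers = 1))[[1]]
  copies <- generate_conformers(conformer_spec(n_conformers = 4))
  dens <- rmsd_density(copies, ref)
  expect_equal(dens$frequencies[1], 1)
  expect_equal(sum(dens$frequencies), 1, tolerance = 1e-12)
  expect_equal(dens$n_bins, 20L)
})

test_that("frequencies always sum to one and edges increase", {
  for (seed in c(91, 92)) {
    ens <- generate_conformers(conformer_spec(
      dihedral_model = "continuous", n_conformers = 30, seed = seed))
    ref <- generate_conformers(conformer_spec())[[1]]
    dens <- rmsd_density(ens, ref)
    expect_lt(abs(sum(dens$frequencies) - 1), 1e-12)
    expect_true(all(diff(dens$bin_edges) > 0))
    expect_length(dens$bin_edges, 21)
    expect_equal(dens$dataset_size, 30)
  }
})

test_that("frequencies equal a hand-counted histogram on a small ensemble", {
  ref <- generate_conformers(conformer_spec())[[1]]
  ens <- generate_conformers(conformer_spec(
    dihedral_model = "rotamer_sampled", n_conformers = 5, seed = 93))
  dens <- rmsd_density(ens, ref, n_bins = 4)
  # oracle: per-conformer RMSDs, binned by explicit interval comparisons
  rmsds <- vapply(ens, function(cf) superpose_carbons(cf, ref)$rmsd,
                  numeric(1))
  edges <- seq(0, max(rmsds), length.out = 5)
  counts <- integer(4)
  for (r in rmsds) {
    placed <- FALSE
    for (b in 1:4) {
      hi_ok <- if (b == 4) r <= edges[b + 1] else r < edges[b + 1]
      if (r >= edges[b] && hi_ok) {
        counts[b] <- counts[b] + 1L
        placed <- TRUE
        break
      }
    }
    expect_true(placed)
  }
  expect_equal(dens$frequencies, counts / 5)
  expect_equal(dens$bin_edges, edges)
})

test_that("a fixed bin range clamps out-of-range values into end bins", {
  ref <- generate_conformers(conformer_spec())[[1]]
  ens <- generate_conformers(conformer_spec(
    dihedral_model = "continuous", n_conformers = 10, seed = 94))
  dens <- rmsd_density(ens, ref, n_bins = 20, bin_range = c(0, 2))
  expect_equal(sum(dens$frequencies), 1, tolerance = 1e-12)
  expect_equal(dens$bin_edges[21], 2)
})

test_that("conformers that cannot superpose are excluded but counted", {
  ref <- generate_conformers(conformer_spec())[[1]]
  ens <- generate_conformers(conformer_spec(
    dihedral_model = "rotamer_sampled", n_conformers = 3, seed = 95))
  broken <- ens[[2]]
  broken$atoms <- broken$atoms[1:2, ]
  dens <- rmsd_density(c(ens[1], list(broken), ens[3]), ref)
  expect_equal(dens$dataset_size, 2)
  expect_equal(dens$n_excluded, 1)
  expect_equal(sum(dens$frequencies), 1, tolerance = 1e-12)
})

test_that("saturated and cis-kinked ensembles both span many bins", {
  ref <- generate_conformers(conformer_spec())[[1]]
  sat <- generate_conformers(conformer_spec(
    dihedral_model = "rotamer_sampled", n_conformers = 200, seed = 96))
  cis <- generate_conformers(conformer_spec(
    dihedral_model = "rotamer_sampled", n_conformers = 200,
    cis_bond_index = 9, seed = 97))
  expect_gte(sum(rmsd_density(sat, ref)$frequencies > 0), 5)
  expect_gte(sum(rmsd_density(cis, ref)$frequencies > 0), 5)
})

test_that("the closest conformer is the argmin with lexicographic ties", {
  ref <- generate_conformers(conformer_spec())[[1]]
  ens <- generate_conformers(conformer_spec(
    dihedral_model = "continuous", n_conformers = 10, seed = 98))
  hit <- closest_conformer(ens, ref)
  rmsds <- vapply(ens, function(cf) superpose_carbons(cf, ref)$rmsd,
                  numeric(1))
  expect_equal(hit$rmsd, min(rmsds))
  expect_equal(hit$source_id, ens[[which.min(rmsds)]]$source_id)
  # an exact copy of the reference wins with RMSD ~ 0
  copy <- ref
  copy$source_id <- "zz_copy"
  hit2 <- closest_conformer(c(ens, list(copy)), ref)
  expect_equal(hit2$source_id, "zz_copy")
  expect_lt(hit2$rmsd, 1e-12)
  # exact tie (identical coordinates) -> lexicographically first source_id
  c1 <- ens[[3]]
  c2 <- ens[[3]]
  c1$source_id <- "b_tie"
  c2$source_id <- "a_tie"
  hit3 <- closest_conformer(list(c1, c2), ref)
  expect_equal(hit3$source_id, "a_tie")
  expect_error(closest_conformer(list(), ref), "at least one")
})
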