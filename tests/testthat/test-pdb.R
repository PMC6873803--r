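test_that("a hand-built 16-carbon residue parses into one conformer", {
  ens <- generate_conformers(conformer_spec(
    dihedral_model = "rotamer_sampled", n_conformers = 1, seed = 71))
  lines <- c("HEADER    SYNTHETIC",
             readLines(write_pdb_conformers(ens, tempfile())), "END")
  conf <- parse_ligands(lines, "PLM", source_id = "fx")
  expect_length(conf, 1)
  expect_equal(sum(conf[[1]]$atoms$element == "C"), 16)
  expect_equal(conf[[1]]$atoms$name, paste0("C", 1:16))
  # coordinates survive the 3-decimal PDB format
  expect_lt(max(abs(as.matrix(conf[[1]]$atoms[, c("x", "y", "z")]) -
                      as.matrix(ens[[1]]$atoms[, c("x", "y", "z")]))),
            5e-4)
})

test_that("empty or non-matching input yields an empty list", {
  expect_identical(parse_ligands(character(0), "PLM"), list())
  expect_identical(parse_ligands("HEADER    NOTHING HERE", "PLM"), list())
  lines <- pdb_line(1, "C1", " ", "PAM", "A", 1, 1, 2, 3)
  expect_identical(parse_ligands(lines, "PLM"), list())
  expect_length(parse_ligands(lines, "PAM"), 1)
})

test_that("alternate locations resolve to the highest occupancy", {
  lines <- c(
    pdb_line(1, "C1", "A", "PLM", "A", 7, 1.0, 0, 0, occ = 0.6),
    pdb_line(2, "C1", "B", "PLM", "A", 7, 9.0, 0, 0, occ = 0.4),
    pdb_line(3, "C2", "B", "PLM", "A", 7, 2.0, 0, 0, occ = 0.5),
    pdb_line(4, "C2", "A", "PLM", "A", 7, 8.0, 0, 0, occ = 0.5),
    pdb_line(5, "C3", " ", "PLM", "A", 7, 3.0, 0, 0))
  conf <- parse_ligands(lines, "PLM")
  expect_length(conf, 1)
  at <- conf[[1]]$atoms
  expect_equal(at$x[at$name == "C1"], 1.0)   # higher occupancy wins
  expect_equal(at$x[at$name == "C2"], 8.0)   # tie -> altloc 'A'
  expect_equal(nrow(at), 3)
})

test_that("residues split by chain and number; malformed lines are located", {
  lines <- c(pdb_line(1, "C1", " ", "PLM", "A", 1, 0, 0, 0),
             pdb_line(2, "C2", " ", "PLM", "A", 1, 1, 0, 0),
             pdb_line(3, "C1", " ", "PLM", "B", 1, 5, 5, 5),
             pdb_line(4, "C1", " ", "PLM", "A", 2, 9, 9, 9))
  conf <- parse_ligands(lines, "PLM", source_id = "x")
  expect_length(conf, 3)
  ids <- sort(vapply(conf, `[[`, character(1), "source_id"))
  expect_identical(ids, c("x:A1", "x:A2", "x:B1"))
  bad <- lines
  substr(bad[2], 31, 38) <- "  xx.yyy"
  expect_error(parse_ligands(bad, "PLM"), "line 2")
})

test_that("elements fall back to atom-name initials when columns 77-78 blank", {
  l <- pdb_line(1, "C7", " ", "PLM", "A", 1, 0, 0, 0)
  blank <- substr(l, 1, 66)  # truncate before the element field
  conf <- parse_ligands(c(blank, pdb_line(2, "O1", " ", "PLM", "A", 1,
                                          1, 1, 1, elem = "O")), "PLM")
  expect_identical(conf[[1]]$atoms$element, c("C", "O"))
})

test_that("parsed coordinates agree with bio3d on a generated file", {
  ens <- generate_conformers(conformer_spec(
    dihedral_model = "continuous", n_conformers = 3, seed = 72))
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  write_pdb_conformers(ens, f)
  mine <- read_ligands(f, "PLM")
  pdb <- bio3d::read.pdb(f, verbose = FALSE)
  theirs <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  mine_xyz <- do.call(rbind, lapply(mine, function(cf)
    as.matrix(cf$atoms[, c("x", "y", "z")])))
  expect_equal(unname(mine_xyz), unname(theirs), tolerance = 1e-6)
})
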