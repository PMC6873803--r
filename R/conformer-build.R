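#' Specification of a synthetic acyl-chain conformer ensemble
#'
#' Describes how to build idealized n-carbon acyl chains (default 16
#' carbons, the palmitate/palmitoleate length) spanning linear-to-kinked
#' shapes. Dihedral models: \code{all_trans} (planar zig-zag),
#' \code{rotamer_sampled} (each dihedral drawn from trans 180 deg /
#' gauche +65 / gauche -65 with \code{rotamer_weights}), or
#' \code{continuous} (uniform dihedrals). Setting \code{cis_bond_index = k}
#' fixes the dihedral about the Ck-C(k+1) bond at 0 deg, emulating the
#' permanent kink of a monounsaturated (16:1-like) chain.
#'
#' @param n_carbons chain length (>= 2), default 16.
#' @param bond_length C-C bond length (Angstrom), default 1.53.
#' @param bond_angle C-C-C bond angle (degrees), default 111.5.
#' @param dihedral_model one of \code{"all_trans"}, \code{"rotamer_sampled"},
#'   \code{"continuous"}.
#' @param rotamer_weights probabilities for (trans, gauche+, gauche-).
#' @param cis_bond_index optional carbon index k (2 <= k <= n_carbons - 2);
#'   the dihedral about bond Ck-C(k+1) is fixed at 0 (cis).
#' @param n_conformers ensemble size (0 allowed).
#' @param seed integer seed; \code{NULL} leaves the RNG state untouched.
#' @return an object of class \code{conformer_spec}.
#' @export
conformer_spec <- function(n_carbons = 16, bond_length = 1.53,
                           bond_angle = 111.5,
                           dihedral_model = c("all_trans", "rotamer_sampled",
                                              "continuous"),
                           rotamer_weights = c(0.5, 0.25, 0.25),
                           cis_bond_index = NULL, n_conformers = 1,
                           seed = NULL) {
  dihedral_model <- match.arg(dihedral_model)
  chk_count(n_carbons, "n_carbons", min = 2L)
  chk_pos(bond_length, "bond_length")
  chk_num(bond_angle, "bond_angle", lo = 0, hi = 180, closed_lo = FALSE,
          closed_hi = FALSE)
  if (!is.numeric(rotamer_weights) || length(rotamer_weights) != 3L ||
      any(rotamer_weights < 0) || sum(rotamer_weights) <= 0)
    stop("'rotamer_weights' must be 3 non-negative numbers", call. = FALSE)
  if (!is.null(cis_bond_index)) {
    chk_count(cis_bond_index, "cis_bond_index", min = 2L)
    if (cis_bond_index > n_carbons - 2)
      stop(sprintf("'cis_bond_index' out of chain range: %d (need 2..%d)",
                   cis_bond_index, n_carbons - 2), call. = FALSE)
  }
  chk_count(n_conformers + 1L, "n_conformers")  # allow 0
  if (!is.null(seed)) seed <- chk_count(seed, "seed", min = 0L)
  structure(list(n_carbons = as.integer(n_carbons),
                 bond_length = bond_length, bond_angle = bond_angle,
                 dihedral_model = dihedral_model,
                 rotamer_weights = rotamer_weights / sum(rotamer_weights),
                 cis_bond_index = cis_bond_index,
                 n_conformers = as.integer(n_conformers), seed = seed),
            class = "conformer_spec")
}

# Place atom d given a, b, c with bond length l, bond angle theta and
# dihedral phi (radians) -- the standard internal-to-Cartesian extension.
place_atom <- function(a, b, c, l, theta, phi) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-l * cos(theta), l * sin(theta) * cos(phi),
          l * sin(theta) * sin(phi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

build_chain <- function(n, l, theta_deg, dihedrals_deg) {
  theta <- theta_deg * pi / 180
  xyz <- matrix(0, n, 3)
  xyz[2, ] <- c(l, 0, 0)
  if (n >= 3)
    xyz[3, ] <- xyz[2, ] + l * c(-cos(theta), sin(theta), 0)
  if (n >= 4) {
    phi <- dihedrals_deg * pi / 180
    for (i in 4:n)
      xyz[i, ] <- place_atom(xyz[i - 3, ], xyz[i - 2, ], xyz[i - 1, ], l,
                             theta, phi[i - 3])
  }
  xyz
}

#' Generate synthetic acyl-chain conformers
#'
#' Builds an ensemble of idealized carbon chains per a [conformer_spec()].
#' Bond lengths and angles are exact; dihedrals follow the requested model.
#' Output conformers carry atom names \code{C1..Cn} and are directly usable
#' by [superpose_carbons()], [rmsd_density()] and [write_pdb_conformers()].
#'
#' @param spec a [conformer_spec()].
#' @param ligand_code 3-letter residue code to stamp on the conformers.
#' @return a list of \code{ligand_conformer} objects (possibly empty).
#' @export
#' @examples
#' ref <- generate_conformers(conformer_spec(dihedral_model = "all_trans"))[[1]]
#' ens <- generate_conformers(conformer_spec(dihedral_model = "rotamer_sampled",
#'                                           n_conformers = 10, seed = 1))
generate_conformers <- function(spec, ligand_code = "PLM") {
  stopifnot(inherits(spec, "conformer_spec"))
  if (spec$n_conformers == 0L) return(list())
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n_dih <- max(0L, spec$n_carbons - 3L)
  lapply(seq_len(spec$n_conformers), function(i) {
    dih <- switch(spec$dihedral_model,
      all_trans = rep(180, n_dih),
      rotamer_sampled = sample(c(180, 65, -65), n_dih, replace = TRUE,
                               prob = spec$rotamer_weights),
      continuous = runif(n_dih, -180, 180))
    if (!is.null(spec$cis_bond_index) && n_dih > 0) {
      # dihedral about bond Ck-C(k+1) is the one placing atom k+2
      dih[spec$cis_bond_index - 1L] <- 0
    }
    xyz <- build_chain(spec$n_carbons, spec$bond_length, spec$bond_angle,
                       dih)
    new_ligand_conformer(
      source_id = sprintf("synthetic_%04d", i),
      ligand_code = ligand_code, chain = "A", res_seq = i,
      atoms = data.frame(name = paste0("C", seq_len(spec$n_carbons)),
                         element = "C", x = xyz[, 1], y = xyz[, 2],
                         z = xyz[, 3], altloc = "", occupancy = 1,
                         stringsAsFactors = FALSE))
  })
}

new_ligand_conformer <- function(source_id, ligand_code, chain, res_seq,
                                 atoms) {
  structure(list(source_id = source_id, ligand_code = ligand_code,
                 chain = chain, res_seq = res_seq, atoms = atoms),
            class = "ligand_conformer")
}

#' @export
print.ligand_conformer <- function(x, ...) {
  cat(sprintf("ligand_conformer %s: %s %s/%s, %d atoms (%d C)\n",
              x$source_id, x$ligand_code, x$chain, x$res_seq,
              nrow(x$atoms), sum(x$atoms$element == "C")))
  invisible(x)
}

#' Write conformers as minimal PDB HETATM records
#'
#' @param conformers list of \code{ligand_conformer}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pdb_conformers <- function(conformers, path) {
  lines <- character(0)
  serial <- 0L
  for (k in seq_along(conformers)) {
    cf <- conformers[[k]]
    at <- cf$atoms
    res_seq <- cf$res_seq %% 10000L
    for (j in seq_len(nrow(at))) {
      serial <- serial + 1L
      nm <- at$name[j]
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      lines <- c(lines, sprintf(
        "HETATM%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, nm_fmt, substr(at$altloc[j], 1, 1),
        cf$ligand_code, substr(cf$chain, 1, 1), res_seq, " ",
        at$x[j], at$y[j], at$z[j], at$occupancy[j], 0, at$element[j]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
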