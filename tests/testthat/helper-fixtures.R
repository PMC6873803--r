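# Shared fixtures, all built in code.

# wrap a bare (lags, G) pair into the curve container fit_acf() expects
make_curve <- function(lags, G, n_frames = 10000, trace_mean = 100,
                       frame_time = 0.003) {
  structure(list(lags = lags, G = G, var_G = rep(NA_real_, length(G)),
                 n_frames = n_frames, trace_mean = trace_mean,
                 frame_time = frame_time),
            class = "fcs_acf")
}

# rotation matrix about a (normalized) axis by angle (radians)
rotation_about <- function(axis, angle) {
  ax <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -ax[3], ax[2],
                ax[3], 0, -ax[1],
                -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# apply a proper rigid motion to a conformer
rigid_move <- function(conf, R, shift) {
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(R) + matrix(shift, nrow(xyz), 3, byrow = TRUE)
  conf$atoms[, c("x", "y", "z")] <- xyz
  conf
}

# a minimal conformer from a coordinate matrix (atoms C1..Cn)
toy_conformer <- function(xyz, id = "toy") {
  n <- nrow(xyz)
  structure(list(source_id = id, ligand_code = "PLM", chain = "A",
                 res_seq = 1L,
                 atoms = data.frame(name = paste0("C", seq_len(n)),
                                    element = "C", x = xyz[, 1],
                                    y = xyz[, 2], z = xyz[, 3],
                                    altloc = "", occupancy = 1,
                                    stringsAsFactors = FALSE)),
            class = "ligand_conformer")
}

# PDB HETATM line with correct fixed columns
pdb_line <- function(serial, name, altloc, res, chain, seq, x, y, z,
                     occ = 1, elem = "C") {
  sprintf(
    "HETATM%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial, sprintf(" %-3s", name), altloc, res, chain, seq, " ",
    x, y, z, occ, 0, elem)
}

# an fcs_stack built directly from a counts array (frames x H x W)
stack_from_counts <- function(counts, a = 0.24, omega0 = 0.24,
                              exposure = 0.003) {
  structure(list(counts = counts, a = a, omega0 = omega0,
                 exposure = exposure, optics = NULL, sim_config = NULL,
                 config_hash = NA_character_),
            class = "fcs_stack")
}

# small rendered free-diffusion stack shared across tests (cheap: ~2 s)
cached_free_stack <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      sim <- sim_config("free", n_particles = 40, D_out = 1,
                        n_steps = 3000, seed = 901)
      opt <- optics_config(roi = c(12L, 12L), n_frames = 3000, seed = 902)
      val <<- render_stack(simulate_trajectories(sim), opt)
    }
    val
  }
})
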