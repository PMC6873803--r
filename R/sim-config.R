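#' Configuration for a membrane-diffusion simulation
#'
#' Defines a 2D Brownian-dynamics run in a periodic square box, in one of
#' three regimes of plasma-membrane diffusion:
#' \describe{
#'   \item{\code{free}}{unobstructed Brownian motion with diffusion
#'     coefficient \code{D_out};}
#'   \item{\code{domain}}{fixed, non-overlapping circular domains (the
#'     picture of quasi-static ordered membrane domains) with interior
#'     diffusivity \code{D_in}; boundary crossings into a domain are accepted
#'     with probability \code{P_enter}, crossings out with \code{P_exit},
#'     rejected crossings are reflected at the circle;}
#'   \item{\code{hop}}{a square meshwork (cytoskeleton picket-fence) of side
#'     \code{mesh_side}; compartment-boundary crossings are accepted with
#'     probability \code{P_hop}, otherwise reflected.}
#' }
#'
#' @param mode one of \code{"free"}, \code{"domain"}, \code{"hop"}.
#' @param box_side side of the periodic simulation box (um).
#' @param n_particles number of particles.
#' @param D_out diffusion coefficient outside domains / within compartments
#'   (um^2/s).
#' @param domain_radius radius of the circular domains (um).
#' @param domain_area_fraction fraction of the box area covered by domains,
#'   in [0, 1].
#' @param D_in diffusion coefficient inside domains (um^2/s).
#' @param P_enter,P_exit acceptance probabilities for boundary crossings
#'   into / out of a domain, in [0, 1].
#' @param mesh_side side of the square mesh compartments (um).
#' @param P_hop acceptance probability for a mesh-boundary crossing, [0, 1].
#' @param dt time step (s).
#' @param n_steps number of steps.
#' @param seed integer seed; \code{NULL} leaves the RNG state untouched.
#' @return an object of class \code{sim_config}.
#' @seealso [simulate_trajectories()]
#' @export
#' @examples
#' cfg <- sim_config("free", n_particles = 10, n_steps = 100, seed = 1)
#' trj <- simulate_trajectories(cfg)
sim_config <- function(mode = c("free", "domain", "hop"),
                       box_side = 6, n_particles = 60, D_out = 0.5,
                       domain_radius = 0.1, domain_area_fraction = 0.4,
                       D_in = 0.05, P_enter = 0.01, P_exit = 0.02,
                       mesh_side = 1.0, P_hop = 0.05,
                       dt = 0.003, n_steps = 10000, seed = NULL) {
  mode <- match.arg(mode)
  chk_pos(box_side, "box_side")
  chk_count(n_particles, "n_particles")
  chk_num(D_out, "D_out", lo = 0)         # D = 0 is a legal degenerate case
  chk_pos(dt, "dt")
  chk_count(n_steps, "n_steps")
  if (mode == "domain") {
    chk_pos(domain_radius, "domain_radius")
    chk_prob(domain_area_fraction, "domain_area_fraction")
    chk_num(D_in, "D_in", lo = 0)
    chk_prob(P_enter, "P_enter")
    chk_prob(P_exit, "P_exit")
    if (2 * domain_radius >= box_side)
      stop("'domain_radius' too large for 'box_side'", call. = FALSE)
  }
  if (mode == "hop") {
    chk_pos(mesh_side, "mesh_side")
    chk_prob(P_hop, "P_hop")
  }
  if (!is.null(seed)) seed <- chk_count(seed, "seed", min = 0L)
  structure(list(mode = mode, box_side = box_side,
                 n_particles = as.integer(n_particles), D_out = D_out,
                 domain_radius = domain_radius,
                 domain_area_fraction = domain_area_fraction, D_in = D_in,
                 P_enter = P_enter, P_exit = P_exit, mesh_side = mesh_side,
                 P_hop = P_hop, dt = dt, n_steps = as.integer(n_steps),
                 seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Membrane diffusion simulation config (mode: %s)\n", x$mode))
  cat(sprintf("  box %g um, %d particles, D_out %g um^2/s, dt %g s, %d steps\n",
              x$box_side, x$n_particles, x$D_out, x$dt, x$n_steps))
  if (x$mode == "domain")
    cat(sprintf("  domains: r %g um, area fraction %g, D_in %g, P_enter %g, P_exit %g\n",
                x$domain_radius, x$domain_area_fraction, x$D_in, x$P_enter,
                x$P_exit))
  if (x$mode == "hop")
    cat(sprintf("  mesh: side %g um, P_hop %g\n", x$mesh_side, x$P_hop))
  invisible(x)
}
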