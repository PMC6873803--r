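#' Simulate 2D membrane-diffusion trajectories
#'
#' Runs Brownian dynamics in a periodic square box according to a
#' [sim_config()]. Free steps are Gaussian with per-axis variance
#' \code{2 * D * dt}. In \code{domain} mode, fixed non-overlapping circular
#' domains (placed by rejection sampling to cover approximately
#' \code{domain_area_fraction} of the box) slow particles to \code{D_in}
#' inside and gate boundary crossings with \code{P_enter} / \code{P_exit};
#' rejected crossings are reflected at the circle. In \code{hop} mode a
#' square mesh gates crossings with \code{P_hop}.
#'
#' @param config a [sim_config()].
#' @return an object of class \code{trajectory_set}: a list with
#'   \code{positions} (array \code{(n_steps + 1) x n_particles x 2}, um,
#'   wrapped into \code{[0, box_side)}), \code{dt}, \code{box_side},
#'   \code{domains} (centers of the placed circles, domain mode only) and
#'   \code{config}.
#' @export
#' @examples
#' trj <- simulate_trajectories(sim_config("free", n_particles = 5,
#'                                         n_steps = 200, seed = 7))
#' dim(trj$positions)
simulate_trajectories <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be a sim_config object", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$box_side
  P <- config$n_particles
  start <- cbind(runif(P, 0, L), runif(P, 0, L))
  sigma_out <- sqrt(2 * config$D_out * config$dt)
  domains <- NULL
  pos <- switch(config$mode,
    free = cpp_sim_free(start, config$n_steps, sigma_out, L),
    hop = cpp_sim_hop(start, config$n_steps, sigma_out, L,
                      config$mesh_side, config$P_hop),
    domain = {
      domains <- place_domains(L, config$domain_radius,
                               config$domain_area_fraction)
      cl <- domain_cell_list(domains, config$domain_radius, L)
      sigma_in <- sqrt(2 * config$D_in * config$dt)
      cpp_sim_domain(start, config$n_steps, sigma_out, sigma_in, L,
                     domains, config$domain_radius, config$P_enter,
                     config$P_exit, cl$offsets, cl$ids, cl$ncell)
    })
  structure(list(positions = pos, dt = config$dt, box_side = L,
                 domains = domains, config = config),
            class = "trajectory_set")
}

# Rejection-sample non-overlapping circle centers covering ~ area_fraction
# of the periodic box (minimum-image separation >= 2 * radius).
place_domains <- function(L, radius, area_fraction, max_tries = 200000L) {
  n_dom <- round(area_fraction * L^2 / (pi * radius^2))
  if (n_dom == 0L) return(matrix(numeric(0), 0, 2))
  if (area_fraction > 0.6)
    stop("'domain_area_fraction' too high for non-overlapping placement",
         call. = FALSE)
  centers <- matrix(NA_real_, n_dom, 2)
  placed <- 0L
  for (i in seq_len(max_tries)) {
    cand <- runif(2, 0, L)
    if (placed > 0L) {
      dx <- abs(centers[seq_len(placed), 1] - cand[1])
      dy <- abs(centers[seq_len(placed), 2] - cand[2])
      dx <- pmin(dx, L - dx)
      dy <- pmin(dy, L - dy)
      if (any(dx^2 + dy^2 < (2 * radius)^2)) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
    if (placed == n_dom) break
  }
  if (placed < n_dom)
    stop("could not place non-overlapping domains; lower ",
         "'domain_area_fraction' or 'domain_radius'", call. = FALSE)
  centers
}

# Cell list: for each grid cell, the domain indices (0-based, for C++) whose
# circle could contain a point in that cell (minimum-image metric).
domain_cell_list <- function(centers, radius, L) {
  ncell <- max(1L, as.integer(floor(L / (2.5 * radius))))
  cs <- L / ncell
  reach <- radius + cs * sqrt(2) / 2
  ids <- vector("list", ncell * ncell)
  ctr <- (seq_len(ncell) - 0.5) * cs
  for (cy in seq_len(ncell)) {
    for (cx in seq_len(ncell)) {
      dx <- abs(centers[, 1] - ctr[cx]); dx <- pmin(dx, L - dx)
      dy <- abs(centers[, 2] - ctr[cy]); dy <- pmin(dy, L - dy)
      ids[[(cy - 1L) * ncell + cx]] <-
        which(sqrt(dx^2 + dy^2) <= reach) - 1L
    }
  }
  lens <- lengths(ids)
  list(offsets = as.integer(c(0L, cumsum(lens))),
       ids = as.integer(unlist(ids)), ncell = ncell)
}

#' Time-averaged mean squared displacement
#'
#' Computes the time- and ensemble-averaged MSD of a trajectory set at the
#' given lags. Positions are unwrapped from the periodic box first (valid
#' while single-step displacements are below half the box side).
#'
#' @param traj a \code{trajectory_set}.
#' @param lags integer vector of step lags.
#' @return data.frame with columns \code{lag}, \code{dt_s}, \code{msd_um2}.
#' @export
msd <- function(traj, lags = seq_len(min(50, dim(traj$positions)[1] - 1))) {
  stopifnot(inherits(traj, "trajectory_set"))
  pos <- traj$positions
  L <- traj$box_side
  # unwrap: minimum-image step increments, cumulated
  unwrap1 <- function(m) {
    d <- diff(m)
    d <- d - L * round(d / L)
    rbind(m[1, , drop = FALSE],
          sweep(apply(d, 2, cumsum), 2, m[1, ], "+"))
  }
  x <- unwrap1(pos[, , 1])
  y <- unwrap1(pos[, , 2])
  n <- nrow(x)
  out <- vapply(lags, function(k) {
    dx <- x[(k + 1):n, , drop = FALSE] - x[1:(n - k), , drop = FALSE]
    dy <- y[(k + 1):n, , drop = FALSE] - y[1:(n - k), , drop = FALSE]
    mean(dx^2 + dy^2)
  }, numeric(1))
  data.frame(lag = lags, dt_s = lags * traj$dt, msd_um2 = out)
}

#' @export
print.trajectory_set <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("trajectory_set: %d particles, %d steps of %g s (%s mode)\n",
              d[2], d[1] - 1L, x$dt, x$config$mode))
  invisible(x)
}
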