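#' Imaging-FCS autocorrelation model
#'
#' The single-component camera-based FCS model for a square pixel of side
#' \code{a} and a Gaussian PSF of 1/e^2 radius \code{omega0}:
#' \deqn{G(\tau) = \frac{1}{N}\left[\frac{g(p(\tau))}{g(p(0))}\right]^2
#'   \left[1 + \frac{F_t}{1-F_t} e^{-\tau/t_f}\right] + G_\infty,}
#' with \eqn{g(p) = \mathrm{erf}(p) + (e^{-p^2} - 1)/(\sqrt{\pi} p)} and
#' \eqn{p(\tau) = a / \sqrt{4 D \tau + \omega_0^2}}. As \eqn{\tau \to 0^+}
#' the amplitude is \eqn{(1/N)(1 + F_t/(1-F_t)) + G_\infty}; for
#' \eqn{F_t = 0} the model decreases strictly in \eqn{\tau} towards
#' \eqn{G_\infty}.
#'
#' @param tau lag times (s).
#' @param N average number of particles in the observation area.
#' @param D diffusion coefficient (um^2/s).
#' @param a pixel side in the sample plane (um; after binning,
#'   \code{n_bin * a}).
#' @param omega0 PSF 1/e^2 radius (um).
#' @param F_t triplet fraction in [0, 1).
#' @param t_f triplet relaxation time (s).
#' @param G_inf offset at long lags.
#' @return numeric vector \code{G(tau)}.
#' @seealso [acf_model_components()] for several diffusive components,
#'   [fit_acf()].
#' @export
acf_model <- function(tau, N, D, a, omega0, F_t = 0, t_f = 1e-3,
                      G_inf = 0) {
  acf_model_components(tau, B = 1, mean_N = N, D = D, a = a,
                       omega0 = omega0, F_t = F_t, t_f = t_f,
                       G_inf = G_inf)
}

#' Multi-component imaging-FCS autocorrelation model
#'
#' Sum of \code{length(D)} diffusive components with brightnesses \code{B}
#' and mean particle numbers \code{mean_N}; component amplitudes are
#' \eqn{\alpha_i = B_i^2 \langle N_i \rangle / (\sum_i B_i \langle N_i
#' \rangle)^2}.
#'
#' @inheritParams acf_model
#' @param B per-component molecular brightness (counts/s).
#' @param mean_N per-component average particle number.
#' @param D per-component diffusion coefficient (um^2/s).
#' @return numeric vector \code{G(tau)}.
#' @export
acf_model_components <- function(tau, B, mean_N, D, a, omega0, F_t = 0,
                                 t_f = 1e-3, G_inf = 0) {
  stopifnot(length(B) == length(D), length(mean_N) == length(D),
            a > 0, omega0 > 0, all(D > 0), F_t >= 0, F_t < 1)
  alpha <- B^2 * mean_N / sum(B * mean_N)^2
  g0 <- gfun(a / omega0)
  spatial <- 0
  for (i in seq_along(D)) {
    p <- a / sqrt(4 * D[i] * tau + omega0^2)
    spatial <- spatial + alpha[i] * (gfun(p) / g0)^2
  }
  triplet <- if (F_t > 0) 1 + F_t / (1 - F_t) * exp(-tau / t_f) else 1
  spatial * triplet + G_inf
}

# g(p) = erf(p) + (exp(-p^2) - 1) / (sqrt(pi) * p), the pixel-PSF overlap
# kernel; p -> 0 limit is p / sqrt(pi).
gfun <- function(p) {
  out <- erf(p) + (exp(-p^2) - 1) / (sqrt(pi) * p)
  small <- p < 1e-8
  if (any(small)) out[small] <- p[small] / sqrt(pi)
  out
}

#' Effective observation area of a binned pixel
#'
#' The observation area of camera-based FCS is the binned pixel area
#' convolved with the PSF. For a square pixel of side \code{a_bin} and a
#' Gaussian PSF of 1/e^2 radius \code{omega0},
#' \deqn{A_{eff} = \frac{a^2}{\left[\mathrm{erf}(p_0) +
#'   (e^{-p_0^2} - 1) / (\sqrt{\pi} p_0)\right]^2}, \qquad p_0 = a/\omega_0,}
#' which equals the convolution-based definition
#' \eqn{(\int W)^2 / \int W^2} with \eqn{W = \mathrm{square}(a) \otimes
#' \mathrm{Gaussian}(\omega_0)}. It is strictly increasing in both
#' arguments, tends to \eqn{a^2} for \eqn{\omega_0 \ll a} and to
#' \eqn{\pi \omega_0^2} for \eqn{a \ll \omega_0}.
#'
#' @param a_bin binned pixel side (um).
#' @param omega0 PSF 1/e^2 radius (um).
#' @return effective area (um^2), vectorized over \code{a_bin}.
#' @export
#' @examples
#' effective_area(0.48, 0.24)
effective_area <- function(a_bin, omega0) {
  chk_pos(omega0, "omega0")
  if (any(a_bin <= 0)) stop("'a_bin' must be > 0", call. = FALSE)
  a_bin^2 / gfun(a_bin / omega0)^2
}
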