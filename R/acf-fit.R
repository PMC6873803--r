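#' Fit the imaging-FCS model to an autocorrelation curve
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of the single-component [acf_model()] -- parameters
#' \code{N}, \code{D}, \code{G_inf}, plus \code{F_t}, \code{t_f} when
#' \code{triplet = TRUE}. Weights are inverse per-lag variances when the
#' curve carries them, otherwise unweighted. Initial values: \code{N} from
#' the first-lag amplitude, \code{D} by inverting the model at the
#' half-decay lag, \code{F_t = 0.05}, \code{t_f = 1} ms. Bounds:
#' \code{D} in (1e-6, 1e3) um^2/s, \code{F_t} in [0, 0.5].
#'
#' The diffusion time is defined as \code{tau_D = A_eff / D} with
#' \code{A_eff = effective_area(a, omega0)}; under this convention the
#' diffusion law is exact with zero intercept for ideal free diffusion
#' (any other positive proportionality rescales the intercept magnitude but
#' never its sign).
#'
#' @param curve an \code{fcs_acf} from [compute_acf()].
#' @param a (binned) pixel side in the sample plane (um).
#' @param omega0 PSF 1/e^2 radius (um).
#' @param triplet include the triplet blinking term?
#' @param init optional named list overriding initial values.
#' @param bounds optional list with elements \code{lower}, \code{upper}
#'   (named numeric vectors) overriding defaults.
#' @param weighted use per-lag variances as inverse weights when available.
#' @return an object of class \code{fcs_fit}: coefficients, covariance,
#'   reduced chi-square, \code{tau_D} (s), \code{A_eff} (um^2),
#'   \code{converged} flag, and the data. Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{vcov}, \code{predict},
#'   \code{fitted}, \code{residuals}, \code{plot}.
#' @export
#' @examples
#' tau <- multitau_lags(2000) * 0.003
#' g <- acf_model(tau, N = 10, D = 0.5, a = 0.24, omega0 = 0.24)
#' crv <- structure(list(lags = tau, G = g, var_G = rep(NA, length(tau)),
#'                       n_frames = 2000, trace_mean = 100,
#'                       frame_time = 0.003), class = "fcs_acf")
#' fit <- fit_acf(crv, a = 0.24, omega0 = 0.24)
#' coef(fit)
fit_acf <- function(curve, a, omega0, triplet = FALSE, init = NULL,
                    bounds = NULL, weighted = TRUE) {
  stopifnot(inherits(curve, "fcs_acf"))
  chk_pos(a, "a"); chk_pos(omega0, "omega0")
  tau <- curve$lags
  G <- curve$G
  n_par <- if (triplet) 5L else 3L
  if (length(tau) <= n_par)
    stop("curve has fewer lags than free parameters", call. = FALSE)

  w <- rep(1, length(G))
  if (weighted && any(is.finite(curve$var_G))) {
    v <- curve$var_G
    vmed <- median(v[is.finite(v) & v > 0])
    if (is.finite(vmed) && vmed > 0) {
      v[!is.finite(v) | v <= 0] <- vmed
      v <- pmax(v, 1e-6 * vmed)    # cap extreme weights
      w <- 1 / v
    }
  }

  start <- acf_fit_init(tau, G, a, omega0, triplet)
  if (!is.null(init)) start[names(init)] <- unlist(init)
  lower <- c(N = 1e-6, D = 1e-6, G_inf = -10)
  upper <- c(N = 1e9, D = 1e3, G_inf = 10)
  if (triplet) {
    lower <- c(lower, F_t = 0, t_f = 1e-6)
    upper <- c(upper, F_t = 0.5, t_f = 1)
  }
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }
  start <- pmin(pmax(start, lower), upper)

  fres <- function(p) {
    g <- acf_model(tau, N = p[["N"]], D = p[["D"]], a = a, omega0 = omega0,
                   F_t = if (triplet) p[["F_t"]] else 0,
                   t_f = if (triplet) p[["t_f"]] else 1e-3,
                   G_inf = p[["G_inf"]])
    sqrt(w) * (G - g)
  }
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = fres,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("ACF fit did not converge: ", fit$message, call. = FALSE)
  p <- fit$par
  dof <- length(G) - length(p)
  chi2_red <- sum(fit$fvec^2) / dof
  covm <- tryCatch(chi2_red * solve(fit$hessian),
                   error = function(e) matrix(NA_real_, length(p),
                                              length(p)))
  dimnames(covm) <- list(names(p), names(p))
  A_eff <- effective_area(a, omega0)
  structure(list(coefficients = unlist(p), covariance = covm,
                 chi2_reduced = chi2_red, tau_D = A_eff / p[["D"]],
                 A_eff = A_eff, converged = converged, a = a,
                 omega0 = omega0, triplet = triplet, curve = curve,
                 weights = w, info = fit$info),
            class = "fcs_fit")
}

# initial values: N from the first-lag amplitude, D from half-decay
acf_fit_init <- function(tau, G, a, omega0, triplet) {
  ginf0 <- median(tail(G, max(3L, length(G) %/% 8L)))
  amp <- G[1] - ginf0
  if (!is.finite(amp) || amp <= 0) amp <- max(abs(G[1]), 1e-3)
  n0 <- 1 / amp
  # first lag at which the decaying part falls below half its initial value
  half_idx <- which(G - ginf0 <= amp / 2)
  tau_half <- if (length(half_idx)) tau[half_idx[1]] else tau[length(tau)]
  g0 <- gfun(a / omega0)
  dhalf <- tryCatch(
    uniroot(function(d)
      (gfun(a / sqrt(4 * d * tau_half + omega0^2)) / g0)^2 - 0.5,
      lower = 1e-6, upper = 1e3, tol = 1e-10)$root,
    error = function(e) effective_area(a, omega0) / (4 * tau_half))
  out <- c(N = n0, D = dhalf, G_inf = ginf0)
  if (triplet) out <- c(out, F_t = 0.05, t_f = 1e-3)
  out
}

#' @export
coef.fcs_fit <- function(object, ...) object$coefficients

#' @export
vcov.fcs_fit <- function(object, ...) object$covariance

#' @export
predict.fcs_fit <- function(object, newdata = NULL, ...) {
  tau <- if (is.null(newdata)) object$curve$lags else
    (newdata$tau %||% newdata)
  p <- object$coefficients
  acf_model(tau, N = p[["N"]], D = p[["D"]], a = object$a,
            omega0 = object$omega0,
            F_t = if (object$triplet) p[["F_t"]] else 0,
            t_f = if (object$triplet) p[["t_f"]] else 1e-3,
            G_inf = p[["G_inf"]])
}

#' @export
fitted.fcs_fit <- function(object, ...) predict(object)

#' @export
residuals.fcs_fit <- function(object, ...) object$curve$G - fitted(object)

#' @export
print.fcs_fit <- function(x, ...) {
  p <- x$coefficients
  cat(sprintf(
    "Imaging-FCS fit%s: N = %.4g, D = %.4g um^2/s, G_inf = %.3g\n",
    if (x$converged) "" else " (NOT converged)", p[["N"]], p[["D"]],
    p[["G_inf"]]))
  if (x$triplet)
    cat(sprintf("  triplet: F_t = %.3g, t_f = %.3g s\n", p[["F_t"]],
                p[["t_f"]]))
  cat(sprintf("  tau_D = %.4g s, A_eff = %.4g um^2, chi2_red = %.3g\n",
              x$tau_D, x$A_eff, x$chi2_reduced))
  invisible(x)
}

#' @export
summary.fcs_fit <- function(object, ...) {
  se <- sqrt(diag(object$covariance))
  out <- data.frame(estimate = object$coefficients, se = se)
  attr(out, "tau_D") <- object$tau_D
  attr(out, "A_eff") <- object$A_eff
  attr(out, "chi2_reduced") <- object$chi2_reduced
  out
}

#' @export
plot.fcs_fit <- function(x, log = "x", ...) {
  plot(x$curve$lags, x$curve$G, log = log,
       xlab = expression(tau ~ "(s)"), ylab = expression(G(tau)), ...)
  tt <- exp(seq(log(min(x$curve$lags)), log(max(x$curve$lags)),
                length.out = 200))
  lines(tt, predict(x, data.frame(tau = tt)), col = 2)
  invisible(x)
}
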