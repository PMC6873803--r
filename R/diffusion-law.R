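#' Build FCS diffusion-law points from an image stack
#'
#' For each binning factor: bins pixels, computes the ACF of every
#' super-pixel trace, fits the imaging-FCS model, pools the converged fits
#' into one diffusion time (median across super-pixels; variance from the
#' median absolute deviation), and pairs it with the effective observation
#' area \code{effective_area(n_bin * a, omega0)}.
#'
#' @param stack an \code{fcs_stack}.
#' @param binnings integer vector of binning factors (>= 3 values).
#' @param triplet,weighted passed to [fit_acf()].
#' @param max_lag_frames largest correlation lag in frames (default a
#'   quarter of the trace).
#' @return a data.frame of class \code{difflaw_points} with columns
#'   \code{n_bin}, \code{a_bin_um}, \code{A_eff_um2}, \code{tau_D_s},
#'   \code{tau_D_var}, \code{D_median}, \code{n_fits}, \code{n_converged}.
#' @seealso [fit_diffusion_law()]
#' @export
build_diffusion_law <- function(stack, binnings = 1:5, triplet = FALSE,
                                weighted = TRUE, max_lag_frames = NULL) {
  stopifnot(inherits(stack, "fcs_stack"))
  binnings <- sort(unique(as.integer(binnings)))
  if (length(binnings) < 3)
    stop("need at least 3 binnings for a diffusion law", call. = FALSE)
  rows <- lapply(binnings, function(nb) {
    bs <- bin_pixels(stack, nb)
    n <- nrow(bs$traces)
    lags <- multitau_lags(n, max_lag = max_lag_frames %||% (n %/% 4))
    tauD <- rep(NA_real_, ncol(bs$traces))
    Dfit <- rep(NA_real_, ncol(bs$traces))
    conv <- logical(ncol(bs$traces))
    for (j in seq_len(ncol(bs$traces))) {
      ft <- tryCatch(suppressWarnings({
        crv <- compute_acf(bs$traces[, j], frame_time = bs$frame_time,
                           lags = lags)
        fit_acf(crv, a = bs$a_bin, omega0 = bs$omega0, triplet = triplet,
                weighted = weighted)
      }), error = function(e) NULL)
      if (!is.null(ft) && ft$converged) {
        tauD[j] <- ft$tau_D
        Dfit[j] <- coef(ft)[["D"]]
        conv[j] <- TRUE
      }
    }
    td <- tauD[conv]
    data.frame(n_bin = nb, a_bin_um = bs$a_bin,
               A_eff_um2 = effective_area(bs$a_bin, bs$omega0),
               tau_D_s = if (any(conv)) median(td) else NA_real_,
               tau_D_var = if (sum(conv) > 1)
                 mad(td)^2 / sum(conv) else NA_real_,
               D_median = if (any(conv)) median(Dfit[conv]) else NA_real_,
               n_fits = length(conv), n_converged = sum(conv))
  })
  out <- do.call(rbind, rows)
  out <- out[is.finite(out$tau_D_s), , drop = FALSE]
  if (nrow(out) < 3)
    stop("insufficient points: fewer than 3 binnings with converged fits",
         call. = FALSE)
  class(out) <- c("difflaw_points", "data.frame")
  out
}

#' Fit the FCS diffusion law
#'
#' Variance-weighted least-squares fit of the line
#' \deqn{\tau_D(A_{eff}) = \tau_0 + A_{eff} / D_{eff}.}
#' The intercept \eqn{\tau_0} diagnoses sub-resolution membrane
#' organization (see [classify_mode()]); the inverse slope is the effective
#' diffusion coefficient.
#'
#' @param points a \code{difflaw_points} data.frame (or any data.frame with
#'   \code{A_eff_um2}, \code{tau_D_s} and optionally \code{tau_D_var});
#'   >= 3 points expected, 2 permitted with a warning.
#' @param threshold classification threshold for \eqn{|\tau_0|} (s),
#'   default 0.2.
#' @return an object of class \code{difflaw_fit}: \code{tau_0} (s),
#'   \code{D_eff} (um^2/s; \code{NA} and flagged when the slope is not
#'   positive), \code{se_tau_0}, \code{r2}, \code{mode}, \code{points},
#'   and the underlying \code{lm} fit. Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{residuals},
#'   \code{plot}.
#' @export
#' @examples
#' pts <- data.frame(A_eff_um2 = 1:5, tau_D_s = 0.5 + (1:5) / 1.0)
#' fit_diffusion_law(pts)
fit_diffusion_law <- function(points, threshold = 0.2) {
  stopifnot(is.data.frame(points))
  pts <- points[is.finite(points$A_eff_um2) & is.finite(points$tau_D_s), ,
                drop = FALSE]
  if (nrow(pts) < 2)
    stop("need at least 2 diffusion-law points", call. = FALSE)
  if (nrow(pts) == 2)
    warning("only 2 points: exact interpolation, no residual information",
            call. = FALSE)
  w <- rep(1, nrow(pts))
  if (!is.null(pts$tau_D_var) && all(is.finite(pts$tau_D_var)) &&
      all(pts$tau_D_var > 0))
    w <- 1 / pts$tau_D_var
  lmfit <- lm(tau_D_s ~ A_eff_um2, data = pts, weights = w)
  cf <- coef(lmfit)
  tau_0 <- unname(cf[1])
  slope <- unname(cf[2])
  sm <- suppressWarnings(summary(lmfit))
  se_tau_0 <- sm$coefficients[1, 2]
  r2 <- sm$r.squared
  negative_slope <- !is.finite(slope) || slope <= 0
  if (negative_slope)
    warning("non-positive slope: D_eff undefined; tau_0 still reported",
            call. = FALSE)
  structure(list(tau_0 = tau_0,
                 D_eff = if (negative_slope) NA_real_ else 1 / slope,
                 se_tau_0 = se_tau_0, r2 = r2,
                 mode = classify_mode(tau_0, threshold),
                 threshold = threshold, negative_slope = negative_slope,
                 points = pts, lm = lmfit),
            class = "difflaw_fit")
}

#' Classify the diffusion mode from the diffusion-law intercept
#'
#' A near-zero intercept (\eqn{|\tau_0| \le} threshold) indicates free
#' diffusion; a positive intercept (\eqn{\tau_0 >} threshold) indicates
#' domain-confined diffusion in membrane domains; a negative intercept
#' (\eqn{\tau_0 < -}threshold) indicates hop diffusion through meshwork
#' compartmentalization. The default threshold of 0.2 s is the published
#' criterion; it is configurable because rescaling the \code{tau_D}
#' convention rescales \eqn{\tau_0} by the same factor.
#'
#' @param tau_0 intercept(s) in seconds (vectorized).
#' @param threshold positive classification threshold (s).
#' @return character vector: \code{"free"}, \code{"domain_confined"} or
#'   \code{"hop"}.
#' @export
#' @examples
#' classify_mode(c(1.66, 0.16, -0.5))
classify_mode <- function(tau_0, threshold = 0.2) {
  chk_pos(threshold, "threshold")
  ifelse(abs(tau_0) <= threshold, "free",
         ifelse(tau_0 > threshold, "domain_confined", "hop"))
}

#' Aggregate replicate diffusion-law fits
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' intercepts of independent replicate measurements.
#'
#' @param fits list of \code{difflaw_fit} objects, or a numeric vector of
#'   intercepts.
#' @param label condition label for reporting.
#' @return an object of class \code{replicate_summary}: \code{tau_0_mean},
#'   \code{tau_0_sd} (0 when n = 1, with \code{single_replicate} flag),
#'   \code{n}, \code{condition_label}.
#' @export
#' @examples
#' aggregate_replicates(c(1, 2, 3), "demo")
aggregate_replicates <- function(fits, label = "") {
  tau0 <- if (is.numeric(fits)) fits else
    vapply(fits, function(f) {
      stopifnot(inherits(f, "difflaw_fit"))
      f$tau_0
    }, numeric(1))
  if (length(tau0) < 1) stop("no replicates supplied", call. = FALSE)
  single <- length(tau0) == 1L
  structure(list(tau_0_mean = mean(tau0),
                 tau_0_sd = if (single) 0 else sd(tau0),
                 n = length(tau0), single_replicate = single,
                 condition_label = label),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("%s: tau_0 = %.3g +/- %.3g s (n = %d%s)\n",
              if (nzchar(x$condition_label)) x$condition_label else
                "replicates",
              x$tau_0_mean, x$tau_0_sd, x$n,
              if (x$single_replicate) ", single replicate" else ""))
  invisible(x)
}

#' @export
print.difflaw_fit <- function(x, ...) {
  cat(sprintf(
    "FCS diffusion law: tau_0 = %.4g +/- %.3g s, D_eff = %.4g um^2/s, R2 = %.4f\n",
    x$tau_0, x$se_tau_0, x$D_eff, x$r2))
  cat(sprintf("  mode: %s (threshold %.3g s, %d points)%s\n", x$mode,
              x$threshold, nrow(x$points),
              if (x$negative_slope) " [non-positive slope]" else ""))
  invisible(x)
}

#' @export
summary.difflaw_fit <- function(object, ...) {
  list(tau_0_s = object$tau_0, se_tau_0_s = object$se_tau_0,
       D_eff_um2_s = object$D_eff, r2 = object$r2, mode = object$mode,
       n_points = nrow(object$points),
       negative_slope = object$negative_slope)
}

#' @export
coef.difflaw_fit <- function(object, ...) {
  c(tau_0 = object$tau_0, D_eff = object$D_eff)
}

#' @export
predict.difflaw_fit <- function(object, newdata = NULL, ...) {
  A <- if (is.null(newdata)) object$points$A_eff_um2 else
    (newdata$A_eff_um2 %||% newdata)
  unname(coef(object$lm)[1] + coef(object$lm)[2] * A)
}

#' @export
residuals.difflaw_fit <- function(object, ...) {
  object$points$tau_D_s - predict(object)
}

#' @export
plot.difflaw_fit <- function(x, ...) {
  pts <- x$points
  plot(pts$A_eff_um2, pts$tau_D_s,
       xlab = expression(A[eff] ~ (mu * m^2)),
       ylab = expression(tau[D] ~ "(s)"),
       xlim = c(0, max(pts$A_eff_um2) * 1.05),
       ylim = range(0, pts$tau_D_s, x$tau_0), ...)
  abline(x$lm, col = 2)
  abline(h = 0, lty = 3)
  legend("topleft", bty = "n", legend = sprintf(
    "tau_0 = %.3g s (%s)", x$tau_0, x$mode))
  invisible(x)
}
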