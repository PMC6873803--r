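#' Software pixel binning of an image stack
#'
#' Sums non-overlapping \code{n_bin x n_bin} pixel blocks per frame,
#' enlarging the observation area post acquisition. Trailing rows/columns
#' that do not fill a block are dropped.
#'
#' @param stack an \code{fcs_stack}.
#' @param n_bin binning factor (>= 1, <= min(H, W)).
#' @return an object of class \code{binned_series}: list with \code{traces}
#'   (matrix \code{n_frames x n_superpixels}, column-major over the
#'   super-pixel grid), \code{n_bin}, \code{a_bin} (um), \code{grid}
#'   (\code{c(H2, W2)}), \code{omega0}, \code{frame_time}.
#' @export
bin_pixels <- function(stack, n_bin) {
  stopifnot(inherits(stack, "fcs_stack"))
  d <- dim(stack$counts)
  n_bin <- chk_count(n_bin, "n_bin")
  if (n_bin > min(d[2], d[3]))
    stop(sprintf("'n_bin' (%d) exceeds ROI (%dx%d)", n_bin, d[2], d[3]),
         call. = FALSE)
  H2 <- d[2] %/% n_bin
  W2 <- d[3] %/% n_bin
  x <- stack$counts[, seq_len(H2 * n_bin), seq_len(W2 * n_bin), drop = FALSE]
  # frames x (n_bin x H2) x (n_bin x W2) -> sum over the two n_bin axes
  dim(x) <- c(d[1], n_bin, H2, n_bin, W2)
  traces <- apply(x, c(1, 3, 5), sum)
  dim(traces) <- c(d[1], H2 * W2)
  structure(list(traces = traces, n_bin = n_bin, a_bin = n_bin * stack$a,
                 grid = c(H2, W2), omega0 = stack$omega0,
                 frame_time = stack$exposure),
            class = "binned_series")
}

#' Pseudo-logarithmic (multi-tau style) lag grid
#'
#' The first block holds 16 consecutive unit lags; each later block adds 8
#' lags at doubled spacing, up to \code{max_lag}.
#'
#' @param n trace length (frames).
#' @param max_lag largest lag in frames (default \code{n \%/\% 4}).
#' @return integer vector of lags (frames), strictly increasing.
#' @export
multitau_lags <- function(n, max_lag = n %/% 4) {
  lags <- 1:16
  b <- 1L
  repeat {
    blk <- (9:16) * 2^b
    if (blk[1] > max_lag) break
    lags <- c(lags, blk)
    b <- b + 1L
  }
  as.integer(lags[lags <= max_lag])
}

#' Temporal autocorrelation of an intensity trace
#'
#' Computes the normalized fluctuation autocorrelation
#' \deqn{G(\tau) = \langle \delta F(t)\, \delta F(t+\tau) \rangle /
#'   \langle F \rangle^2, \quad \delta F = F - \langle F \rangle,}
#' at a pseudo-logarithmic lag grid (see [multitau_lags()]); each retained
#' lag is evaluated with the exact direct estimator, so values agree with a
#' naive double-sum to machine precision. Per-lag variances come from
#' splitting the trace into \code{n_segments} contiguous blocks and taking
#' the variance of the per-segment estimates over segments (divided by the
#' number of segments).
#'
#' @param trace numeric intensity time series (counts); length >= 16, mean
#'   > 0.
#' @param frame_time frame duration (s); lags are reported in seconds.
#' @param lags integer lags in frames; default [multitau_lags()].
#' @param n_segments segments for the variance estimate (default 8); traces
#'   too short for segmentation fall back to unit variances.
#' @return an object of class \code{fcs_acf}: list with \code{lags} (s),
#'   \code{G}, \code{var_G}, \code{n_frames}, \code{trace_mean},
#'   \code{frame_time}.
#' @export
compute_acf <- function(trace, frame_time = 1, lags = NULL,
                        n_segments = 8) {
  trace <- as.numeric(trace)
  n <- length(trace)
  if (n < 16) stop("trace must contain at least 16 frames", call. = FALSE)
  mu <- mean(trace)
  if (!is.finite(mu) || mu <= 0)
    stop("undefined normalization: trace mean must be positive",
         call. = FALSE)
  if (is.null(lags)) lags <- multitau_lags(n)
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1) || any(lags >= n))
    stop("lags must lie in [1, n_frames - 1]", call. = FALSE)
  G <- acf_at_lags(trace, lags)
  # per-lag variance via contiguous segments
  var_G <- rep(NA_real_, length(lags))
  seg_len <- n %/% n_segments
  if (n_segments >= 2 && seg_len >= 32) {
    usable <- lags <= seg_len %/% 2
    if (any(usable)) {
      gs <- vapply(seq_len(n_segments), function(s) {
        seg <- trace[((s - 1) * seg_len + 1):(s * seg_len)]
        out <- rep(NA_real_, sum(usable))
        if (mean(seg) > 0) out <- acf_at_lags(seg, lags[usable])
        out
      }, numeric(sum(usable)))
      gs <- matrix(gs, nrow = sum(usable))
      var_G[usable] <- apply(gs, 1, var) / n_segments
      # lags beyond segment reach inherit the largest estimated variance
      if (any(!usable) && any(is.finite(var_G)))
        var_G[!usable] <- max(var_G[usable], na.rm = TRUE)
    }
  }
  structure(list(lags = lags * frame_time, G = G, var_G = var_G,
                 n_frames = n, trace_mean = mu, frame_time = frame_time),
            class = "fcs_acf")
}

# exact direct estimator at integer lags (vectorized)
acf_at_lags <- function(trace, lags) {
  n <- length(trace)
  mu <- mean(trace)
  df <- trace - mu
  vapply(lags, function(k) {
    mean(df[1:(n - k)] * df[(k + 1):n]) / mu^2
  }, numeric(1))
}

#' Direct double-sum ACF estimator (reference implementation)
#'
#' Literal, loop-based evaluation of the normalized fluctuation
#' autocorrelation, kept for validating the production estimator.
#'
#' @inheritParams compute_acf
#' @param lags integer lags in frames.
#' @return numeric vector of G values.
#' @export
acf_direct <- function(trace, lags) {
  n <- length(trace)
  mu <- sum(trace) / n
  out <- numeric(length(lags))
  for (j in seq_along(lags)) {
    k <- lags[j]
    s <- 0
    for (t in seq_len(n - k))
      s <- s + (trace[t] - mu) * (trace[t + k] - mu)
    out[j] <- (s / (n - k)) / mu^2
  }
  out
}

#' @export
print.fcs_acf <- function(x, ...) {
  cat(sprintf(
    "fcs_acf: %d lags in [%.3g, %.3g] s, %d frames, mean %.2f counts\n",
    length(x$lags), min(x$lags), max(x$lags), x$n_frames, x$trace_mean))
  invisible(x)
}

#' @export
plot.fcs_acf <- function(x, log = "x", ...) {
  plot(x$lags, x$G, log = log, xlab = expression(tau ~ "(s)"),
       ylab = expression(G(tau)), ...)
  invisible(x)
}
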