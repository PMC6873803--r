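#' Error function
#'
#' \code{erf(x) = 2 * pnorm(x * sqrt(2)) - 1}, used throughout the imaging-FCS
#' model equations.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validation helpers: fail with the offending field named.
chk_num <- function(x, field, lo = -Inf, hi = Inf, len = 1L,
                    closed_lo = TRUE, closed_hi = TRUE) {
  if (!is.numeric(x) || length(x) != len || anyNA(x))
    stop(sprintf("'%s' must be a numeric of length %d", field, len),
         call. = FALSE)
  ok_lo <- if (closed_lo) all(x >= lo) else all(x > lo)
  ok_hi <- if (closed_hi) all(x <= hi) else all(x < hi)
  if (!ok_lo || !ok_hi)
    stop(sprintf("'%s' out of range [%s, %s]: %s", field,
                 format(lo), format(hi), paste(format(x), collapse = ", ")),
         call. = FALSE)
  invisible(x)
}

chk_pos <- function(x, field, len = 1L)
  chk_num(x, field, lo = 0, len = len, closed_lo = FALSE)

chk_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < min)
    stop(sprintf("'%s' must be an integer count >= %d", field, min),
         call. = FALSE)
  invisible(as.integer(x))
}

chk_prob <- function(x, field) chk_num(x, field, lo = 0, hi = 1)

#' Expand a global seed into per-stage seeds
#'
#' Deterministically derives independent-looking 32-bit seeds for pipeline
#' stages from one user-facing seed.
#'
#' @param seed integer master seed.
#' @param stage integer stage index (1-based).
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + 104729 * as.numeric(stage)) %%
               2147483647)
}

# md5 of the JSON serialization of a config (used in sidecars and reports)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}
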