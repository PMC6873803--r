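#' Least-squares rigid-body superposition over carbon atoms
#'
#' Superposes the carbon skeleton of \code{mobile} onto \code{reference} by
#' the optimal proper rotation + translation (Kabsch algorithm via SVD;
#' reflections are forbidden so chirality is preserved, and there is no
#' scaling). Carbons are matched by atom name (\code{C1..Cn}); when atoms
#' are missing on either side the common subset is used and flagged.
#'
#' @param mobile,reference \code{ligand_conformer} objects.
#' @param matching optional named character vector mapping reference carbon
#'   names to mobile carbon names (\code{c(C1 = "CA", ...)}); default is
#'   identity matching on shared names.
#' @return an object of class \code{superposition}: list with
#'   \code{rotation} (3x3, det +1), \code{translation} (the transform is
#'   \code{x -> rotation \%*\% x + translation}), \code{rmsd} (Angstrom),
#'   \code{n_matched}, \code{matched} (reference atom names used) and
#'   \code{common_subset} (TRUE when not all reference carbons matched).
#' @export
#' @examples
#' ref <- generate_conformers(conformer_spec())[[1]]
#' superpose_carbons(ref, ref)$rmsd
superpose_carbons <- function(mobile, reference, matching = NULL) {
  stopifnot(inherits(mobile, "ligand_conformer"),
            inherits(reference, "ligand_conformer"))
  cm <- carbon_coords(mobile)
  cr <- carbon_coords(reference)
  if (is.null(matching)) {
    shared <- intersect(rownames(cr), rownames(cm))
    matching <- setNames(shared, shared)
  }
  ref_names <- names(matching)
  ok <- ref_names %in% rownames(cr) & matching %in% rownames(cm)
  if (sum(ok) < 3) {
    miss <- unique(c(setdiff(rownames(cr), ref_names[ok]),
                     setdiff(ref_names, rownames(cr))))
    stop(sprintf(
      "fewer than 3 matched carbon pairs between %s and %s (unmatched: %s)",
      mobile$source_id, reference$source_id,
      paste(head(miss, 8), collapse = ", ")), call. = FALSE)
  }
  P <- cm[matching[ok], , drop = FALSE]      # mobile
  Q <- cr[ref_names[ok], , drop = FALSE]     # reference
  mu_p <- colMeans(P)
  mu_q <- colMeans(Q)
  Pc <- sweep(P, 2, mu_p)
  Qc <- sweep(Q, 2, mu_q)
  H <- crossprod(Pc, Qc)                     # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - Qc)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(mu_q - R %*% mu_p),
                 rmsd = rmsd, n_matched = sum(ok),
                 matched = unname(ref_names[ok]),
                 common_subset = sum(ok) < nrow(cr)),
            class = "superposition")
}

# Carbon coordinate matrix, rows named by atom name, ordered by the numeric
# part of the name (C1, C2, ..., C16) with non-numeric names last.
carbon_coords <- function(conf) {
  at <- conf$atoms[conf$atoms$element == "C", , drop = FALSE]
  if (nrow(at) < 2)
    stop(sprintf("conformer %s has fewer than 2 carbon atoms",
                 conf$source_id), call. = FALSE)
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", at$name)))
  at <- at[order(is.na(num), num, at$name), , drop = FALSE]
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- at$name
  m
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: RMSD %.4f A over %d matched carbons%s\n",
              x$rmsd, x$n_matched,
              if (x$common_subset) " (common subset)" else ""))
  invisible(x)
}

#' Binned, dataset-size-normalized RMSD distribution
#'
#' Superposes every conformer on the reference over carbon atoms, bins the
#' resulting RMSDs into \code{n_bins} equal-width bins over
#' \code{[0, max(RMSD)]} (or \code{bin_range}), and divides counts by the
#' dataset size, so the frequencies sum to 1 and can be read as the
#' probability of being conformationally close to the reference. This is a
#' normalized frequency, not a per-Angstrom density.
#'
#' @param conformers list of \code{ligand_conformer}.
#' @param reference the reference \code{ligand_conformer}.
#' @param n_bins number of bins (default 20).
#' @param bin_range optional \code{c(lo, hi)} in Angstrom.
#' @return an object of class \code{rmsd_density}: list with
#'   \code{bin_edges} (length \code{n_bins + 1}), \code{frequencies},
#'   \code{n_bins}, \code{dataset_size} (number of conformers successfully
#'   superposed), \code{rmsd} (per-conformer table) and \code{n_excluded}.
#' @export
rmsd_density <- function(conformers, reference, n_bins = 20,
                         bin_range = NULL) {
  stopifnot(length(conformers) >= 1)
  chk_count(n_bins, "n_bins")
  tab <- conformer_rmsd_table(conformers, reference)
  okv <- tab$rmsd_A[!is.na(tab$rmsd_A)]
  if (length(okv) == 0L)
    stop("all superpositions failed; no RMSDs to bin", call. = FALSE)
  if (is.null(bin_range)) {
    hi <- max(okv)
    if (hi < 1e-9) hi <- 1         # degenerate: all identical to reference
    bin_range <- c(0, hi)
  }
  if (bin_range[2] <= bin_range[1])
    stop("'bin_range' must be increasing", call. = FALSE)
  edges <- seq(bin_range[1], bin_range[2], length.out = n_bins + 1)
  idx <- findInterval(okv, edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  idx <- pmin(pmax(idx, 1L), n_bins)   # clamp values outside bin_range
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, frequencies = counts / length(okv),
                 n_bins = as.integer(n_bins), dataset_size = length(okv),
                 rmsd = tab, n_excluded = sum(is.na(tab$rmsd_A))),
            class = "rmsd_density")
}

conformer_rmsd_table <- function(conformers, reference) {
  rows <- lapply(conformers, function(cf) {
    sp <- tryCatch(superpose_carbons(cf, reference), error = function(e) NULL)
    data.frame(source_id = cf$source_id, chain = cf$chain,
               res_seq = cf$res_seq,
               n_matched = if (is.null(sp)) NA_integer_ else sp$n_matched,
               rmsd_A = if (is.null(sp)) NA_real_ else sp$rmsd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.rmsd_density <- function(x, ...) {
  cat(sprintf(
    "rmsd_density: %d conformers in %d bins over [%.3g, %.3g] A (%d excluded)\n",
    x$dataset_size, x$n_bins, x$bin_edges[1],
    x$bin_edges[length(x$bin_edges)], x$n_excluded))
  invisible(x)
}

#' @export
plot.rmsd_density <- function(x, main = "RMSD distribution", ...) {
  mids <- (head(x$bin_edges, -1) + tail(x$bin_edges, -1)) / 2
  barplot(x$frequencies, names.arg = sprintf("%.2f", mids),
          xlab = "RMSD to reference (A)",
          ylab = "normalized frequency", main = main, ...)
  invisible(x)
}

#' Closest conformer to a reference
#'
#' Identifies the conformer with minimum carbon-atom RMSD to the reference
#' after optimal rigid superposition; ties break to the lexicographically
#' first \code{source_id}.
#'
#' @inheritParams rmsd_density
#' @return list with \code{source_id}, \code{rmsd} and the full per-
#'   conformer table \code{rmsd_table}.
#' @export
closest_conformer <- function(conformers, reference) {
  if (length(conformers) < 1)
    stop("need at least one conformer", call. = FALSE)
  tab <- conformer_rmsd_table(conformers, reference)
  ok <- !is.na(tab$rmsd_A)
  if (!any(ok)) stop("all superpositions failed", call. = FALSE)
  sub <- tab[ok, , drop = FALSE]
  sub <- sub[order(sub$rmsd_A, sub$source_id), , drop = FALSE]
  list(source_id = sub$source_id[1], rmsd = sub$rmsd_A[1], rmsd_table = tab)
}
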