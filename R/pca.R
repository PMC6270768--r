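# Principal component analysis of backbone covariance: eigen-decomposition,
# projections, variance fractions, cross-system eigenvector overlap, and
# detection of pressurisation-driven drift modes.

#' PCA of a trajectory's positional covariance
#'
#' Every frame is superposed (Kabsch, over the masked atoms) onto
#' `reference`, the 3N coordinate covariance matrix of the fitted frames is
#' formed, and its eigen-system is extracted (via SVD of the centred data
#' matrix). Cross-system comparison requires the same mask dimension and
#' the same fit reference.
#'
#' @param t An `md_trajectory` with more than one frame.
#' @param mask Optional `atom_mask` selecting the analysed atoms
#'   (typically the backbone core).
#' @param reference Reference coordinates for fitting (matrix or
#'   `pc_structure`); default: frame 1. Pre-masked matrices (rows equal to
#'   mask length) are accepted.
#' @return List of class `eigen_system`: `mean_coords` (atoms x 3),
#'   `eigenvalues` (A^2, descending), `eigenvectors` (3N x modes,
#'   orthonormal columns), `projections` (frames x modes), `times`,
#'   `mask_length`, `fit_reference`.
#' @export
fit_pca <- function(t, mask = NULL, reference = NULL) {
  nf <- n_frames(t)
  if (nf < 2) abort("fit_pca requires more than one frame")
  X <- .traj_masked(t, mask)
  na <- dim(X)[2]
  if (is.null(reference)) {
    reference <- X[1, , ]; dim(reference) <- c(na, 3)
  } else {
    reference <- if (is.matrix(reference)) reference else coords(reference)
    if (nrow(reference) != na) {
      ir <- .mask_indices(mask, nrow(reference))
      if (length(ir) != na) abort("reference does not match the mask")
      reference <- reference[ir, , drop = FALSE]
    }
  }
  X <- .fit_frames_to(X, reference)
  flat <- matrix(X, nrow = nf)          # frames x 3N (atom-major per axis)
  # reorder to atom blocks (x1 y1 z1 x2 ...) for per-atom eigenvector blocks
  ord <- as.vector(t(matrix(seq_len(3 * na), na, 3)))
  flat <- flat[, ord, drop = FALSE]
  mu <- colMeans(flat)
  C <- sweep(flat, 2, mu)
  sv <- svd(C / sqrt(nf - 1))
  keep <- which(sv$d^2 > max(sv$d^2) * 1e-12)
  if (length(keep) == 0) keep <- 1L
  eigenvalues <- sv$d[keep]^2
  eigenvectors <- sv$v[, keep, drop = FALSE]
  projections <- C %*% eigenvectors
  structure(list(
    mean_coords = matrix(mu, ncol = 3, byrow = TRUE),
    eigenvalues = eigenvalues,
    eigenvectors = eigenvectors,
    projections = projections,
    times = t$times,
    mask_length = na,
    fit_reference = reference,
    total_variance = sum(sv$d^2)
  ), class = "eigen_system")
}

#' @export
print.eigen_system <- function(x, ...) {
  cat("<eigen_system> ", length(x$eigenvalues), " modes over ",
      x$mask_length, " atoms; top eigenvalue ",
      signif(x$eigenvalues[1], 4), " A^2\n", sep = "")
  invisible(x)
}

#' @export
tidy.eigen_system <- function(x, ...) {
  tibble(mode = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         variance_fraction = x$eigenvalues / sum(x$eigenvalues),
         cumulative_fraction = cumsum(x$eigenvalues) / sum(x$eigenvalues))
}

#' @export
glance.eigen_system <- function(x, ...) {
  k <- min(10L, length(x$eigenvalues))
  tibble(n_modes = length(x$eigenvalues),
         n_atoms = x$mask_length,
         total_variance = sum(x$eigenvalues),
         top10_fraction = variance_fraction(x, k))
}

#' Fraction of total variance carried by the first k modes
#'
#' @param e An `eigen_system`.
#' @param k Number of leading modes.
#' @return Fraction in [0, 1].
#' @export
variance_fraction <- function(e, k) {
  if (k < 1 || k > length(e$eigenvalues)) abort("k out of range")
  sum(e$eigenvalues[seq_len(k)]) / sum(e$eigenvalues)
}

#' Eigenvector overlap (inner-product) matrix between two systems
#'
#' Entry (i, j) is the absolute inner product of mode i of system `a` with
#' mode j of system `b`; 1 means identical directions of collective
#' motion, 0 orthogonal. Requires equal mask dimension and an identical
#' fit reference (otherwise the comparison is meaningless and an error is
#' raised).
#'
#' @param a,b `eigen_system`s.
#' @param n Number of leading modes to compare (default 10, truncated to
#'   what each system has).
#' @return Matrix of class `overlap_matrix` (values in [0, 1]).
#' @export
overlap_matrix <- function(a, b, n = 10) {
  if (a$mask_length != b$mask_length) {
    abort(paste0("systems differ in atom count (", a$mask_length, " vs ",
                 b$mask_length, "); overlap requires identical masks"))
  }
  if (!isTRUE(all.equal(a$fit_reference, b$fit_reference,
                        tolerance = 1e-8))) {
    abort("systems were fitted to different reference structures")
  }
  na <- min(n, ncol(a$eigenvectors))
  nb <- min(n, ncol(b$eigenvectors))
  M <- abs(crossprod(a$eigenvectors[, seq_len(na), drop = FALSE],
                     b$eigenvectors[, seq_len(nb), drop = FALSE]))
  dimnames(M) <- list(paste0("a", seq_len(na)), paste0("b", seq_len(nb)))
  class(M) <- c("overlap_matrix", class(M))
  M
}

#' @export
tidy.overlap_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(mode_a = rep(seq_len(nrow(m)), ncol(m)),
         mode_b = rep(seq_len(ncol(m)), each = nrow(m)),
         overlap = as.vector(m))
}

#' Detect a pressurisation drift mode
#'
#' A drift mode is a principal component whose projection changes
#' monotonically with time — the signature of externally driven
#' deformation rather than thermal oscillation. The mode maximising the
#' absolute Pearson correlation of its projection with time is returned
#' if that correlation reaches `threshold`; constant projections are
#' treated as non-drifting.
#'
#' @param projections An `eigen_system`, or a frames x modes matrix.
#' @param times Frame times (taken from the eigen system when omitted).
#' @param threshold Correlation threshold (default 0.9).
#' @return Tibble: `mode` (`NA` if none reaches the threshold),
#'   `correlation` per candidate in `detail` attribute; primary columns
#'   `mode`, `correlation`.
#' @export
detect_drift_mode <- function(projections, times = NULL, threshold = 0.9) {
  if (inherits(projections, "eigen_system")) {
    if (is.null(times)) times <- projections$times
    projections <- projections$projections
  }
  projections <- as.matrix(projections)
  if (is.null(times)) times <- seq_len(nrow(projections))
  cors <- apply(projections, 2, function(p) {
    if (sd(p) < 1e-12) return(0)
    abs(cor(p, times))
  })
  best <- which.max(cors)
  out <- tibble(
    mode = if (cors[best] >= threshold) as.integer(best) else NA_integer_,
    correlation = cors[best]
  )
  attr(out, "all_correlations") <- cors
  out
}

#' Per-atom fluctuation amplitude of one mode
#'
#' The contribution of a single principal mode to each atom's fluctuation:
#' sqrt(eigenvalue) times the norm of the atom's 3-vector block of the
#' eigenvector. Squared amplitudes sum to the eigenvalue.
#'
#' @param e An `eigen_system`.
#' @param mode Mode index.
#' @return Tibble: `atom`, `amplitude` (Angstrom).
#' @export
mode_rmsf <- function(e, mode) {
  if (mode < 1 || mode > ncol(e$eigenvectors)) abort("mode out of range")
  v <- matrix(e$eigenvectors[, mode], ncol = 3, byrow = TRUE)
  amp <- sqrt(e$eigenvalues[mode]) * sqrt(rowSums(v^2))
  tibble(atom = seq_along(amp), amplitude = amp)
}
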