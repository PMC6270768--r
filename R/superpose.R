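# Rigid-body superposition (Kabsch) and RMSD.

#' Optimal rigid superposition of two coordinate sets
#'
#' Finds the proper rotation and translation minimising the (weighted)
#' RMSD between `mobile` and `reference` via the SVD of the weighted
#' covariance of the centred coordinates, with the determinant correction
#' that excludes reflections.
#'
#' @param mobile,reference Numeric matrices (atoms x 3) with equal row counts
#'   (at least 3 non-collinear points).
#' @param weights Optional per-atom non-negative weights.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` (Angstrom) and `fitted` (mobile after superposition). The fit is
#'   `fitted = (mobile - cm_mobile) %*% rotation + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    abort("mobile and reference must have the same number of atoms")
  }
  n <- nrow(mobile)
  if (n < 3L) abort("superposition requires at least 3 atoms")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
    abort("weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)
  cm_m <- colSums(mobile * w)
  cm_r <- colSums(reference * w)
  A <- sweep(mobile, 2, cm_m)
  B <- sweep(reference, 2, cm_r)
  H <- t(A * w) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  fitted <- A %*% R
  dev <- fitted - B
  rmsd <- sqrt(sum(w * rowSums(dev^2)))
  fitted <- sweep(fitted, 2, cm_r, `+`)
  list(rotation = R, translation = cm_r, rmsd = rmsd, fitted = fitted)
}

#' Root-mean-square deviation between two conformations
#'
#' @param a,b Coordinate matrices (atoms x 3) or `pc_structure`s.
#' @param mask Optional `atom_mask` (or integer indices) applied to both.
#' @param fit If `TRUE` (default) superpose `b`'s masked atoms onto `a`'s
#'   before measuring; if `FALSE`, measure in the given frames.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, mask = NULL, fit = TRUE) {
  xa <- if (is.matrix(a)) a else coords(a)
  xb <- if (is.matrix(b)) b else coords(b)
  ia <- .mask_indices(mask, nrow(xa))
  ib <- .mask_indices(mask, nrow(xb))
  if (length(ia) != length(ib)) abort("mask selects different atom counts")
  xa <- xa[ia, , drop = FALSE]
  xb <- xb[ib, , drop = FALSE]
  if (fit) {
    kabsch_superpose(xb, xa)$rmsd
  } else {
    sqrt(mean(rowSums((xa - xb)^2)))
  }
}
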