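# Trajectory analyses: atomic fluctuations, RMSD series, centre-of-mass
# distance series and probability distributions.

.traj_masked <- function(t, mask) {
  idx <- .mask_indices(mask, dim(t$coords)[2])
  t$coords[, idx, , drop = FALSE]
}

.fit_frames_to <- function(X, ref) {
  # X: frames x atoms x 3; superpose every frame onto ref (atoms x 3)
  for (f in seq_len(dim(X)[1])) {
    m <- X[f, , ]; dim(m) <- dim(X)[2:3]
    X[f, , ] <- kabsch_superpose(m, ref)$fitted
  }
  X
}

#' Per-atom root-mean-square fluctuations
#'
#' RMSF about the mean conformation, optionally after superposing every
#' frame (Kabsch, over the masked atoms) onto the mean: frames are first
#' fitted to frame 1, the mean is formed, frames are re-fitted to that
#' mean, and sqrt(<|x - <x>|^2>) is taken per atom.
#'
#' @param t An `md_trajectory` with at least 2 frames.
#' @param mask Optional `atom_mask` restricting the atoms analysed (and the
#'   fit).
#' @param fit Superpose frames before measuring (default `TRUE`).
#' @return Tibble with `atom` (index within the mask), `res_number`,
#'   `atom_name` (when labels exist) and `rmsf` (Angstrom).
#' @export
atomic_fluctuations <- function(t, mask = NULL, fit = TRUE) {
  if (n_frames(t) < 2) abort("atomic_fluctuations requires at least 2 frames")
  X <- .traj_masked(t, mask)
  if (fit) {
    ref <- X[1, , ]; dim(ref) <- dim(X)[2:3]
    X <- .fit_frames_to(X, ref)
    mean1 <- apply(X, c(2, 3), mean)
    X <- .fit_frames_to(X, mean1)
  }
  mu <- apply(X, c(2, 3), mean)
  dev2 <- sweep(X, c(2, 3), mu)^2
  rmsf <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames of |dx|^2
  out <- tibble(atom = seq_along(rmsf), rmsf = rmsf)
  if (!is.null(t$atoms)) {
    idx <- .mask_indices(mask, nrow(t$atoms))
    out$res_number <- t$atoms$res_number[idx]
    out$atom_name <- t$atoms$name[idx]
    out <- out[, c("atom", "res_number", "atom_name", "rmsf")]
  }
  out
}

#' RMSD of each frame against one or more references
#'
#' @param t An `md_trajectory`.
#' @param reference A coordinate matrix / `pc_structure`, or a named list
#'   of them (e.g. initial conformation, a later snapshot, crystal
#'   structures) evaluated in one pass.
#' @param mask Optional `atom_mask` (applied to trajectory and references;
#'   references may also be given pre-masked with matching atom count).
#' @param fit Kabsch-fit each frame to the reference before measuring
#'   (default `TRUE`).
#' @return Long tibble: `frame`, `time_ps`, `reference`, `rmsd`.
#' @export
rmsd_series <- function(t, reference, mask = NULL, fit = TRUE) {
  refs <- if (is.list(reference) && !is.matrix(reference) &&
              !inherits(reference, "pc_structure")) reference else list(ref = reference)
  if (is.null(names(refs))) names(refs) <- paste0("ref", seq_along(refs))
  X <- .traj_masked(t, mask)
  na <- dim(X)[2]
  purrr::imap(refs, function(rf, nm) {
    xr <- if (is.matrix(rf)) rf else coords(rf)
    if (nrow(xr) != na) {
      ir <- .mask_indices(mask, nrow(xr))
      if (length(ir) != na) abort(paste0("reference '", nm, "' does not match the mask"))
      xr <- xr[ir, , drop = FALSE]
    }
    vals <- vapply(seq_len(dim(X)[1]), function(f) {
      m <- X[f, , ]; dim(m) <- c(na, 3)
      if (fit) kabsch_superpose(m, xr)$rmsd else sqrt(mean(rowSums((m - xr)^2)))
    }, 1.0)
    tibble(frame = seq_along(vals), time_ps = t$times, reference = nm,
           rmsd = vals)
  }) |> dplyr::bind_rows()
}

.group_com <- function(xyz, sel, w) {
  w <- w / sum(w)
  colSums(xyz[sel, , drop = FALSE] * w)
}

#' Centre-of-mass distance between two residues along a trajectory
#'
#' @param t An `md_trajectory` with atom labels.
#' @param res_a,res_b Residue numbers (chain A unless given as
#'   `c(chain, number)` is unnecessary here: single-chain fixtures).
#' @param mass_weighted Use atomic masses (default); otherwise geometric
#'   centres.
#' @param atoms `"all"` residue atoms (default) or `"backbone"` (N, CA, C).
#' @return Tibble of class `distance_series`: `frame`, `time_ps`,
#'   `distance` (Angstrom), with `res_a`/`res_b` attributes. Summarise with
#'   `mean()`/`sd()` on `$distance` or [glance()].
#' @export
com_distance_series <- function(t, res_a, res_b, mass_weighted = TRUE,
                                atoms = c("all", "backbone")) {
  atoms <- match.arg(atoms)
  if (is.null(t$atoms)) abort("trajectory has no atom labels")
  a <- t$atoms
  pick <- function(res) {
    sel <- which(a$res_number == res)
    if (atoms == "backbone") sel <- sel[a$name[sel] %in% c("N", "CA", "C")]
    if (length(sel) == 0L) abort(paste0("residue ", res, " not present in the trajectory"))
    sel
  }
  sel_a <- pick(res_a); sel_b <- pick(res_b)
  wa <- if (mass_weighted) a$mass[sel_a] else rep(1, length(sel_a))
  wb <- if (mass_weighted) a$mass[sel_b] else rep(1, length(sel_b))
  d <- vapply(seq_len(n_frames(t)), function(f) {
    xyz <- frame_coords(t, f)
    sqrt(sum((.group_com(xyz, sel_a, wa) - .group_com(xyz, sel_b, wb))^2))
  }, 1.0)
  out <- tibble(frame = seq_along(d), time_ps = t$times, distance = d)
  attr(out, "res_a") <- res_a
  attr(out, "res_b") <- res_b
  class(out) <- c("distance_series", class(out))
  out
}

#' @export
glance.distance_series <- function(x, ...) {
  tibble(mean = mean(x$distance), sd = sd(x$distance),
         min = min(x$distance), max = max(x$distance), n = nrow(x))
}

#' Probability histogram of a distance series
#'
#' Bins cover the data range in widths of `bin_width`; bar heights are
#' probabilities (summing to 1), as used for pocket-opening distance
#' distributions.
#'
#' @param d A `distance_series` tibble, or a numeric vector of values.
#' @param bin_width Bin width, Angstrom.
#' @return Tibble: `bin_lower`, `bin_upper`, `bin_mid`, `count`,
#'   `probability`.
#' @export
histogram_probability <- function(d, bin_width) {
  values <- if (is.data.frame(d)) d$distance else as.numeric(d)
  if (length(values) < 1) abort("histogram_probability: no values")
  if (bin_width <= 0) abort("histogram_probability: bin_width must be positive")
  lo <- min(values)
  n_bins <- max(1L, ceiling((max(values) - lo) / bin_width - 1e-12))
  edges <- lo + bin_width * (0:n_bins)
  idx <- pmin(pmax(floor((values - lo) / bin_width) + 1L, 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  tibble(
    bin_lower = edges[-length(edges)],
    bin_upper = edges[-1],
    bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
    count = counts,
    probability = counts / length(values)
  )
}
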