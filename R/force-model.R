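# Desk-scale force model: 12-6 Lennard-Jones particle interactions, an
# elastic-network protein model, and harmonic restraints. Units: Angstrom,
# kcal/mol, Da, ps throughout.

#' Lennard-Jones parameter set
#'
#' The 12-6 potential is parameterised by its well depth and the distance of
#' its minimum: E(r) = eps * ((rmin/r)^12 - 2 (rmin/r)^6). Particle pairs
#' combine as: particle-particle uses `eps`/`rmin` directly; particle-protein
#' uses `eps` with the arithmetic mean of `rmin` and `rmin_protein` (protein
#' atoms present as soft LJ spheres of a single configurable size).
#'
#' @param eps Well depth, kcal/mol (default 0.1: soft, uncharged particles).
#' @param rmin Particle-particle equilibrium distance, Angstrom (default 1.4).
#' @param rmin_protein Effective protein-atom LJ diameter contribution,
#'   Angstrom (default 3.0).
#' @param cutoff Non-bonded cutoff, Angstrom (default 10).
#' @param core_frac Soft-core fraction: below `core_frac * rmin` the engine
#'   continues the potential linearly (constant force), so inserting a
#'   lattice particle on top of existing matter exerts a large but finite
#'   push instead of the divergent 12-6 wall. Default 0.6; 0 disables.
#' @param protein_wca If `TRUE`, the particle-protein interaction keeps
#'   only the repulsive branch (truncated and shifted at its minimum,
#'   WCA-style): wall contact then always opposes growth, and the probe
#'   force decreases monotonically with clearance. Default `FALSE`
#'   (full 12-6).
#' @return List of class `lj_params`.
#' @export
lj_params <- function(eps = 0.1, rmin = 1.4, rmin_protein = 3.0, cutoff = 10,
                      core_frac = 0.6, protein_wca = FALSE) {
  if (eps <= 0 || rmin <= 0 || rmin_protein <= 0 || cutoff <= 0) {
    abort("lj_params: eps, rmin, rmin_protein and cutoff must be positive")
  }
  if (core_frac < 0 || core_frac >= 1) {
    abort("lj_params: core_frac must be in [0, 1)")
  }
  structure(list(eps = eps, rmin = rmin, rmin_protein = rmin_protein,
                 rmin_ap = (rmin + rmin_protein) / 2, cutoff = cutoff,
                 core_frac = core_frac, protein_wca = isTRUE(protein_wca)),
            class = "lj_params")
}

#' Pairwise 12-6 Lennard-Jones energy and force
#'
#' @param r Separation(s), Angstrom; must be positive.
#' @param eps Well depth, kcal/mol.
#' @param rmin Distance of the energy minimum, Angstrom.
#' @return Tibble with `r`, `energy` (kcal/mol) and `force` (kcal/mol/A;
#'   `force = -dE/dr`, positive = repulsive).
#' @examples
#' lj_pair(1.4, eps = 1, rmin = 1.4) # at the minimum: energy -1, force 0
#' @export
lj_pair <- function(r, eps = 0.1, rmin = 1.4) {
  if (any(r <= 0)) abort("lj_pair: separation must be positive")
  s6 <- (rmin / r)^6
  tibble(r = r,
         energy = eps * (s6^2 - 2 * s6),
         force = 12 * eps * (s6^2 - s6) / r)
}

#' Build an elastic-network model of a structure
#'
#' Connects every unordered pair of atoms closer than `cutoff` with a
#' harmonic spring whose rest length is the build-time distance, a
#' coarse-grained stand-in for a full protein force field.
#'
#' @param s A `pc_structure`.
#' @param cutoff Spring cutoff, Angstrom.
#' @param k Spring force constant, kcal/mol/A^2.
#' @return List of class `enm_model` with a `springs` tibble
#'   (`i`, `j`, `rest_length`, `k`) and `n_atoms`.
#' @export
build_enm <- function(s, cutoff = 8, k = 10) {
  if (cutoff <= 0) abort("build_enm: cutoff must be positive")
  if (k <= 0) abort("build_enm: k must be positive")
  xyz <- coords(s)
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  sel <- which(upper.tri(d) & d > 0 & d < cutoff, arr.ind = TRUE)
  springs <- tibble(
    i = sel[, 1], j = sel[, 2],
    rest_length = d[sel], k = k
  ) |> dplyr::arrange(.data$i, .data$j)
  structure(list(springs = springs, n_atoms = n, cutoff = cutoff),
            class = "enm_model")
}

#' @export
print.enm_model <- function(x, ...) {
  cat("<enm_model> ", x$n_atoms, " nodes, ", nrow(x$springs),
      " springs (cutoff ", x$cutoff, " A)\n", sep = "")
  invisible(x)
}

#' Assemble a force specification
#'
#' Bundles the interaction terms acting on a mixed system of protein atoms
#' (ENM nodes) and particles: ENM springs between protein atoms, LJ for any
#' pair involving a particle, and harmonic anchors. Used by [total_forces()]
#' and [integrate_dynamics()].
#'
#' @param kind Integer/character vector per particle: `0`/"protein" or
#'   `1`/"particle".
#' @param enm Optional `enm_model` over the protein atoms (indices must
#'   refer to rows of the position matrix).
#' @param lj An [lj_params()] set.
#' @param anchors Optional anchor positions (n x 3).
#' @param anchor_k Per-particle anchor force constants (kcal/mol/A^2;
#'   0 disables an anchor). Recycled.
#' @param particle_lj Whether particle-particle LJ acts (default `TRUE`).
#' @return List of class `force_spec`.
#' @export
force_spec <- function(kind, enm = NULL, lj = lj_params(), anchors = NULL,
                       anchor_k = 0, particle_lj = TRUE) {
  if (is.character(kind)) kind <- as.integer(kind == "particle")
  kind <- as.integer(kind)
  n <- length(kind)
  if (is.null(anchors)) anchors <- matrix(0, n, 3)
  anchors <- as.matrix(anchors)
  if (nrow(anchors) != n) abort("force_spec: anchors must have one row per particle")
  anchor_k <- rep_len(anchor_k, n)
  if (any(anchor_k < 0)) abort("force_spec: anchor_k must be >= 0")
  if (!is.null(enm)) {
    sp <- enm$springs
    if (max(c(sp$i, sp$j, 0)) > n) abort("force_spec: ENM indices out of bounds")
  }
  structure(list(kind = kind, enm = enm, lj = lj, anchors = anchors,
                 anchor_k = anchor_k, particle_lj = isTRUE(particle_lj)),
            class = "force_spec")
}

.spec_springs <- function(spec) {
  if (is.null(spec$enm)) {
    list(i = integer(0), j = integer(0), r0 = numeric(0), k = numeric(0))
  } else {
    sp <- spec$enm$springs
    list(i = as.integer(sp$i) - 1L, j = as.integer(sp$j) - 1L,
         r0 = sp$rest_length, k = sp$k)
  }
}

#' Total forces and potential energy
#'
#' Evaluates analytic forces (kcal/mol/A) and the potential energy
#' (kcal/mol) of the interacting system described by a [force_spec()].
#' Interaction forces obey Newton's third law; only anchor terms break
#' translation invariance.
#'
#' @param positions Numeric matrix (n x 3), Angstrom.
#' @param spec A [force_spec()].
#' @return List with `forces` (n x 3), `energy`, and per-term energies
#'   `energy_spring`, `energy_lj`, `energy_anchor`.
#' @export
total_forces <- function(positions, spec) {
  positions <- as.matrix(positions)
  if (nrow(positions) != length(spec$kind)) {
    abort("total_forces: positions and force_spec particle counts differ")
  }
  sp <- .spec_springs(spec)
  lj <- spec$lj
  cpp_forces(positions, spec$kind, sp$i, sp$j, sp$r0, sp$k,
             spec$anchors, spec$anchor_k,
             lj$eps, lj$rmin, lj$eps, lj$rmin_ap, lj$cutoff,
             spec$particle_lj, lj$core_frac, lj$protein_wca)
}
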