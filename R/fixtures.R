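# Seed-deterministic synthetic fixtures: kinase-like backbones, shell
# pockets with a tunable soft expansion axis, and trajectories with
# planted harmonic/drift modes.

#' Core residue ranges of the CDK5-numbered kinase core
#'
#' The nine printed residue ranges (with one-letter endpoint identities)
#' that define the 214-residue structurally conserved core in CDK5
#' numbering; 3 backbone atoms per residue give the 642-atom core mask.
#'
#' @return Character vector of nine range tokens.
#' @export
cdk5_core_ranges <- function() {
  c("7L-33K", "47S-72S", "75K-92D", "98L-144D", "147L-148A",
    "166W-197N", "199G-220G", "241M-250N", "255L-284P")
}

#' Kinase-like backbone fixture
#'
#' A single-chain poly-alanine-like backbone with residues numbered 7-284
#' laid out along a loose helix, with the residue identities at the core
#' range endpoints set to their true one-letter codes (L7, K33, S47, S72,
#' K75, D92, L98, D144, L147, A148, W166, N197, G199, G220, M241, N250,
#' L255, P284) so that range parsing, letter-code validation and the
#' 642-atom core mask are exercised end to end. Each residue carries N,
#' CA, C and O atoms in standard order.
#'
#' @param path Optional path: when given, the fixture is also written as a
#'   PDB file.
#' @return A `pc_structure`.
#' @export
make_kinase_like_fixture <- function(path = NULL) {
  res_numbers <- 7:284
  special <- c(`7` = "L", `33` = "K", `47` = "S", `72` = "S", `75` = "K",
               `92` = "D", `98` = "L", `144` = "D", `147` = "L",
               `148` = "A", `166` = "W", `197` = "N", `199` = "G",
               `220` = "G", `241` = "M", `250` = "N", `255` = "L",
               `284` = "P")
  rows <- vector("list", length(res_numbers))
  # local backbone geometry within a residue (idealised, A)
  local <- rbind(N = c(0.0, 0.0, 0.0),
                 CA = c(1.46, 0.0, 0.0),
                 C = c(2.0, 1.42, 0.0),
                 O = c(1.4, 2.4, 0.4))
  for (n in seq_along(res_numbers)) {
    res <- res_numbers[n]
    aa1 <- special[as.character(res)]
    res_name <- if (is.na(aa1)) "ALA" else unname(.aa1to3[aa1])
    # helix-like placement of the residue frame
    theta <- n * 100 * pi / 180
    base <- c(9 * cos(theta), 9 * sin(theta), 1.5 * n)
    rot <- matrix(c(cos(theta), -sin(theta), 0,
                    sin(theta), cos(theta), 0,
                    0, 0, 1), 3, 3, byrow = TRUE)
    xyz <- sweep(local %*% t(rot), 2, base, `+`)
    rows[[n]] <- tibble(
      name = rownames(local),
      element = c("N", "C", "C", "O"),
      res_name = res_name, res_number = res,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  }
  s <- as_structure(dplyr::bind_rows(rows))
  if (!is.null(path)) write_pdb(s, path)
  s
}

.fibonacci_sphere <- function(n, rot = 0) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i + rot
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shell pocket with a tunable soft expansion axis
#'
#' A pseudo-protein forming a thick spherical shell around an empty
#' cavity: half the beads sit on a sphere of radius `cavity_radius`, the
#' other half on a staggered outer sphere 1.5 A further out, so the wall
#' cannot be crossed through a single gap. Beads are connected as an
#' elastic network; springs whose bond segment crosses the soft-axis
#' cylinder (within 0.75 cavity radii of the axis line) have their
#' force constants scaled by `stiffness_ratio`, which turns the two polar
#' caps along `soft_axis` into compliant lids that yield under cast
#' pressure. `stiffness_ratio = 1` gives an isotropic pocket. Bead
#' positions are deterministically jittered per `seed`.
#'
#' @param n_shell_atoms Total number of shell beads (>= 20; default 260,
#'   split between the two layers).
#' @param cavity_radius Cavity radius, Angstrom (default 4.4).
#' @param soft_axis Unit 3-vector of the soft direction (default x).
#' @param stiffness_ratio Soft/hard spring-constant ratio in (0, 1]
#'   (default 1).
#' @param seed Integer seed for the deterministic jitter.
#' @param enm_cutoff Spring cutoff, Angstrom (default: 1.8 times the mean
#'   nearest-neighbour spacing).
#' @param enm_k Hard-direction spring constant, kcal/mol/A^2 (default 25).
#' @param bead_mass Bead mass, Da (default 100).
#' @param layers 2 (default) for the thick two-layer wall, 1 for a single
#'   stretchable layer.
#' @return List with `structure` (a `pc_structure`) and `enm`
#'   (an `enm_model`).
#' @export
make_toy_pocket <- function(n_shell_atoms = 260, cavity_radius = 4.4,
                            soft_axis = c(1, 0, 0), stiffness_ratio = 1,
                            seed = 1L, enm_cutoff = NULL, enm_k = 25,
                            bead_mass = 100, layers = 2) {
  if (n_shell_atoms < 20) abort("make_toy_pocket: n_shell_atoms must be >= 20")
  if (cavity_radius <= 0) abort("make_toy_pocket: cavity_radius must be positive")
  if (stiffness_ratio <= 0 || stiffness_ratio > 1) {
    abort("make_toy_pocket: stiffness_ratio must be in (0, 1]")
  }
  soft_axis <- soft_axis / sqrt(sum(soft_axis^2))
  n1 <- if (layers >= 2) ceiling(n_shell_atoms / 2) else n_shell_atoms
  n2 <- n_shell_atoms - n1
  dirs <- rbind(.fibonacci_sphere(n1),
                if (n2 > 0) .fibonacci_sphere(n2, rot = 1.1))
  radii <- c(rep(cavity_radius, n1), rep(cavity_radius + 1.5, n2))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  jitter <- matrix(rnorm(3 * n_shell_atoms, sd = 0.05), ncol = 3)
  dirs <- dirs + jitter
  dirs <- dirs / sqrt(rowSums(dirs^2))
  xyz <- dirs * radii
  s <- as_structure(tibble(
    name = "CA", element = "C", res_name = "GLY",
    res_number = seq_len(n_shell_atoms),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    mass = bead_mass
  ))
  if (is.null(enm_cutoff)) {
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- Inf
    enm_cutoff <- 1.8 * mean(apply(d, 1, min))
  }
  enm <- build_enm(s, cutoff = enm_cutoff, k = enm_k)
  if (stiffness_ratio < 1) {
    # weaken springs crossing the soft axis: bonds whose segment passes
    # within three-quarters of a cavity radius of the axis line form lids
    # of the pocket along that direction
    sp <- enm$springs
    u <- soft_axis
    perp <- function(v) v - outer(as.vector(v %*% u), u)
    p <- perp(xyz[sp$i, , drop = FALSE])
    q <- perp(xyz[sp$j, , drop = FALSE])
    d <- q - p
    tt <- -rowSums(p * d) / pmax(rowSums(d * d), 1e-12)
    tt <- pmin(pmax(tt, 0), 1)
    nearest <- p + d * tt
    crossing <- sqrt(rowSums(nearest^2)) < 0.75 * cavity_radius
    sp$k[crossing] <- sp$k[crossing] * stiffness_ratio
    enm$springs <- sp
  }
  list(structure = s, enm = enm, soft_axis = soft_axis,
       cavity_radius = cavity_radius, seed = seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Trajectory with planted principal modes
#'
#' Frames are `base + sum_m amplitude_m * signal_m(t) * direction_m +
#' noise`: harmonic modes follow sinusoids (distinct incommensurate
#' frequencies, RMS amplitude `amplitude / sqrt(2)`), drift modes follow a
#' linear ramp from -amplitude to +amplitude. Mode directions must be
#' orthonormal 3N vectors. Deterministic per seed.
#'
#' @param base_coords Base conformation (atoms x 3).
#' @param modes List of modes, each `list(direction =, amplitude =,
#'   kind = "harmonic"|"drift")`; directions are length-3N vectors in
#'   atom-major order (x1, y1, z1, x2, ...).
#' @param n_frames Number of frames.
#' @param noise_sd Isotropic white-noise sd per coordinate, Angstrom.
#' @param seed Integer seed.
#' @param dt_ps Frame spacing, ps.
#' @return An `md_trajectory`.
#' @export
make_planted_trajectory <- function(base_coords, modes, n_frames = 400,
                                    noise_sd = 0, seed = 1L, dt_ps = 1) {
  base_coords <- as.matrix(base_coords)
  na <- nrow(base_coords)
  nd <- 3 * na
  dirs <- vapply(modes, function(m) as.numeric(m$direction), numeric(nd))
  dirs <- matrix(dirs, nrow = nd)
  if (length(modes) > 0) {
    G <- crossprod(dirs)
    if (max(abs(G - diag(ncol(dirs)))) > 1e-6) {
      abort("mode directions must be orthonormal")
    }
  }
  tt <- seq_len(n_frames)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  flat_base <- as.vector(t(base_coords))      # atom-major
  X <- matrix(rep(flat_base, each = n_frames), nrow = n_frames)
  for (m in seq_along(modes)) {
    md <- modes[[m]]
    kind <- if (is.null(md$kind)) "harmonic" else md$kind
    sig <- switch(kind,
      harmonic = sin(2 * pi * (0.5 + 0.37 * m) * tt / n_frames * 5),
      drift = seq(-1, 1, length.out = n_frames),
      abort(paste0("unknown mode kind: ", kind))
    )
    X <- X + md$amplitude * outer(sig, dirs[, m])
  }
  if (noise_sd > 0) X <- X + matrix(rnorm(length(X), sd = noise_sd), nrow = n_frames)
  arr <- array(0, dim = c(n_frames, na, 3))
  for (f in seq_len(n_frames)) {
    arr[f, , ] <- matrix(X[f, ], ncol = 3, byrow = TRUE)
  }
  as_trajectory(arr, times = tt * dt_ps)
}

#' Orthonormal mode directions for planted trajectories
#'
#' Deterministic helper producing `k` orthonormal 3N vectors (atom-major)
#' via QR decomposition of a seeded Gaussian matrix. When `base_coords`
#' is supplied, the rigid-body subspace (3 translations, 3 rotations about
#' the centroid) is projected out first, so that planted internal modes
#' survive trajectory superposition unchanged.
#'
#' @param n_atoms Number of atoms.
#' @param k Number of directions.
#' @param seed Integer seed.
#' @param base_coords Optional base conformation (atoms x 3) whose
#'   rigid-body modes are removed.
#' @return Matrix (3N x k) with orthonormal columns (atom-major order).
#' @export
random_orthonormal_modes <- function(n_atoms, k, seed = 1L,
                                     base_coords = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  M <- matrix(rnorm(3 * n_atoms * k), ncol = k)
  if (!is.null(base_coords)) {
    R <- .rigid_body_basis(as.matrix(base_coords))
    M <- M - R %*% crossprod(R, M)
  }
  qr.Q(qr(M))[, seq_len(k), drop = FALSE]
}

.rigid_body_basis <- function(xyz) {
  # orthonormal basis of infinitesimal rigid motions, atom-major 3N vectors
  n <- nrow(xyz)
  ctr <- sweep(xyz, 2, colMeans(xyz))
  B <- matrix(0, 3 * n, 6)
  for (ax in 1:3) B[seq(ax, 3 * n, by = 3), ax] <- 1     # translations
  axes <- diag(3)
  for (ax in 1:3) {                                      # rotations
    v <- t(apply(ctr, 1, function(r) .cross3(axes[ax, ], r)))
    B[, 3 + ax] <- as.vector(t(v))
  }
  qr.Q(qr(B))[, 1:6, drop = FALSE]
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
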