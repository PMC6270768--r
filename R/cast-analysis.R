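# Cast descriptors: latent-force maps and gyration-tensor shape measures.

#' Latent-force map at an activation event
#'
#' The latent particles present during a given accumulation interval,
#' with their positions and accumulated force scalars — the data behind
#' force-coloured latent-shell renderings (growth happens where the
#' pocket presses least).
#'
#' @param cast An `asp_cast`.
#' @param event Activation event index (1-based; event k is the interval
#'   whose lowest-force latent became cast member k+1).
#' @return Tibble: `particle_id`, `x`, `y`, `z`, `force` (kcal/mol/A).
#' @export
latent_force_map <- function(cast, event) {
  n_ev <- nrow(cast$activation_log)
  if (event < 1 || event > n_ev) abort("event index out of range")
  tab <- cast$latent_force_tables[[event]]
  sites <- cast$grid$sites[tab$particle_id, ]
  tibble(particle_id = tab$particle_id,
         x = sites$x, y = sites$y, z = sites$z,
         force = tab$force)
}

.gyration_eigen <- function(xyz) {
  xyz <- sweep(xyz, 2, colMeans(xyz))
  S <- crossprod(xyz) / nrow(xyz)
  sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Cast shape descriptors
#'
#' Gyration-tensor eigenvalues of the cast particle positions, with the
#' derived asphericity (0 for a perfect sphere) and elongation (ratio of
#' largest to smallest eigenvalue). Globular casts have elongation near 1;
#' long flat casts have large elongation.
#'
#' @param x An `asp_cast`, or a plain coordinate matrix (n x 3).
#' @param event Optional activation event; default: the final cast.
#' @param positions `"lattice"` (activated lattice sites, default) or
#'   `"instantaneous"` (saved dynamical coordinates).
#' @return Tibble: `lambda1 >= lambda2 >= lambda3` (A^2),
#'   `asphericity = lambda1 - (lambda2 + lambda3) / 2`,
#'   `elongation = lambda1 / lambda3` (`Inf` for degenerate sets),
#'   `n_particles`.
#' @export
cast_shape <- function(x, event = NULL,
                       positions = c("lattice", "instantaneous")) {
  positions <- match.arg(positions)
  if (inherits(x, "asp_cast")) {
    n_ev <- nrow(x$activation_log)
    if (is.null(event)) event <- n_ev
    if (event < 1 || event > n_ev) abort("event index out of range")
    xyz <- if (positions == "lattice") {
      cast_lattice_positions(x, n_active = event + 1L)
    } else {
      x$active_positions[[event]]
    }
  } else {
    xyz <- as.matrix(x)
  }
  if (nrow(xyz) < 3) abort("cast_shape requires at least 3 particles")
  lam <- .gyration_eigen(xyz)
  tibble(
    lambda1 = lam[1], lambda2 = lam[2], lambda3 = lam[3],
    asphericity = lam[1] - (lam[2] + lam[3]) / 2,
    elongation = if (lam[3] > 1e-12) lam[1] / lam[3] else Inf,
    n_particles = nrow(xyz)
  )
}

#' Spatial extent of the cast along each axis
#'
#' @param cast An `asp_cast`.
#' @param event Optional activation event; default final.
#' @return Named numeric vector `c(x =, y =, z =)` of coordinate ranges
#'   (Angstrom) of the activated lattice sites.
#' @export
cast_extent <- function(cast, event = NULL) {
  n_ev <- nrow(cast$activation_log)
  if (is.null(event)) event <- n_ev
  xyz <- cast_lattice_positions(cast, n_active = event + 1L)
  c(x = diff(range(xyz[, 1])), y = diff(range(xyz[, 2])),
    z = diff(range(xyz[, 3])))
}

#' Principal growth axis of the cast
#'
#' Leading gyration-tensor eigenvector of the activated lattice sites: the
#' direction along which the cast has extended most.
#'
#' @param cast An `asp_cast`.
#' @param event Optional activation event; default final.
#' @return Unit 3-vector.
#' @export
cast_principal_axis <- function(cast, event = NULL) {
  n_ev <- nrow(cast$activation_log)
  if (is.null(event)) event <- n_ev
  xyz <- cast_lattice_positions(cast, n_active = event + 1L)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(xyz) / nrow(xyz), symmetric = TRUE)
  v <- ev$vectors[, 1]
  v / sqrt(sum(v^2))
}

#' @export
tidy.asp_cast <- function(x, ...) x$activation_log

#' @export
glance.asp_cast <- function(x, ...) {
  shp <- cast_shape(x)
  tibble(n_events = nrow(x$activation_log),
         n_active = nrow(x$activation_log) + 1L,
         status = x$status,
         elongation = shp$elongation, asphericity = shp$asphericity)
}
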