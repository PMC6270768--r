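# The pressurisation lattice: cubic grid of particles in three states
# (inactive / latent / active) grown outward from a seed site.

.STATE_INACTIVE <- 0L
.STATE_LATENT <- 1L
.STATE_ACTIVE <- 2L

#' Build a cubic particle grid around a point
#'
#' Constructs a cubic lattice of candidate cast particles centred on
#' `center`, with `floor(edge / spacing) + 1` points per axis. A warning is
#' issued when the box volume `edge^3` falls outside the working window of
#' 3375-8000 A^3 (large enough to envelope a binding site, small enough
#' that the cast does not reach the boundary during a standard run).
#'
#' @param center Centre of the box (3-vector, Angstrom), typically the
#'   binding-site centre.
#' @param edge Box edge length, Angstrom.
#' @param spacing Lattice spacing, Angstrom (default 1.1).
#' @param particle_mass Particle mass, Da (default 10).
#' @param restraint_k Harmonic anchor force constant tethering active
#'   particles to their lattice sites, kcal/mol/A^2 (default 0.1).
#' @return List of class `asp_grid`: `sites` tibble (`index`, `i`, `j`,
#'   `k`, `x`, `y`, `z`), integer `state` per site, and lattice metadata.
#' @export
build_grid <- function(center = c(0, 0, 0), edge = 15, spacing = 1.1,
                       particle_mass = 10, restraint_k = 0.1) {
  if (edge <= 0 || spacing <= 0) abort("build_grid: edge and spacing must be positive")
  if (particle_mass <= 0) abort("build_grid: particle_mass must be positive")
  if (restraint_k < 0) abort("build_grid: restraint_k must be >= 0")
  vol <- edge^3
  if (vol < 3375 || vol > 8000) {
    warn(sprintf("box volume %.0f A^3 outside the working window [3375, 8000] A^3", vol))
  }
  m <- floor(edge / spacing) + 1
  ax <- (seq_len(m) - 1 - (m - 1) / 2) * spacing
  g <- expand.grid(i = seq_len(m), j = seq_len(m), k = seq_len(m))
  sites <- tibble(
    index = seq_len(nrow(g)),
    i = g$i, j = g$j, k = g$k,
    x = center[1] + ax[g$i],
    y = center[2] + ax[g$j],
    z = center[3] + ax[g$k]
  )
  structure(
    list(sites = sites, state = rep(.STATE_INACTIVE, nrow(sites)),
         n_axis = c(m, m, m), spacing = spacing, center = center,
         particle_mass = particle_mass, restraint_k = restraint_k,
         seed_index = NA_integer_),
    class = "asp_grid"
  )
}

#' @export
print.asp_grid <- function(x, ...) {
  cat("<asp_grid> ", paste(x$n_axis, collapse = " x "), " sites at ",
      x$spacing, " A spacing; active ", sum(x$state == .STATE_ACTIVE),
      ", latent ", sum(x$state == .STATE_LATENT), "\n", sep = "")
  invisible(x)
}

.lattice_linear <- function(g, ijk) {
  nx <- g$n_axis[1]; ny <- g$n_axis[2]
  (ijk[3] - 1L) * nx * ny + (ijk[2] - 1L) * nx + ijk[1]
}

.lattice_neighbors <- function(g, index, adjacency = 6) {
  s <- g$sites[index, ]
  if (adjacency == 6) {
    off <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                 c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  } else if (adjacency == 26) {
    off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  } else {
    abort("adjacency must be 6 or 26")
  }
  ii <- s$i + off[, 1]; jj <- s$j + off[, 2]; kk <- s$k + off[, 3]
  ok <- ii >= 1 & ii <= g$n_axis[1] & jj >= 1 & jj <= g$n_axis[2] &
    kk >= 1 & kk <= g$n_axis[3]
  if (!any(ok)) return(integer(0))
  as.integer(vapply(which(ok),
                    function(r) .lattice_linear(g, c(ii[r], jj[r], kk[r])),
                    numeric(1)))
}

#' Seed the cast
#'
#' Activates a single grid particle (the first cast member) and marks its
#' lattice neighbours latent; all other particles remain inactive.
#'
#' @param g An `asp_grid` with no active particles.
#' @param seed Lattice triple `c(i, j, k)`, or `"center"` (default) for the
#'   site nearest the box centre.
#' @param adjacency Lattice connectivity, 6 (face neighbours, default)
#'   or 26.
#' @return The updated `asp_grid`.
#' @export
seed_cast <- function(g, seed = "center", adjacency = 6) {
  if (any(g$state != .STATE_INACTIVE)) abort("grid is already seeded")
  if (identical(seed, "center")) {
    seed <- rep(ceiling(g$n_axis[1] / 2), 3)
  }
  seed <- as.integer(seed)
  if (length(seed) != 3 || any(seed < 1) || any(seed > g$n_axis)) {
    abort("seed lattice triple outside the grid")
  }
  idx <- .lattice_linear(g, seed)
  g$state[idx] <- .STATE_ACTIVE
  nb <- .lattice_neighbors(g, idx, adjacency)
  g$state[nb] <- .STATE_LATENT
  g$seed_index <- idx
  g$adjacency <- adjacency
  g
}

#' Activate the latent particle under least force
#'
#' Switches the latent particle with the smallest accumulated force to
#' active and promotes its inactive lattice neighbours to latent. Exact
#' ties resolve to the lowest linear lattice index.
#'
#' @param g A seeded `asp_grid`.
#' @param accumulated Named numeric vector of accumulated force scalars,
#'   one per latent particle (names = lattice indices), or an unnamed
#'   vector ordered by increasing lattice index.
#' @return List with the updated `grid` and the activated `particle_id`.
#' @export
activate_lowest <- function(g, accumulated) {
  latent <- which(g$state == .STATE_LATENT)
  if (length(latent) == 0L) abort("no latent particles to activate")
  if (!is.null(names(accumulated))) {
    ids <- as.integer(names(accumulated))
    if (!setequal(ids, latent)) abort("accumulated forces must cover exactly the latent set")
    accumulated <- accumulated[match(latent, ids)]
  } else if (length(accumulated) != length(latent)) {
    abort("accumulated forces must cover exactly the latent set")
  }
  winner <- latent[which.min(accumulated)]  # latent sorted -> lowest index wins ties
  g$state[winner] <- .STATE_ACTIVE
  nb <- .lattice_neighbors(g, winner, if (is.null(g$adjacency)) 6 else g$adjacency)
  nb <- nb[g$state[nb] == .STATE_INACTIVE]
  g$state[nb] <- .STATE_LATENT
  list(grid = g, particle_id = winner)
}

#' Grid sites with their current state
#'
#' @param g An `asp_grid`.
#' @return The `sites` tibble with a `state` factor column
#'   (inactive/latent/active).
#' @export
grid_sites <- function(g) {
  dplyr::mutate(g$sites, state = factor(
    c("inactive", "latent", "active")[g$state + 1L],
    levels = c("inactive", "latent", "active")))
}
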