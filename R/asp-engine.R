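# The pressurisation engine: restrained Langevin dynamics of the protein
# (elastic network) plus the active particle cast; forces on latent grid
# particles are accumulated over each interval and the lowest-force latent
# is activated, one per interval.

#' Simulation configuration
#'
#' Defaults are the standard pressurisation protocol: 1 fs step, one
#' activation per 1 ps over a 400 ps run at 300 K, with an initial heating
#' ramp (0 to 300 K, protein restraints released 100 to 0 kcal/mol/A^2)
#' over 115 ps before pressurisation starts. Snapshots are saved once per
#' activation interval.
#'
#' @param dt Integration time step, fs (default 1).
#' @param duration Pressurisation run length, ps (default 400).
#' @param activation_interval Time between particle activations, ps
#'   (default 1); must divide `duration`.
#' @param temperature Target temperature, K (default 300).
#' @param ramp_time Heating/restraint-release ramp length, ps (default 115).
#' @param thermostat_friction Langevin collision frequency, 1/ps (default 1).
#' @param seed Integer RNG seed recorded into all outputs.
#' @param thermostat `"langevin"` (default) or `"none"` (NVE).
#' @param adjacency Lattice connectivity for cast growth, 6 or 26.
#' @param particle_lj Whether particle-particle LJ acts (default `TRUE`).
#' @param latent_feel_active Whether latent probes feel LJ forces from
#'   active cast particles as well as from the protein (default `TRUE`).
#' @param ramp_restraint_k Initial protein restraint during the ramp,
#'   kcal/mol/A^2 (default 100, released linearly to 0).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(dt = 1, duration = 400, activation_interval = 1,
                       temperature = 300, ramp_time = 115,
                       thermostat_friction = 1, seed = 1L,
                       thermostat = c("langevin", "none"),
                       adjacency = 6, particle_lj = TRUE,
                       latent_feel_active = TRUE, ramp_restraint_k = 100) {
  thermostat <- match.arg(thermostat)
  if (dt <= 0) abort("sim_config: dt must be positive")
  if (duration <= 0 || activation_interval <= 0) {
    abort("sim_config: duration and activation_interval must be positive")
  }
  n_events <- duration / activation_interval
  if (abs(n_events - round(n_events)) > 1e-9) {
    abort("sim_config: activation_interval must divide duration")
  }
  steps <- activation_interval * 1000 / dt
  if (abs(steps - round(steps)) > 1e-9) {
    abort("sim_config: dt must divide activation_interval")
  }
  structure(list(
    dt = dt, duration = duration, activation_interval = activation_interval,
    temperature = temperature, ramp_time = ramp_time,
    thermostat_friction = thermostat_friction, seed = as.integer(seed),
    thermostat = thermostat, adjacency = adjacency,
    particle_lj = isTRUE(particle_lj),
    latent_feel_active = isTRUE(latent_feel_active),
    ramp_restraint_k = ramp_restraint_k,
    n_events = as.integer(round(n_events)),
    steps_per_interval = as.integer(round(steps))
  ), class = "sim_config")
}

#' Integrate restrained dynamics
#'
#' Velocity-Verlet (BAOAB-split Langevin when a thermostat is active)
#' propagation of the interacting system described by a [force_spec()].
#' Temperature and anchor force constants can be ramped linearly across the
#' call, which implements the heating/restraint-release phase.
#'
#' @param positions,velocities Matrices (n x 3); `velocities = NULL` starts
#'   at rest.
#' @param mass Per-particle masses, Da (recycled).
#' @param spec A [force_spec()].
#' @param n_steps Number of steps.
#' @param dt Time step, fs.
#' @param thermostat `"none"` (NVE) or `"langevin"`.
#' @param friction Langevin collision frequency, 1/ps.
#' @param temperature Target temperature, K; `temperature_start` permits a
#'   linear ramp (defaults to `temperature`).
#' @param temperature_start Start temperature for a ramp, K.
#' @param anchor_k_end Optional per-particle anchor constants at the end of
#'   the call (linear release/tightening); default: unchanged.
#' @param mobile Logical per particle; fixed particles do not move
#'   (default: all mobile).
#' @param probes Optional fixed probe positions (m x 3): the mean net LJ
#'   force magnitude on each probe over the call is returned.
#' @param probe_feel_particles Whether probes feel LJ from mobile particles
#'   of kind "particle" in addition to the protein.
#' @return List with `positions`, `velocities`, `probe_mean_force`,
#'   `energy` (final potential energy) and `ok`.
#' @export
integrate_dynamics <- function(positions, velocities = NULL, mass, spec,
                               n_steps, dt = 1,
                               thermostat = c("none", "langevin"),
                               friction = 1, temperature = 300,
                               temperature_start = temperature,
                               anchor_k_end = NULL, mobile = NULL,
                               probes = NULL, probe_feel_particles = TRUE) {
  thermostat <- match.arg(thermostat)
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  if (nrow(velocities) != n) abort("positions and velocities differ in length")
  if (length(spec$kind) != n) abort("force_spec does not match particle count")
  mass <- rep_len(mass, n)
  if (is.null(mobile)) mobile <- rep(TRUE, n)
  if (is.null(anchor_k_end)) anchor_k_end <- spec$anchor_k
  if (is.null(probes)) probes <- matrix(0, 0, 3)
  sp <- .spec_springs(spec)
  lj <- spec$lj
  out <- cpp_integrate(
    positions, velocities, mass, mobile, spec$kind,
    sp$i, sp$j, sp$r0, sp$k,
    spec$anchors, spec$anchor_k, rep_len(anchor_k_end, n),
    lj$eps, lj$rmin, lj$eps, lj$rmin_ap, lj$cutoff, spec$particle_lj,
    lj$core_frac, lj$protein_wca, dt / 1000, as.integer(n_steps), thermostat == "langevin", friction,
    temperature_start, temperature,
    as.matrix(probes), probe_feel_particles
  )
  if (!out$ok) {
    abort("integration produced non-finite coordinates (time step too large or severe particle overlap)")
  }
  names(out)[names(out) == "pos"] <- "positions"
  names(out)[names(out) == "vel"] <- "velocities"
  out
}

#' Accumulate forces on latent particles
#'
#' Runs the dynamical system for one interval and returns, for each latent
#' probe position, the time-average of the net force magnitude it
#' experiences (kcal/mol/A). Probes are held fixed and exert no reaction
#' force: they measure how hard the surrounding matter presses on each
#' candidate lattice site.
#'
#' @inheritParams integrate_dynamics
#' @param probes Latent probe positions (m x 3), m >= 1.
#' @param interval Accumulation interval, ps.
#' @return Numeric vector of mean force magnitudes, one per probe.
#' @export
accumulate_latent_forces <- function(positions, velocities = NULL, mass, spec,
                                     probes, interval, dt = 1,
                                     thermostat = "none", friction = 1,
                                     temperature = 300,
                                     probe_feel_particles = TRUE) {
  probes <- as.matrix(probes)
  if (nrow(probes) == 0L) abort("accumulate_latent_forces: empty latent set")
  n_steps <- round(interval * 1000 / dt)
  out <- integrate_dynamics(positions, velocities, mass, spec,
                            n_steps = n_steps, dt = dt,
                            thermostat = thermostat, friction = friction,
                            temperature = temperature, probes = probes,
                            probe_feel_particles = probe_feel_particles)
  out$probe_mean_force
}

#' Run a pressurisation simulation
#'
#' Grows a particle cast inside the pocket of `protein`: after a heating
#' ramp (temperature 0 to `config$temperature`, protein restraints released
#' linearly to zero), the engine repeatedly (i) integrates the protein +
#' active-particle system for one activation interval while accumulating
#' the mean force magnitude on every latent lattice probe, (ii) activates
#' the latent particle under least force (ties to the lowest lattice
#' index), and (iii) promotes its inactive lattice neighbours to latent.
#' One particle is activated per interval; protein coordinates are saved
#' once per interval.
#'
#' @param protein A `pc_structure` (the pocket), or `NULL` for a
#'   protein-free run.
#' @param enm An `enm_model` over `protein` (ignored when `protein` is
#'   `NULL`); defaults to `build_enm(protein)`.
#' @param grid A seeded [build_grid()]/[seed_cast()] lattice.
#' @param config A [sim_config()].
#' @param lj An [lj_params()] set.
#' @return List of class `asp_run`: `cast` (an `asp_cast`), `trajectory`
#'   (an `md_trajectory` of protein coordinates, `NULL` without protein),
#'   `grid`, `config`, and `status` (`"completed"` or
#'   `"frontier_exhausted"`).
#' @export
run_asp <- function(protein, enm = NULL, grid, config = sim_config(),
                    lj = lj_params()) {
  if (is.na(grid$seed_index)) abort("run_asp: grid must be seeded (seed_cast)")
  if (!is.null(protein) && is.null(enm)) enm <- build_enm(protein)
  set.seed(config$seed)

  prot_xyz <- if (is.null(protein)) matrix(0, 0, 3) else coords(protein)
  n_prot <- nrow(prot_xyz)
  prot_mass <- if (n_prot) protein$mass else numeric(0)

  g <- grid
  active_ids <- g$seed_index                      # activation order, seed first
  site_xyz <- as.matrix(g$sites[, c("x", "y", "z")])

  pos <- rbind(prot_xyz, site_xyz[active_ids, , drop = FALSE])
  vel <- matrix(0, nrow(pos), 3)
  langevin <- config$thermostat == "langevin"

  make_spec <- function(prot_anchor_k) {
    n_act <- length(active_ids)
    force_spec(
      kind = c(rep(0L, n_prot), rep(1L, n_act)),
      enm = enm,
      lj = lj,
      anchors = rbind(prot_xyz, site_xyz[active_ids, , drop = FALSE]),
      anchor_k = c(rep(prot_anchor_k, n_prot), rep(g$restraint_k, n_act)),
      particle_lj = config$particle_lj
    )
  }
  mass_vec <- function() c(prot_mass, rep(g$particle_mass, length(active_ids)))

  # Heating ramp with restraint release
  if (config$ramp_time > 0) {
    spec <- make_spec(config$ramp_restraint_k)
    out <- integrate_dynamics(
      pos, vel, mass_vec(), spec,
      n_steps = round(config$ramp_time * 1000 / config$dt), dt = config$dt,
      thermostat = if (langevin) "langevin" else "none",
      friction = config$thermostat_friction,
      temperature = config$temperature, temperature_start = 0,
      anchor_k_end = c(rep(0, n_prot), rep(g$restraint_k, length(active_ids)))
    )
    pos <- out$positions; vel <- out$velocities
  }

  n_events <- config$n_events
  log_rows <- vector("list", n_events)
  latent_tables <- vector("list", n_events)
  frames <- vector("list", n_events)
  cast_snapshots <- vector("list", n_events)
  status <- "completed"
  events_done <- 0L

  for (ev in seq_len(n_events)) {
    latent <- which(g$state == .STATE_LATENT)
    if (length(latent) == 0L) { status <- "frontier_exhausted"; break }
    spec <- make_spec(0)
    out <- integrate_dynamics(
      pos, vel, mass_vec(), spec,
      n_steps = config$steps_per_interval, dt = config$dt,
      thermostat = if (langevin) "langevin" else "none",
      friction = config$thermostat_friction,
      temperature = config$temperature,
      probes = site_xyz[latent, , drop = FALSE],
      probe_feel_particles = config$latent_feel_active
    )
    pos <- out$positions; vel <- out$velocities
    acc <- out$probe_mean_force

    act <- activate_lowest(g, setNames(acc, latent))
    g <- act$grid
    winner <- act$particle_id

    t_now <- ev * config$activation_interval
    site <- g$sites[winner, ]
    log_rows[[ev]] <- tibble(
      event = ev, time_ps = t_now, particle_id = winner,
      i = site$i, j = site$j, k = site$k,
      accumulated_force = acc[match(winner, latent)]
    )
    latent_tables[[ev]] <- tibble(particle_id = latent, force = acc)
    if (n_prot) frames[[ev]] <- pos[seq_len(n_prot), , drop = FALSE]
    cast_snapshots[[ev]] <- pos[n_prot + seq_along(active_ids), , drop = FALSE]

    # new particle joins at its lattice anchor, at rest
    active_ids <- c(active_ids, winner)
    pos <- rbind(pos, site_xyz[winner, , drop = FALSE])
    vel <- rbind(vel, c(0, 0, 0))
    events_done <- ev
  }

  keep <- seq_len(events_done)
  cast <- structure(list(
    activation_log = dplyr::bind_rows(log_rows[keep]),
    latent_force_tables = latent_tables[keep],
    active_positions = cast_snapshots[keep],
    active_ids = active_ids,
    grid = g, seed_index = grid$seed_index, status = status,
    seed = config$seed
  ), class = "asp_cast")

  trajectory <- NULL
  if (n_prot && events_done > 0) {
    arr <- array(0, dim = c(events_done, n_prot, 3))
    for (f in keep) arr[f, , ] <- frames[[f]]
    trajectory <- as_trajectory(arr,
                                times = keep * config$activation_interval,
                                atoms = protein)
  }

  structure(list(cast = cast, trajectory = trajectory, grid = g,
                 config = config, status = status),
            class = "asp_run")
}

#' @export
print.asp_cast <- function(x, ...) {
  cat("<asp_cast> ", nrow(x$activation_log), " activation events (+ seed); status: ",
      x$status, "\n", sep = "")
  invisible(x)
}

#' @export
print.asp_run <- function(x, ...) {
  cat("<asp_run> ", nrow(x$cast$activation_log), " events; status ", x$status,
      if (!is.null(x$trajectory)) paste0("; ", dim(x$trajectory$coords)[1],
                                         " saved frames"), "\n", sep = "")
  invisible(x)
}

#' Lattice anchor positions of the activated cast particles
#'
#' @param cast An `asp_cast`.
#' @param n_active Use only the first `n_active` cast members (seed
#'   included); default all.
#' @return Matrix of lattice coordinates (n x 3).
#' @export
cast_lattice_positions <- function(cast, n_active = NULL) {
  ids <- cast$active_ids
  if (!is.null(n_active)) ids <- ids[seq_len(n_active)]
  as.matrix(cast$grid$sites[ids, c("x", "y", "z")])
}
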