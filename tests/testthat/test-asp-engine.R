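# Grid bookkeeping, integrator physics, latent-force accumulation, and the
# pressurisation scheduler.

test_that("build_grid sizes the lattice from edge and spacing", {
  g <- build_grid(edge = 15, spacing = 1.1)
  expect_equal(g$n_axis, c(14, 14, 14))  # floor(15 / 1.1) + 1
  expect_equal(nrow(g$sites), 2744L)
  expect_equal(sort(unique(round(diff(sort(unique(g$sites$x))), 9))), 1.1)
  # centred on the requested point
  expect_equal(colMeans(as.matrix(g$sites[, c("x", "y", "z")])), c(0, 0, 0),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("build_grid warns outside the working volume window", {
  expect_warning(build_grid(edge = 10), "volume")
  expect_warning(build_grid(edge = 25), "volume")
  expect_silent(build_grid(edge = 15))
  g <- suppressWarnings(build_grid(edge = 15, spacing = 20))
  expect_equal(nrow(g$sites), 1L)
  expect_error(build_grid(edge = -1), "positive")
  expect_error(build_grid(edge = 15, spacing = 0), "positive")
})

test_that("seeding activates one particle and marks face neighbours latent", {
  g <- suppressWarnings(build_grid(edge = 5.5, spacing = 1.1))  # 6^3
  gi <- seed_cast(g, seed = c(3, 3, 3))
  expect_equal(sum(gi$state == 2L), 1L)
  expect_equal(sum(gi$state == 1L), 6L)
  gc <- seed_cast(g, seed = c(1, 1, 1))
  expect_equal(sum(gc$state == 1L), 3L)
  gf <- seed_cast(g, seed = c(1, 3, 3))
  expect_equal(sum(gf$state == 1L), 5L)
  expect_error(seed_cast(gi), "already seeded")
  expect_error(seed_cast(g, seed = c(9, 1, 1)), "outside")
})

test_that("activation picks the lowest force with index tie-break", {
  g <- seed_cast(suppressWarnings(build_grid(edge = 5.5, spacing = 1.1)),
                 seed = c(3, 3, 3))
  latent <- which(g$state == 1L)
  acc <- setNames(c(0.5, 0.2, 0.9, 0.4, 0.8, 0.7), latent)
  out <- activate_lowest(g, acc)
  expect_equal(out$particle_id, latent[2])
  # exact tie: lowest linear lattice index wins
  acc_tie <- setNames(rep(1, 6), latent)
  expect_equal(activate_lowest(g, acc_tie)$particle_id, min(latent))
  # frontier update: previously inactive neighbours of the winner are latent
  win <- out$particle_id
  g2 <- out$grid
  nb <- pocketcast:::.lattice_neighbors(g2, win)
  expect_true(all(g2$state[nb] %in% c(1L, 2L)))
  expect_error(activate_lowest(g, setNames(1, latent[1])), "latent set")
})

test_that("zero-force motion is exactly uniform and linear", {
  spec <- force_spec(kind = 1L, particle_lj = FALSE)
  out <- integrate_dynamics(matrix(c(0, 0, 0), 1), matrix(c(1, 2, -1), 1),
                            mass = 10, spec, n_steps = 100, dt = 1)
  expect_equal(out$positions[1, ], c(1, 2, -1) * 0.1, tolerance = 1e-12)
})

test_that("harmonic oscillation period matches the closed form within 1%", {
  spec <- force_spec(kind = 1L, anchors = matrix(0, 1, 3), anchor_k = 1,
                     particle_lj = FALSE)
  pos <- matrix(c(1, 0, 0), 1); vel <- matrix(0, 1, 3)
  xs <- numeric(10000)
  for (i in seq_len(10000)) {
    st <- integrate_dynamics(pos, vel, 10, spec, n_steps = 1, dt = 1)
    pos <- st$positions; vel <- st$velocities
    xs[i] <- pos[1, 1]
  }
  crossings <- which(diff(sign(xs)) < 0)
  period_ps <- mean(diff(crossings)) / 1000
  expected <- 2 * pi * sqrt(10 / (1 * 418.4))  # m/k in internal units
  expect_equal(period_ps, expected, tolerance = 0.01)
})

test_that("NVE energy drift of an LJ dimer stays below 1e-3 kcal/mol", {
  spec <- force_spec(kind = c(1L, 1L), lj = lj_params(eps = 0.1, rmin = 1.4))
  pos <- rbind(c(0, 0, 0), c(1.6, 0, 0))
  kinetic <- function(v) 0.5 * sum(10 * rowSums(v^2)) / 418.4
  e0 <- total_forces(pos, spec)$energy
  out <- integrate_dynamics(pos, NULL, 10, spec, n_steps = 10000, dt = 1,
                            thermostat = "none")
  e1 <- out$energy + kinetic(out$velocities)
  expect_lt(abs(e1 - e0), 1e-3)
})

test_that("langevin integration is deterministic given the R seed", {
  spec <- force_spec(kind = c(1L, 1L), anchors = matrix(0, 2, 3),
                     anchor_k = 0.1)
  pos <- rbind(c(0, 0, 0), c(1.6, 0, 0))
  set.seed(99)
  a <- integrate_dynamics(pos, NULL, 10, spec, 500, dt = 1,
                          thermostat = "langevin", temperature = 300)
  set.seed(99)
  b <- integrate_dynamics(pos, NULL, 10, spec, 500, dt = 1,
                          thermostat = "langevin", temperature = 300)
  expect_identical(a$positions, b$positions)
})

test_that("latent probes accumulate distance-monotone, symmetric forces", {
  prot <- tiny_structure(matrix(c(0, 0, 0), 1), mass = 100)
  spec <- force_spec(kind = 0L, lj = lj_params())
  rmin_ap <- lj_params()$rmin_ap
  probes <- rbind(c(0.5 * rmin_ap, 0, 0),
                  c(2 * rmin_ap, 0, 0),
                  c(25, 0, 0),
                  c(-0.5 * rmin_ap, 0, 0))
  acc <- accumulate_latent_forces(coords(prot), NULL, 100, spec,
                                  probes = probes, interval = 0.05)
  expect_gt(acc[1], acc[2])          # overlap presses harder than contact+
  expect_lt(acc[3], 1e-4)            # beyond cutoff: nothing
  expect_equal(acc[1], acc[4], tolerance = 1e-6)  # mirror symmetry
  expect_error(accumulate_latent_forces(coords(prot), NULL, 100, spec,
                                        probes = matrix(0, 0, 3),
                                        interval = 0.05), "empty latent")
})

test_that("a short pressurisation run honours the schedule contract", {
  run <- cached_small_run()
  cfg <- run$config
  expect_equal(nrow(run$cast$activation_log),
               cfg$duration / cfg$activation_interval)
  # active set after k events has k + 1 members (seed included)
  expect_equal(length(run$cast$active_ids),
               nrow(run$cast$activation_log) + 1L)
  expect_equal(run$status, "completed")
  # snapshots: one per interval, times strictly increasing
  expect_equal(dim(run$trajectory$coords)[1], nrow(run$cast$activation_log))
  expect_true(all(diff(run$cast$activation_log$time_ps) > 0))
})

test_that("cast growth is lattice-connected from the seed at every event", {
  run <- cached_small_run()
  g <- run$grid
  active <- run$cast$active_ids[1]
  for (ev in seq_len(nrow(run$cast$activation_log))) {
    new_id <- run$cast$active_ids[ev + 1L]
    nb <- pocketcast:::.lattice_neighbors(g, new_id)
    expect_true(any(nb %in% active),
                label = sprintf("event %d adjacent to cast", ev))
    active <- c(active, new_id)
  }
})

test_that("identical config and seed give bit-identical activation logs", {
  tp <- make_toy_pocket(n_shell_atoms = 40, cavity_radius = 3,
                        stiffness_ratio = 1, seed = 2)
  cfg <- sim_config(dt = 1, duration = 3, activation_interval = 0.25,
                    ramp_time = 0.5, seed = 7)
  g <- seed_cast(build_grid(c(0, 0, 0), edge = 15, spacing = 1.1))
  r1 <- run_asp(tp$structure, tp$enm, g, cfg)
  r2 <- run_asp(tp$structure, tp$enm, g, cfg)
  expect_identical(r1$cast$activation_log, r2$cast$activation_log)
})

test_that("frontier exhaustion stops the run early with explicit status", {
  g <- suppressWarnings(build_grid(edge = 2.2, spacing = 1.1))  # 3^3 lattice
  g <- seed_cast(g, seed = c(2, 2, 2))
  cfg <- sim_config(dt = 1, duration = 60, activation_interval = 0.25,
                    ramp_time = 0, seed = 1, thermostat = "none")
  run <- run_asp(NULL, NULL, g, cfg)
  expect_equal(run$status, "frontier_exhausted")
  expect_lt(nrow(run$cast$activation_log), 60)
  expect_equal(length(run$cast$active_ids), 27L)  # whole lattice consumed
})

test_that("protein-free growth is statistically isotropic", {
  centroids <- t(sapply(1:20, function(seed) {
    g <- seed_cast(suppressWarnings(build_grid(edge = 9.9, spacing = 1.1)))
    cfg <- sim_config(dt = 1, duration = 2, activation_interval = 0.05,
                      ramp_time = 0.2, seed = seed)
    run <- run_asp(NULL, NULL, g, cfg)
    colMeans(cast_lattice_positions(run$cast))
  }))
  bias <- sqrt(sum(colMeans(centroids)^2))
  expect_lt(bias, 1.1)  # mean displacement below one lattice spacing
})

test_that("sim_config validates its schedule invariants", {
  expect_error(sim_config(duration = 10, activation_interval = 3), "divide")
  expect_error(sim_config(dt = 0), "positive")
  expect_error(sim_config(dt = 300, activation_interval = 1), "divide")
  cfg <- sim_config(duration = 400, activation_interval = 1)
  expect_equal(cfg$n_events, 400L)
  expect_equal(cfg$steps_per_interval, 1000L)
})
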