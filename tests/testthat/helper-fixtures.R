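# Shared helpers: tiny structures and reusable simulation products.

tiny_structure <- function(xyz, mass = 12, name = "CA") {
  xyz <- as.matrix(xyz)
  as_structure(tibble::tibble(
    name = name, element = "C", res_name = "GLY",
    res_number = seq_len(nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], mass = mass
  ))
}

one_residue_structure <- function(res_name = "ALA", res_number = 5) {
  as_structure(tibble::tibble(
    name = c("N", "CA", "C", "O"),
    element = c("N", "C", "C", "O"),
    res_name = res_name, res_number = res_number,
    x = c(0, 1.46, 2.0, 1.4), y = c(0, 0, 1.42, 2.4), z = 0
  ))
}

random_cloud <- function(n, seed, scale = 3) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = scale), ncol = 3)
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Independent oracle: minimal RMSD over rotations by quaternion-grid search
# with local polish (generic optimiser over axis-angle), never Kabsch.
brute_force_rmsd <- function(mobile, reference, n_grid = 4000) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  rot_from_q <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), 3, 3, byrow = TRUE)
  }
  score_rot <- function(R) sqrt(mean(rowSums((a %*% R - b)^2)))
  set.seed(1234)
  best <- Inf; best_q <- c(1, 0, 0, 0)
  for (i in seq_len(n_grid)) {
    q <- stats::rnorm(4)
    s <- score_rot(rot_from_q(q))
    if (s < best) { best <- s; best_q <- q }
  }
  # polish over axis-angle perturbations of the best quaternion
  obj <- function(v) {
    dq <- c(1, v / 2)
    q0 <- best_q / sqrt(sum(best_q^2))
    # quaternion product dq * q0
    w1 <- dq[1]; v1 <- dq[2:4]; w2 <- q0[1]; v2 <- q0[2:4]
    q <- c(w1 * w2 - sum(v1 * v2), w1 * v2 + w2 * v1 +
             c(v1[2] * v2[3] - v1[3] * v2[2],
               v1[3] * v2[1] - v1[1] * v2[3],
               v1[1] * v2[2] - v1[2] * v2[1]))
    score_rot(rot_from_q(q))
  }
  opt <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  min(best, opt$value)
}

# quick seeded pocket + grid + short run, memoised across tests
.run_cache <- new.env(parent = emptyenv())

cached_small_run <- function() {
  if (is.null(.run_cache$small)) {
    tp <- make_toy_pocket(n_shell_atoms = 60, cavity_radius = 3,
                          stiffness_ratio = 1, seed = 1)
    g <- seed_cast(build_grid(c(0, 0, 0), edge = 15, spacing = 1.1))
    cfg <- sim_config(dt = 1, duration = 8, activation_interval = 0.25,
                      ramp_time = 1, seed = 42)
    .run_cache$small <- run_asp(tp$structure, tp$enm, g, cfg)
  }
  .run_cache$small
}
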