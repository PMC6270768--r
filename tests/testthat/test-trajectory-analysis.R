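# Fluctuations, RMSD series, COM distances, histograms, stage
# segmentation, and cast descriptors.

make_traj <- function(frames_list, atoms = NULL, times = NULL) {
  nf <- length(frames_list)
  na <- nrow(frames_list[[1]])
  arr <- array(0, dim = c(nf, na, 3))
  for (f in seq_len(nf)) arr[f, , ] <- frames_list[[f]]
  as_trajectory(arr, times = times, atoms = atoms)
}

test_that("RMSF is zero for a static trajectory and exact for a two-state atom", {
  x <- random_cloud(8, seed = 1)
  t_static <- make_traj(list(x, x, x))
  expect_true(all(atomic_fluctuations(t_static, fit = FALSE)$rmsf == 0))
  expect_error(atomic_fluctuations(make_traj(list(x))), "2 frames")

  a <- 0.7
  up <- x; up[3, 1] <- up[3, 1] + a
  dn <- x; dn[3, 1] <- dn[3, 1] - a
  t2 <- make_traj(list(up, dn, up, dn))
  r <- atomic_fluctuations(t2, fit = FALSE)
  expect_equal(r$rmsf[3], a, tolerance = 1e-12)
  expect_true(all(r$rmsf[-3] == 0))
})

test_that("fitting removes rigid-body rotation from RMSF", {
  x <- random_cloud(10, seed = 2)
  frames <- lapply(1:6, function(i) x %*% random_rotation(i) + i * 0.5)
  t_rot <- make_traj(frames)
  expect_lt(max(atomic_fluctuations(t_rot, fit = TRUE)$rmsf), 1e-6)
})

test_that("rmsd_series starts at zero on its own first frame and tracks a linear path", {
  a <- random_cloud(12, seed = 3)
  b <- a + matrix(rnorm(36, sd = 1), ncol = 3)
  frames <- lapply(seq(0, 1, length.out = 8), function(w) (1 - w) * a + w * b)
  t_lin <- make_traj(frames)
  s <- rmsd_series(t_lin, list(initial = a), fit = FALSE)
  expect_equal(s$rmsd[1], 0, tolerance = 1e-12)
  expect_true(all(diff(s$rmsd) > 0))
  # repeated reference trajectory: all zeros
  t_rep <- make_traj(list(a, a, a))
  expect_true(all(rmsd_series(t_rep, a)$rmsd < 1e-9))
  # multiple references in one pass, long format
  s2 <- rmsd_series(t_lin, list(start = a, end = b))
  expect_setequal(unique(s2$reference), c("start", "end"))
  expect_equal(nrow(s2), 16L)
})

test_that("COM distances honour masses and reduce to hand computation", {
  atoms <- as_structure(tibble::tibble(
    name = c("CA", "CB", "CA"), element = "C", res_name = "GLY",
    res_number = c(1L, 1L, 2L),
    x = c(0, 2, 1), y = c(0, 0, 3), z = 0, mass = c(1, 1, 7)
  ))
  xyz <- coords(atoms)
  t1 <- make_traj(list(xyz, xyz), atoms = atoms)
  d <- com_distance_series(t1, 1, 2)
  expect_equal(d$distance, c(3, 3))  # COM (1,0,0) vs atom (1,3,0)
  expect_error(com_distance_series(t1, 1, 9), "residue 9")

  # 5-frame random fixture vs spreadsheet-style oracle
  set.seed(4)
  atoms5 <- as_structure(tibble::tibble(
    name = c("N", "CA", "C", "N", "CA"), element = c("N", "C", "C", "N", "C"),
    res_name = "ALA", res_number = c(1L, 1L, 1L, 2L, 2L),
    x = rnorm(5), y = rnorm(5), z = rnorm(5),
    mass = c(14, 12, 12, 14, 12)
  ))
  frames <- lapply(1:5, function(i) coords(atoms5) + matrix(rnorm(15), ncol = 3))
  t5 <- make_traj(frames, atoms = atoms5)
  d5 <- com_distance_series(t5, 1, 2)
  oracle <- vapply(frames, function(fr) {
    ca <- colSums(fr[1:3, ] * c(14, 12, 12)) / 38
    cb <- colSums(fr[4:5, ] * c(14, 12)) / 26
    sqrt(sum((ca - cb)^2))
  }, 1.0)
  expect_equal(d5$distance, oracle, tolerance = 1e-12)
  g <- glance(d5)
  expect_equal(g$mean, mean(oracle))
  expect_equal(g$sd, sd(oracle))
})

test_that("histogram probabilities sum to one and bin correctly", {
  h1 <- histogram_probability(c(2, 2, 2), bin_width = 0.5)
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$probability, 1)
  h2 <- histogram_probability(c(1, 2, 3, 4), bin_width = 0.8)
  expect_true(all(abs(h2$probability - 0.25) < 1e-12))
  expect_error(histogram_probability(c(1, 2), bin_width = 0), "positive")
  set.seed(5)
  x <- rnorm(300, mean = 4, sd = 1)
  h3 <- histogram_probability(x, bin_width = 0.3)
  expect_equal(sum(h3$probability), 1, tolerance = 1e-9)
})

test_that("histogram of a pocket-opening-like Gaussian sample recovers its mean", {
  set.seed(6)
  d <- rnorm(1e4, mean = 8.49, sd = 0.68)
  h <- histogram_probability(d, bin_width = 0.1)
  est <- sum(h$bin_mid * h$probability)
  expect_lt(abs(est - 8.49), 3 * 0.68 / sqrt(1e4) + 0.05)  # 3 se + half-bin
})

test_that("stage segmentation recovers planted breakpoints exactly", {
  # 4-piece continuous curve with distinct slopes, knots between samples
  slopes <- c(0.08, 0.02, 0.005, 0.03)
  knots <- c(40.5, 150.5, 260.5)          # knots fall between samples
  xs <- 1:400
  icepts <- numeric(4); icepts[1] <- 0
  for (p in 2:4) {
    icepts[p] <- icepts[p - 1] + (slopes[p - 1] - slopes[p]) * knots[p - 1]
  }
  seg_of <- findInterval(xs, knots) + 1
  ys <- icepts[seg_of] + slopes[seg_of] * xs
  fit <- segment_stages(data.frame(particle_count = xs, rmsd = ys),
                        n_segments = 4)
  expect_equal(fit$breakpoints, c(40, 150, 260))
  expect_lt(fit$total_sse, 1e-10)
})

test_that("stage segmentation degenerate cases and monotonicity", {
  xs <- 1:30
  line <- data.frame(x = xs, y = 2 + 0.5 * xs)
  expect_lt(segment_stages(line, n_segments = 1)$total_sse, 1e-12)
  set.seed(7)
  wig <- data.frame(x = 1:20, y = rnorm(20))
  expect_lt(segment_stages(wig, n_segments = 10)$total_sse, 1e-12)  # saturated
  sse <- vapply(1:5, function(k) segment_stages(wig, k)$total_sse, 1.0)
  expect_true(all(diff(sse) <= 1e-9))
  expect_error(segment_stages(wig[1:5, ], n_segments = 4), "at least")
})

test_that("latent force maps expose per-event probe forces", {
  run <- cached_small_run()
  m1 <- latent_force_map(run$cast, 1)
  expect_gte(nrow(m1), 6L)  # seeded frontier
  expect_true(all(m1$force >= 0))
  n_ev <- nrow(run$cast$activation_log)
  for (ev in c(1, n_ev)) {
    m <- latent_force_map(run$cast, ev)
    winner <- run$cast$activation_log$particle_id[ev]
    expect_equal(min(m$force), m$force[m$particle_id == winner])
  }
  expect_error(latent_force_map(run$cast, n_ev + 1), "out of range")
})

test_that("gyration shape descriptors behave on canonical point sets", {
  line <- cbind(seq(0, 10, length.out = 11), 0, 0)
  sl <- cast_shape(line)
  expect_equal(sl$lambda2, 0, tolerance = 1e-12)
  expect_equal(sl$lambda3, 0, tolerance = 1e-12)

  cube <- as.matrix(expand.grid(x = 1:5, y = 1:5, z = 1:5)) * 1.1
  sc <- cast_shape(cube)
  expect_equal(sc$lambda1, sc$lambda3, tolerance = 1e-9)
  expect_equal(sc$asphericity, 0, tolerance = 1e-9)

  slab <- as.matrix(expand.grid(x = 1:10, y = 1:3, z = 1:3)) * 1.1
  expect_gt(cast_shape(slab)$elongation, cast_shape(cube)$elongation)
  expect_error(cast_shape(line[1:2, ]), "3 particles")
})

test_that("trajectory multi-model PDB round-trips through the reader", {
  run <- cached_small_run()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(run$trajectory, path)
  t2 <- read_trajectory_pdb(path)
  expect_equal(dim(t2$coords)[1:2], dim(run$trajectory$coords)[1:2])
  expect_equal(t2$coords, run$trajectory$coords, tolerance = 2e-3)
})
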