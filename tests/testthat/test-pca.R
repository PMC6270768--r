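# Covariance PCA, variance fractions, eigenvector overlap, drift
# detection, per-mode fluctuation maps.

base50 <- random_cloud(50, seed = 100, scale = 5)

test_that("a single planted mode is recovered almost perfectly", {
  dirs <- random_orthonormal_modes(50, 1, seed = 1, base_coords = base50)
  t1 <- make_planted_trajectory(base50,
                                list(list(direction = dirs[, 1],
                                          amplitude = 1)),
                                n_frames = 200, noise_sd = 0, seed = 1)
  es <- fit_pca(t1, reference = base50)
  expect_gt(abs(sum(es$eigenvectors[, 1] * dirs[, 1])), 0.999)
  # essentially one nonzero eigenvalue
  expect_gt(es$eigenvalues[1] / sum(es$eigenvalues), 0.999)
})

test_that("eigenvalue sum equals total positional variance", {
  dirs <- random_orthonormal_modes(50, 3, seed = 2, base_coords = base50)
  modes <- lapply(1:3, function(m) list(direction = dirs[, m], amplitude = m))
  t3 <- make_planted_trajectory(base50, modes, n_frames = 150,
                                noise_sd = 0.05, seed = 3)
  es <- fit_pca(t3, reference = base50)
  X <- pocketcast:::.fit_frames_to(t3$coords, base50)
  flat <- matrix(X, nrow = 150)
  tr <- sum(apply(flat, 2, stats::var))
  expect_equal(sum(es$eigenvalues), tr, tolerance = 1e-8)
})

test_that("a two-frame trajectory has at most one nonzero eigenvalue", {
  arr <- array(0, dim = c(2, 10, 3))
  arr[1, , ] <- random_cloud(10, seed = 4)
  arr[2, , ] <- arr[1, , ] + random_cloud(10, seed = 5) * 0.1
  es <- fit_pca(as_trajectory(arr), reference = arr[1, , ])
  expect_lte(sum(es$eigenvalues > 1e-10 * max(es$eigenvalues)), 1L)
  expect_error(fit_pca(as_trajectory(arr[1, , , drop = FALSE])), "one frame")
})

test_that("variance fractions are cumulative ratios of eigenvalues", {
  es <- structure(list(eigenvalues = c(4, 3, 2, 1)), class = "eigen_system")
  expect_equal(variance_fraction(es, 2), 0.7)
  expect_equal(variance_fraction(es, 4), 1.0)
  fr <- vapply(1:4, function(k) variance_fraction(es, k), 1.0)
  expect_true(all(diff(fr) > 0))
  expect_error(variance_fraction(es, 0), "out of range")
  expect_error(variance_fraction(es, 5), "out of range")
})

test_that("PCA is invariant to a rigid transform of the whole trajectory", {
  dirs <- random_orthonormal_modes(30, 2, seed = 5,
                                   base_coords = base50[1:30, ])
  modes <- list(list(direction = dirs[, 1], amplitude = 2),
                list(direction = dirs[, 2], amplitude = 1))
  t0 <- make_planted_trajectory(base50[1:30, ], modes, n_frames = 120,
                                noise_sd = 0, seed = 6)
  R <- random_rotation(8)
  arr <- t0$coords
  for (f in seq_len(120)) arr[f, , ] <- arr[f, , ] %*% R + 5
  t_moved <- as_trajectory(arr, times = t0$times)
  e0 <- fit_pca(t0, reference = base50[1:30, ])
  e1 <- fit_pca(t_moved, reference = base50[1:30, ])
  expect_equal(e0$eigenvalues[1:2], e1$eigenvalues[1:2], tolerance = 1e-6)
})

test_that("overlap of a system with itself is the identity", {
  dirs <- random_orthonormal_modes(50, 3, seed = 7, base_coords = base50)
  modes <- lapply(1:3, function(m) list(direction = dirs[, m],
                                        amplitude = 4 / m))
  tt <- make_planted_trajectory(base50, modes, n_frames = 100,
                                noise_sd = 0.02, seed = 8)
  es <- fit_pca(tt, reference = base50)
  M <- overlap_matrix(es, es, n = 5)
  expect_equal(unclass(M), diag(nrow(M)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(M <= 1 + 1e-12))
})

test_that("mode swaps appear as permutation matrices and rotations as cosines", {
  es <- list(mask_length = 50, fit_reference = base50,
             eigenvalues = c(3, 2, 1),
             eigenvectors = random_orthonormal_modes(50, 3, seed = 9))
  class(es) <- "eigen_system"
  es_swap <- es
  es_swap$eigenvectors <- es$eigenvectors[, c(2, 1, 3)]
  M <- overlap_matrix(es, es_swap, n = 3)
  perm <- rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))
  expect_equal(unclass(M), perm, tolerance = 1e-10, ignore_attr = TRUE)

  theta <- 30 * pi / 180
  es_rot <- es
  es_rot$eigenvectors[, 1] <- cos(theta) * es$eigenvectors[, 1] +
    sin(theta) * es$eigenvectors[, 2]
  es_rot$eigenvectors[, 2] <- -sin(theta) * es$eigenvectors[, 1] +
    cos(theta) * es$eigenvectors[, 2]
  M2 <- overlap_matrix(es, es_rot, n = 2)
  expect_equal(unclass(M2),
               rbind(c(cos(theta), sin(theta)), c(sin(theta), cos(theta))),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("overlap refuses mismatched masks or fit references", {
  esA <- list(mask_length = 50, fit_reference = base50,
              eigenvectors = random_orthonormal_modes(50, 2, seed = 10),
              eigenvalues = c(2, 1))
  class(esA) <- "eigen_system"
  esB <- esA; esB$mask_length <- 40
  expect_error(overlap_matrix(esA, esB), "atom count")
  esC <- esA; esC$fit_reference <- base50 + 0.5
  expect_error(overlap_matrix(esA, esC), "reference")
})

test_that("drift detection prefers the monotone mode and ignores oscillations", {
  tt <- seq_len(400)
  sine <- sin(2 * pi * 5 * tt / 400)
  ramp <- seq(-1, 1, length.out = 400)
  res <- detect_drift_mode(cbind(sine, ramp), times = tt)
  expect_equal(res$mode, 2L)
  res2 <- detect_drift_mode(cbind(sine, sin(2 * pi * 3 * tt / 400)),
                            times = tt)
  expect_true(is.na(res2$mode))
  # constant projection treated as non-drifting, not an error
  res3 <- detect_drift_mode(cbind(rep(1, 400), sine), times = tt)
  expect_true(is.na(res3$mode))
})

test_that("mode fluctuation amplitudes square-sum to the eigenvalue", {
  n <- 20
  uniform <- rep(1 / sqrt(3 * n), 3 * n)
  es <- structure(list(eigenvalues = c(2.5), eigenvectors = cbind(uniform)),
                  class = "eigen_system")
  amp <- mode_rmsf(es, 1)
  expect_equal(sd(amp$amplitude), 0, tolerance = 1e-12)
  expect_equal(sum(amp$amplitude^2), 2.5, tolerance = 1e-8)
  # single-atom mode concentrates its amplitude there
  single <- rep(0, 3 * n); single[7:9] <- 1 / sqrt(3)
  es2 <- structure(list(eigenvalues = 1, eigenvectors = cbind(single)),
                   class = "eigen_system")
  amp2 <- mode_rmsf(es2, 1)
  expect_gt(amp2$amplitude[3]^2 / sum(amp2$amplitude^2), 0.99)
  expect_error(mode_rmsf(es2, 2), "out of range")
})
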