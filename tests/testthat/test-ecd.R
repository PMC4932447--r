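test_that("superposition removes rigid-body motion exactly", {
  set.seed(10)
  ref <- matrix(rnorm(12), 4, 3)
  co <- array(0, dim = c(5, 4, 3))
  for (f in 1:5) {
    R <- random_rotation()
    co[f, , ] <- sweep(ref %*% R, 2, rnorm(3), "+")
  }
  tr <- toy_traj(co)
  fitted <- superpose_frames(tr, fit_selection = "heavy")
  v <- apply(fitted$coords, c(2, 3), stats::var)
  expect_lt(max(v), 1e-20)
  # idempotence on an already superposed trajectory
  again <- superpose_frames(fitted, fit_selection = "heavy")
  expect_lt(max(abs(again$coords - fitted$coords)), 1e-12)
})

test_that("Kabsch fit recovers a known rotation and matches bio3d", {
  set.seed(11)
  P <- matrix(rnorm(12), 4, 3)
  R <- random_rotation()
  t <- c(0.3, -0.2, 0.5)
  Q <- sweep(P %*% R, 2, t, "+")
  k <- ecdyn:::kabsch(P, Q)
  expect_lt(max(abs(k$R - R)), 1e-10)
  expect_lt(max(abs(sweep(P %*% k$R, 2, k$t, "+") - Q)), 1e-10)
  # independent oracle: bio3d least-squares fit of the same pair
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(Q)),
                           mobile = as.vector(t(P)),
                           fixed.inds = 1:12, mobile.inds = 1:12)
  expect_lt(max(abs(matrix(fitted, ncol = 3, byrow = TRUE) - Q)), 1e-8)
  expect_error(superpose_frames(toy_traj(cbind(1:4, 0, 0)),
                                fit_selection = "heavy"), "collinear")
})

test_that("covariance of the coherent two-atom toy matches the closed form", {
  cv <- compute_covariance(two_atom_traj(+1), selection = "heavy",
                           method = "dense")
  C_exp <- matrix(0, 6, 6)
  C_exp[c(1, 4), c(1, 4)] <- 1
  expect_lt(max(abs(cv$covariance - C_exp)), 1e-12)
  expect_equal(cv$eigenvalues[1], 2, tolerance = 1e-12)
  expect_equal(cv$eigenvectors[, 1], c(1, 0, 0, 1, 0, 0) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(variance_captured(cv, 1), 1, tolerance = 1e-12)
  # constant trajectory: all-zero spectrum and undefined captured fraction
  co <- array(1, dim = c(3, 2, 3))
  cv0 <- compute_covariance(toy_traj(co), selection = "heavy")
  expect_lt(max(abs(cv0$eigenvalues)), 1e-15)
  expect_error(variance_captured(cv0, 1), "zero")
  expect_error(variance_captured(cv, 0), "3N")
})

test_that("projected images separate coherent from anti-correlated motion", {
  img_c <- project_images(compute_covariance(two_atom_traj(+1), "heavy"), 1)
  expect_lt(max(abs(img_c$images[1, ] - c(1 / sqrt(2), 0, 0))), 1e-10)
  expect_lt(max(abs(img_c$images[2, ] - c(1 / sqrt(2), 0, 0))), 1e-10)
  expect_equal(pair_correlations(img_c)$map[1, 2], 0, tolerance = 1e-10)
  img_a <- project_images(compute_covariance(two_atom_traj(-1), "heavy"), 1)
  expect_lt(max(abs(img_a$images[1, ] - c(1 / sqrt(2), 0, 0))), 1e-10)
  expect_lt(max(abs(img_a$images[2, ] + c(1 / sqrt(2), 0, 0))), 1e-10)
  expect_equal(pair_correlations(img_a)$map[1, 2], sqrt(2),
               tolerance = 1e-10)
  expect_error(project_images(compute_covariance(two_atom_traj(1), "heavy"),
                              5), "rank")
})

test_that("flexibility is the image distance to the C-alpha centroid", {
  img <- project_images(compute_covariance(two_atom_traj(-1), "heavy"), 1)
  fl <- flexibility_profile(img)
  # two atoms with images u, v: F = |u - v| / 2 for both
  expect_equal(fl$profile$F, rep(sqrt(2) / 2, 2), tolerance = 1e-10)
  # centroid deviation sums to zero
  dev <- sweep(img$images, 2, fl$centroid)
  expect_lt(max(abs(colSums(dev))), 1e-10)
  # identical images -> F identically zero
  fl0 <- flexibility_profile(
    project_images(compute_covariance(two_atom_traj(+1), "heavy"), 1))
  expect_lt(max(fl0$profile$F), 1e-10)
})

test_that("a global eigenvector sign flip leaves descriptors unchanged", {
  set.seed(12)
  tr <- random_traj(n_atoms = 5, n_frames = 8)
  cv <- compute_covariance(tr, "heavy", method = "dense")
  img <- project_images(cv, 3)
  cv_flipped <- cv
  cv_flipped$eigenvectors <- -cv$eigenvectors
  img2 <- project_images(cv_flipped, 3)
  expect_equal(pair_correlations(img2)$map, pair_correlations(img)$map,
               tolerance = 1e-12)
  expect_equal(flexibility_profile(img2)$profile$F,
               flexibility_profile(img)$profile$F, tolerance = 1e-12)
})

test_that("gram-matrix spectrum path agrees with the dense decomposition", {
  set.seed(13)
  tr <- random_traj(n_atoms = 8, n_frames = 5)  # rank-deficient: T < 3N
  dense <- compute_covariance(tr, "heavy", method = "dense")
  gram <- compute_covariance(tr, "heavy", method = "gram")
  r <- sum(gram$eigenvalues > max(gram$eigenvalues) * 1e-10)
  expect_equal(gram$eigenvalues[seq_len(r)], dense$eigenvalues[seq_len(r)],
               tolerance = 1e-8)
  expect_equal(gram$total_variance, dense$total_variance, tolerance = 1e-10)
  expect_lt(max(abs(abs(gram$eigenvectors[, seq_len(r)]) -
                      abs(dense$eigenvectors[, seq_len(r)]))), 1e-8)
  d1 <- pair_correlations(project_images(dense, r))$map
  d2 <- pair_correlations(project_images(gram, r))$map
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("segment averaging is the elementwise mean with retained scatter", {
  set.seed(14)
  segs <- list(random_traj(4, 6), random_traj(4, 6))
  for (s in 2) segs[[2]]$atoms <- segs[[1]]$atoms
  one <- average_descriptors(segs[1], selection = "heavy", k_max = 3,
                             which = "correlation", superpose = FALSE)
  single <- pair_correlations(
    project_images(compute_covariance(segs[[1]], "heavy"), 3))
  expect_equal(one$map, single$map, tolerance = 1e-12)
  both <- average_descriptors(segs, selection = "heavy", k_max = 3,
                              which = "correlation", superpose = FALSE)
  m2 <- pair_correlations(
    project_images(compute_covariance(segs[[2]], "heavy"), 3))
  expect_equal(both$map, (single$map + m2$map) / 2, tolerance = 1e-12)
  flx <- average_descriptors(segs, selection = "heavy", k_max = 3,
                             which = "flexibility", superpose = FALSE)
  expect_true(all(flx$profile$F_sd >= 0))
  segs[[2]]$atoms$atom_name[1] <- "CB"
  expect_error(average_descriptors(segs, selection = "heavy", k_max = 3),
               "atom tables")
})

test_that("k_max cutting a degenerate cluster warns", {
  # isotropic 2-frame toy: x and y fluctuations identical by symmetry
  co <- array(0, dim = c(4, 2, 3))
  co[, 1, 1] <- c(1, -1, 0, 0); co[, 2, 1] <- c(1, -1, 0, 0)
  co[, 1, 2] <- c(0, 0, 1, -1); co[, 2, 2] <- c(0, 0, 1, -1)
  tr <- toy_traj(co)
  cv <- compute_covariance(tr, "heavy", method = "dense")
  expect_warning(project_images(cv, 1), "degenerate")
})
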