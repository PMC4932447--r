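test_that("spring assignment separates blocks, linkers and couplings", {
  m <- block_linker_model(16)
  # linker sites carry a strictly lower summed stiffness than block sites
  deg <- numeric(16)
  for (r in seq_len(nrow(m$springs))) {
    deg[m$springs$i[r]] <- deg[m$springs$i[r]] + m$springs$k[r]
    deg[m$springs$j[r]] <- deg[m$springs$j[r]] + m$springs$k[r]
  }
  linker <- is.na(m$block_of)
  expect_true(max(deg[linker]) < min(deg[!linker]))
  # all-rigid 10-residue chain: connected, >= 9 springs
  m10 <- hnm_from_construct(build_extended_chain(poly_ala(10)))
  expect_gte(nrow(m10$springs), 9)
  expect_equal(max(ecdyn:::graph_components(10, m10$springs)), 1L)
})

test_that("two uncoupled chains are rejected as disconnected", {
  con <- assemble_construct("dimer", arrangement = "HH1",
                            sequence = poly_ala(8))
  expect_error(hnm_from_construct(con), "disconnected")
})

test_that("closed-form covariance obeys equipartition and linearity", {
  con <- build_extended_chain("AA")
  m1 <- hnm_from_construct(con, k_block = 100)
  eq1 <- equilibrium_covariance(m1)
  # relative coordinate u1 - u2: variance kT/k per axis
  w <- c(1, -1)
  Cs <- eq1$covariance[c(1, 4), c(1, 4)]     # x components of both sites
  expect_equal(drop(t(w) %*% Cs %*% w), m1$kT / 100, tolerance = 1e-12)
  # doubling every stiffness halves the covariance elementwise
  m2 <- hnm_from_construct(con, k_block = 200)
  eq2 <- equilibrium_covariance(m2)
  expect_equal(eq2$covariance, eq1$covariance / 2, tolerance = 1e-12)
})

test_that("long-run sample covariance matches the closed form (4-site chain)", {
  con <- build_extended_chain("AAAA")
  m <- hnm_from_construct(con, k_block = 100)
  eq <- equilibrium_covariance(m)
  n <- 50000
  tr <- simulate(m, seed = 5, n_frames = n, frame_interval = 2,
                 satellites = FALSE)
  cv <- compute_covariance(tr, selection = "calpha", method = "dense")
  # elementwise Monte-Carlo standard errors for Gaussian covariances;
  # 3.5 accounts for taking the max over 144 entries
  se <- sqrt((outer(diag(eq$covariance), diag(eq$covariance)) +
                eq$covariance^2) / n)
  expect_lt(max(abs(cv$covariance - eq$covariance) / se), 3.5)
  # mean structure unbiased within 3 standard errors
  se_mu <- sqrt(diag(eq$covariance) / n)
  dev_mu <- abs(as.vector(t(cv$mean_coords)) - as.vector(t(m$sites)))
  expect_lt(max(dev_mu / se_mu), 3)
})

test_that("simulation is reproducible and degenerates correctly", {
  m <- block_linker_model(8, blocks = c(1, 4, 6, 8))
  a <- simulate(m, seed = 3, n_frames = 50, frame_interval = 0.5)
  b <- simulate(m, seed = 3, n_frames = 50, frame_interval = 0.5)
  expect_identical(a$coords, b$coords)
  expect_false(identical(
    a$coords, simulate(m, seed = 4, n_frames = 50,
                       frame_interval = 0.5)$coords))
  expect_equal(attr(a, "sim_meta")$seed, 3)
  # kT -> 0: every frame equals the reference geometry
  m0 <- block_linker_model(8, blocks = c(1, 4, 6, 8), kT = 0, jitter_sd = 0)
  fr <- simulate(m0, seed = 1, n_frames = 5, frame_interval = 0.5,
                 satellites = FALSE)
  expect_lt(max(abs(sweep(fr$coords, c(2, 3), m0$sites))), 1e-12)
  expect_error(simulate(m, n_frames = 10), "seed")
  expect_error(simulate(m, seed = 1, n_frames = 1), "n_frames")
})

test_that("satellite atoms ride their residue site with bounded jitter", {
  m <- block_linker_model(6, blocks = c(1, 3, 5, 6), jitter_sd = 0.001)
  tr <- simulate(m, seed = 8, n_frames = 200, frame_interval = 0.5)
  expect_equal(nrow(tr$atoms), nrow(m$atoms))
  ca <- which(tr$atoms$is_calpha)
  # satellite displacement relative to its site stays near the reference
  soa <- m$site_of_atom
  sat <- which(!tr$atoms$is_calpha)[1]
  rel <- tr$coords[, sat, ] - tr$coords[, ca[soa[sat]], ]
  ref_rel <- m$ref_coords[sat, ] - m$sites[soa[sat], ]
  expect_lt(max(abs(sweep(rel, 2, ref_rel))), 6 * 0.001)
})

test_that("two independent seeds agree within segment-to-segment scatter", {
  m <- block_linker_model(12, blocks = c(1, 5, 8, 12))
  fits <- lapply(c(101, 202), function(s) {
    tr <- simulate(m, seed = s, n_frames = 10000, frame_interval = 0.5,
                   satellites = FALSE)
    ecd(tr, selection = "calpha", k_max = 6, window = 500, take_last = 5000,
        superpose = FALSE)
  })
  sem <- sqrt(fits[[1]]$map$sd^2 + fits[[2]]$map$sd^2) / sqrt(10)
  dev <- abs(fits[[1]]$map$map - fits[[2]]$map$map)
  ut <- upper.tri(dev)
  expect_lt(max(pmax(dev - 4 * sem, 0)[ut]), 0.05)
})
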