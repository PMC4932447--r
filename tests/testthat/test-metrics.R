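test_that("mean shortest-distance map averages the per-frame minima", {
  # two single-atom residues 0.4 nm apart in frame 1 and 0.6 nm in frame 2
  co <- array(0, dim = c(2, 2, 3))
  co[1, 2, 1] <- 0.4; co[2, 2, 1] <- 0.6
  dm <- mean_shortest_distance_map(toy_traj(co), selection = "heavy")
  expect_equal(dm$map[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(dm$map[2, 1], 0.5, tolerance = 1e-12)
  expect_equal(diag(dm$map), c(`A:1` = 0, `A:2` = 0))
  # fixed geometry: entry equals the static distance
  co2 <- array(0, dim = c(3, 2, 3)); co2[, 2, 2] <- 0.5
  dm2 <- mean_shortest_distance_map(toy_traj(co2), selection = "heavy")
  expect_equal(dm2$map[1, 2], 0.5, tolerance = 1e-12)
})

test_that("distance-map entries never increase when atoms are added", {
  set.seed(20)
  co <- array(rnorm(2 * 6 * 3, sd = 0.5), dim = c(2, 6, 3))
  tr <- toy_traj(co, atom_names = c("CA", "CB", "CG", "CA", "CB", "CG"))
  tr$atoms$residue_index <- c(1, 1, 1, 2, 2, 2)
  full <- mean_shortest_distance_map(tr, selection = "heavy")
  ca_only <- mean_shortest_distance_map(tr, selection = "calpha")
  expect_true(all(full$map[1, 2] <= ca_only$map[1, 2] + 1e-12))
})

test_that("RMSD traces honour superposition and the closed form", {
  set.seed(21)
  tr <- random_traj(n_atoms = 4, n_frames = 3)
  r <- rmsd_trace(tr, reference = 2)
  expect_equal(unname(r[2]), 0, tolerance = 1e-12)
  # rigid translation + rotation: zero after fitting
  co <- array(0, dim = c(2, 4, 3))
  co[1, , ] <- tr$coords[1, , ]
  co[2, , ] <- sweep(tr$coords[1, , ] %*% random_rotation(), 2, c(1, 2, 3), "+")
  expect_lt(max(rmsd_trace(toy_traj(co))), 1e-10)
  # two-frame hand case: after optimal fit of a 4-atom square stretched
  # symmetrically, rmsd = sqrt(mean(residual^2)) computed independently
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  sq2 <- rbind(c(-0.1, 0, 0), c(1.1, 0, 0), c(1.1, 1, 0), c(-0.1, 1, 0))
  co2 <- array(0, dim = c(2, 4, 3)); co2[1, , ] <- sq; co2[2, , ] <- sq2
  r2 <- rmsd_trace(toy_traj(co2))
  expect_equal(unname(r2[2]), 0.1, tolerance = 1e-12)  # pure x stretch
  # rigid motion of the whole trajectory leaves the trace unchanged
  R <- random_rotation()
  co3 <- co2
  for (f in 1:2) co3[f, , ] <- sweep(co2[f, , ] %*% R, 2, c(3, -1, 2), "+")
  expect_equal(unname(rmsd_trace(toy_traj(co3))), unname(r2),
               tolerance = 1e-10)
})

test_that("timelines parse, normalise blanks, and round-trip", {
  tl <- parse_dssp_timeline(matrix(c("E", "E", "E", "E"), 1, 4))
  expect_equal(as.vector(tl$codes), rep("E", 4))
  expect_error(parse_dssp_timeline(matrix("X", 1, 1)), "unknown")
  m <- rbind(c("H", "E", "-", "T"), c("H", "E", "C", "S"))
  tl2 <- parse_dssp_timeline(m, frame_times = c(0, 10))
  expect_equal(unname(tl2$codes[1, 3]), "C")
  p <- tempfile(fileext = ".tsv")
  write_ss_timeline(tl2, p)
  back <- parse_dssp_timeline(p)
  expect_equal(back$codes, tl2$codes)
  expect_equal(back$frame_times, tl2$frame_times)
})

test_that("occupancy thresholds are strict and classes sum to one", {
  codes <- matrix("C", 100, 3)
  codes[1:85, 1] <- "E"          # 85% extended strand
  codes[1:50, 2] <- "H"          # exactly 50% helix
  tl <- parse_dssp_timeline(codes, frame_times = seq_len(100) - 1)
  occ <- ss_occupancy(tl)
  expect_true(occ$table$stable_beta[1])
  expect_false(occ$table$stable_alpha[2])   # exactly 50% is not stable
  expect_false(any(occ$table$stable_beta[2:3]))
  expect_equal(unname(rowSums(as.matrix(occ$table[, ecdyn:::.ss_codes]))),
               rep(1, 3), tolerance = 1e-12)
  # all-coil residue: zero occupancy in every structured class
  expect_equal(occ$table$E[3] + occ$table$H[3], 0)
  expect_equal(occ$ranges$from, 1)
  expect_equal(occ$ranges$to, 1)
  # trailing-window restriction changes the statistics
  codes2 <- matrix("C", 100, 1)
  codes2[51:100, 1] <- "E"       # strand only in the second half
  occ2 <- ss_occupancy(parse_dssp_timeline(codes2,
                                           frame_times = seq_len(100) - 1),
                       window = 50)
  expect_true(occ2$table$stable_beta[1])
})

test_that("region annotation labels overlaps, including boundary spans", {
  codes <- matrix("C", 10, 100)
  codes[, 75:80] <- "E"     # stable strand inside the NAC core
  codes[, 2:6] <- "E"       # stable strand at the N terminus
  codes[, 94:98] <- "E"     # element spanning the NAC/C-terminal boundary
  tl <- parse_dssp_timeline(codes)
  occ <- annotate_regions(ss_occupancy(tl))
  rg <- occ$ranges
  expect_true(grepl("NAC", rg$regions[rg$from == 75]))
  expect_true(grepl("NAC-core", rg$regions[rg$from == 75]))
  expect_true(grepl("N-terminal", rg$regions[rg$from == 2]))
  both <- rg$regions[rg$from == 94]
  expect_true(grepl("NAC", both) && grepl("C-terminal", both))
  expect_error(annotate_regions(occ, regions = list(a = c(1, 5), a = c(6, 9))),
               "duplicate")
})
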