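test_that("PDB reading converts Angstrom to nanometres and flags C-alpha", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), p)
  tr <- read_structure(p)
  expect_equal(dim(tr$coords), c(1, 1, 3))
  expect_equal(as.numeric(tr$coords[1, 1, ]), c(0.1, 0.2, 0.3))
  expect_true(tr$atoms$is_calpha)
  expect_true(tr$atoms$is_heavy)
})

test_that("packaged alpha-synuclein fixture builds a 140-residue chain A", {
  con <- build_extended_chain(alpha_synuclein_sequence())
  p <- tempfile(fileext = ".pdb")
  write_trajectory(con$structure, p)
  tr <- read_structure(p)
  expect_equal(unique(tr$atoms$chain_id), "A")
  expect_equal(sum(tr$atoms$is_calpha), 140)
  expect_equal(length(unique(tr$atoms$residue_index)), 140)
})

test_that("HETATM-only input is rejected as empty", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"), p)
  expect_error(read_structure(p), "ATOM")
})

test_that("multi-model round trip preserves coordinates and metadata", {
  set.seed(42)
  tr <- random_traj(n_atoms = 4, n_frames = 3)
  p <- tempfile(fileext = ".pdb")
  write_trajectory(tr, p)
  back <- read_trajectory(p, frame_interval = tr$frame_interval)
  expect_equal(dim(back$coords), dim(tr$coords))
  expect_lt(max(abs(back$coords - tr$coords)), 1e-3)  # PDB precision, nm
  expect_identical(back$atoms$atom_name, tr$atoms$atom_name)
  expect_identical(back$atoms$residue_index, tr$atoms$residue_index)
  expect_identical(back$atoms$chain_id, tr$atoms$chain_id)
})

test_that("trajectory readers validate format and topology", {
  expect_error(read_trajectory(tempfile(fileext = ".xtc")), "not found")
  p <- tempfile(fileext = ".pdb")
  writeLines("END", p)
  f <- tempfile(fileext = ".xtc"); file.create(f)
  expect_error(read_trajectory(f, format = "xtc"), "XTC")
  # multi-frame input demands an explicit frame interval
  tr <- random_traj(n_atoms = 3, n_frames = 2)
  q <- tempfile(fileext = ".pdb")
  write_trajectory(tr, q)
  expect_error(read_trajectory(q), "frame_interval")
})

test_that("selections respect chemistry and compose as set operations", {
  co <- array(rnorm(2 * 5 * 3), dim = c(2, 5, 3))
  tr <- toy_traj(co, atom_names = c("N", "CA", "CB", "HB1", "HB2"))
  heavy <- select_atoms(tr, "heavy")
  expect_equal(heavy$indices, 1:3)
  expect_equal(select_atoms(tr, "calpha")$indices, 2L)
  # heavy union hydrogens = all atoms
  hyd <- which(!tr$atoms$is_heavy)
  expect_equal(sort(c(heavy$indices, hyd)), 1:5)
  # idempotence: re-selecting heavy from the heavy subset keeps every atom
  sub <- traj_subset(tr, heavy)
  expect_equal(select_atoms(sub, "heavy")$indices, seq_along(heavy$indices))
  expect_error(select_atoms(tr, "chain:Z"), "no atoms")
})

test_that("segment slicing covers exactly the trailing window in order", {
  co <- array(0, dim = c(100, 1, 3))
  co[, 1, 1] <- seq_len(100)   # frame index encoded in x
  tr <- toy_traj(co, dt = 100) # 10 000 ps total
  segs <- slice_segments(tr, window = 200, take_last = 10000)
  expect_length(segs, 50)
  expect_equal(unique(vapply(segs, n_frames, integer(1))), 2L)
  glued <- unlist(lapply(segs, function(s) s$coords[, 1, 1]))
  expect_equal(glued, as.numeric(seq_len(100)))
  # window == take_last -> one segment equal to the trailing window
  one <- slice_segments(tr, window = 400, take_last = 400)
  expect_length(one, 1)
  expect_equal(one[[1]]$coords[, 1, 1], as.numeric(97:100))
  expect_error(slice_segments(tr, window = 300, take_last = 10000), "evenly")
  expect_error(slice_segments(tr, window = 200, take_last = 20000), "duration")
  expect_error(slice_segments(tr, window = 500, take_last = 400), "exceeds")
})
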