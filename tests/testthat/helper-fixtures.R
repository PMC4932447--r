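# Small in-code fixtures shared across tests.

# trajectory with explicit coordinates; atoms default to one CA per residue
toy_traj <- function(coords, atom_names = NULL, elements = NULL,
                     chain = "A", dt = 1) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  n <- dim(coords)[2]
  if (is.null(atom_names)) atom_names <- rep("CA", n)
  atoms <- data.frame(atom_name = atom_names,
                      residue_index = seq_len(n),
                      residue_name = rep("ALA", n),
                      chain_id = rep(chain, length.out = n),
                      stringsAsFactors = FALSE)
  if (!is.null(elements)) atoms$element <- elements
  traj(coords, atoms, frame_interval = dt)
}

# the hand-computable two-atom correlated/anti-correlated segments:
# mean structure (1,0,0),(2,0,0); frame deviations +/- (1,0,0, s*1,0,0)
two_atom_traj <- function(sign = +1) {
  f1 <- rbind(c(0, 0, 0), c(2 - sign * 1, 0, 0))
  f2 <- rbind(c(2, 0, 0), c(2 + sign * 1, 0, 0))
  co <- array(0, dim = c(2, 2, 3))
  co[1, , ] <- f1; co[2, , ] <- f2
  toy_traj(co)
}

# random fluctuation trajectory around a random non-degenerate geometry
random_traj <- function(n_atoms = 5, n_frames = 6, sd = 0.3) {
  ref <- matrix(stats::rnorm(n_atoms * 3), n_atoms, 3)
  co <- array(stats::rnorm(n_frames * n_atoms * 3, sd = sd),
              dim = c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames)) co[f, , ] <- co[f, , ] + ref
  toy_traj(co)
}

# uniform rotation matrix from random normals (QR with positive diagonal)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

poly_ala <- function(n) paste(rep("A", n), collapse = "")

# small two-block-plus-linker single chain model
block_linker_model <- function(n = 16, blocks = c(1, 7, 10, 16), ...) {
  con <- build_extended_chain(poly_ala(n))
  hnm_from_construct(con,
                     blocks = data.frame(chain = "A",
                                         from = blocks[c(1, 3)],
                                         to = blocks[c(2, 4)]), ...)
}
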