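#' Trajectory objects
#'
#' A `traj` object holds a molecular-dynamics trajectory (or a single-frame
#' structure) as a `frames x atoms x 3` coordinate array in nanometres,
#' together with an atom table and the frame spacing in picoseconds.  It is the
#' substrate every analysis in the package consumes.
#'
#' The atom table has one row per atom with columns `atom_index` (1-based),
#' `atom_name`, `element`, `residue_index` (1-based within each chain),
#' `residue_name` (3-letter code), `chain_id`, `is_heavy`, `is_calpha`.
#'
#' @param coords numeric array `frames x atoms x 3`, nanometres.  A
#'   `atoms x 3` matrix is accepted for a single frame.
#' @param atoms data frame as described above; missing `element`, `is_heavy`
#'   and `is_calpha` columns are derived from `atom_name`.
#' @param frame_interval frame spacing in picoseconds (> 0).
#' @param origin_time time of the first frame in picoseconds.
#' @return An object of class `traj`.
#' @export
traj <- function(coords, atoms, frame_interval = 1, origin_time = 0) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("'coords' must be a frames x atoms x 3 array", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in trajectory", call. = FALSE)
  if (dim(coords)[1] < 1L || dim(coords)[2] < 1L)
    stop("trajectory must contain at least one frame and one atom", call. = FALSE)
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L || frame_interval <= 0)
    stop("'frame_interval' must be a single positive number (ps)", call. = FALSE)
  atoms <- complete_atom_table(atoms, n = dim(coords)[2])
  structure(list(coords = coords, atoms = atoms,
                 frame_interval = as.numeric(frame_interval),
                 origin_time = as.numeric(origin_time)),
            class = "traj")
}

# Fill derived atom-table columns and validate invariants.
complete_atom_table <- function(atoms, n) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) != n)
    stop("atom table has ", nrow(atoms), " rows but coordinates have ", n,
         " atoms", call. = FALSE)
  req <- c("atom_name", "residue_index", "residue_name", "chain_id")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  atoms$atom_index <- seq_len(n)
  if (is.null(atoms$element))
    atoms$element <- guess_element(atoms$atom_name)
  atoms$is_heavy <- atoms$element != "H"
  atoms$is_calpha <- atoms$atom_name == "CA" & atoms$element == "C"
  for (ch in unique(atoms$chain_id)) {
    ri <- atoms$residue_index[atoms$chain_id == ch]
    if (any(diff(ri) < 0))
      stop("residue_index not non-decreasing within chain ", ch, call. = FALSE)
  }
  rownames(atoms) <- NULL
  atoms[c("atom_index", "atom_name", "element", "residue_index",
          "residue_name", "chain_id", "is_heavy", "is_calpha")]
}

# PDB-convention element guess for protein atoms: strip leading digits and
# primes, take the first letter; anything starting with H is hydrogen.
guess_element <- function(atom_name) {
  core <- sub("^[0-9']+", "", trimws(atom_name))
  toupper(substr(core, 1L, 1L))
}

#' @export
print.traj <- function(x, ...) {
  d <- dim(x$coords)
  cat("MD trajectory:", d[1], "frame(s),", d[2], "atoms,",
      length(unique(x$atoms$chain_id)), "chain(s)\n")
  cat("  frame interval:", x$frame_interval, "ps; duration:",
      traj_duration(x), "ps; origin:", x$origin_time, "ps\n")
  res <- tapply(x$atoms$residue_index, x$atoms$chain_id,
                function(r) length(unique(r)))
  cat("  residues per chain:", paste(names(res), res, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Number of frames and duration of a trajectory
#'
#' Duration counts each frame as one sampling interval, so `n_frames *
#' frame_interval`; a 200-ps window sampled every 0.1 ps holds 2000 frames.
#'
#' @param x a [traj] object.
#' @return `traj_duration`: duration in picoseconds. `n_frames`: frame count.
#' @export
traj_duration <- function(x) dim(x$coords)[1] * x$frame_interval

#' @rdname traj_duration
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' Read a single-frame structure from a PDB file
#'
#' Coordinates are converted from Angstrom to nanometres at the boundary.
#' Only ATOM records are kept (HETATM solvent/ligands are dropped); files with
#' insertion codes are rejected and for alternate locations only the first
#' occurrence of each atom is kept.
#'
#' @param path path to a PDB file.
#' @param format file format; only `"pdb"` is supported here.
#' @return A single-frame [traj] object (with `frame_interval = 1` ps,
#'   meaningless for a static structure).
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  read_trajectory(path, format = "pdb", frame_interval = 1)
}

#' Read a trajectory
#'
#' Multi-model PDB files are read directly; DCD files additionally require a
#' PDB `topology` naming the atoms.  The frame spacing is never guessed: pass
#' `frame_interval` explicitly (picoseconds).
#'
#' @param path trajectory file.
#' @param topology PDB file with the atom table (required for DCD).
#' @param format `"auto"` (by extension), `"pdb"`, `"dcd"` or `"xtc"`.
#' @param frame_interval frame spacing in picoseconds.
#' @return A [traj] object.
#' @export
read_trajectory <- function(path, topology = NULL,
                            format = c("auto", "pdb", "dcd", "xtc"),
                            frame_interval = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", dcd = "dcd", xtc = "xtc",
                     stop("cannot infer trajectory format from extension '",
                          ext, "'", call. = FALSE))
  }
  if (format == "xtc")
    stop("XTC reading is not supported; convert to multi-model PDB or DCD",
         call. = FALSE)
  if (format == "dcd") {
    if (is.null(topology))
      stop("DCD trajectories require a PDB 'topology'", call. = FALSE)
    top <- read_pdb_frames(topology)
    xyz <- tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                    error = function(e) stop("unreadable DCD file: ",
                                             conditionMessage(e), call. = FALSE))
    if (ncol(xyz) != nrow(top$atoms) * 3L)
      stop("topology has ", nrow(top$atoms), " atoms but trajectory frames have ",
           ncol(xyz) / 3, call. = FALSE)
    coords <- xyz_to_array(xyz)
    atoms <- top$atoms
  } else {
    parsed <- read_pdb_frames(path)
    coords <- parsed$coords
    atoms <- parsed$atoms
  }
  if (is.null(frame_interval)) {
    if (dim(coords)[1] > 1L)
      stop("'frame_interval' (ps) must be given for multi-frame trajectories",
           call. = FALSE)
    frame_interval <- 1
  }
  traj(coords, atoms, frame_interval = frame_interval)
}

# Parse a (possibly multi-model) PDB via bio3d, apply the package's
# record-filtering rules, and return nm coordinates plus the atom table.
read_pdb_frames <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("malformed PDB file '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (!any(keep))
    stop("no ATOM records in '", path, "' (HETATM-only input)", call. = FALSE)
  if (any(!is.na(at$insert[keep]) & at$insert[keep] != ""))
    stop("insertion codes are not supported (file '", path, "')", call. = FALSE)
  # first altloc kept: first occurrence of each (chain, resno, atom name)
  key <- paste(at$chain, at$resno, at$elety)
  keep <- keep & !duplicated(key)
  idx <- which(keep)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  xyz <- xyz[, cols, drop = FALSE]
  at <- at[idx, , drop = FALSE]
  chain <- ifelse(is.na(at$chain), "A", at$chain)
  # renumber residues 1-based within each chain, in order of appearance
  resix <- integer(nrow(at))
  for (ch in unique(chain)) {
    sel <- chain == ch
    resix[sel] <- match(at$resno[sel], unique(at$resno[sel]))
  }
  atoms <- data.frame(atom_name = at$elety, residue_index = resix,
                      residue_name = at$resid, chain_id = chain,
                      stringsAsFactors = FALSE)
  list(coords = xyz_to_array(xyz), atoms = atoms)
}

# frames x 3N Angstrom matrix -> frames x N x 3 nm array
xyz_to_array <- function(xyz) {
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  arr <- array(0, dim = c(nf, na, 3L))
  for (ax in 1:3) arr[, , ax] <- xyz[, seq(ax, by = 3L, length.out = na),
                                     drop = FALSE] / 10
  arr
}

# traj -> frames x 3N Angstrom matrix (bio3d layout)
array_to_xyz <- function(coords) {
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  xyz <- matrix(0, nf, 3L * na)
  for (ax in 1:3) xyz[, seq(ax, by = 3L, length.out = na)] <- coords[, , ax] * 10
  xyz
}

#' Write a trajectory as a (multi-model) PDB file
#'
#' Coordinates are converted back to Angstrom.  Chains keep their residue
#' numbering (1-based within chain).
#'
#' @param x a [traj] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "traj"))
  a <- x$atoms
  bio3d::write.pdb(file = path, xyz = array_to_xyz(x$coords),
                   type = rep("ATOM", nrow(a)), resno = a$residue_index,
                   resid = a$residue_name, elety = a$atom_name,
                   chain = a$chain_id, elesy = a$element)
  invisible(path)
}

#' Write per-chain sequences as FASTA
#'
#' @param x a [traj] object.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_chain_fasta <- function(x, path) {
  stopifnot(inherits(x, "traj"))
  a <- x$atoms[x$atoms$is_calpha, ]
  chains <- unique(a$chain_id)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    res3 <- a$residue_name[a$chain_id == ch]
    seq1 <- paste(bio3d::aa321(res3), collapse = "")
    writeLines(c(paste0(">chain_", ch), seq1), con)
  }
  invisible(path)
}

#' Select atoms from a trajectory
#'
#' @param x a [traj] object.
#' @param criterion `"heavy"` (excludes hydrogens), `"calpha"`,
#'   `"chain:<id>"`, or an integer vector of atom indices.
#' @return An `atom_mask`: ordered unique 1-based atom indices plus a label.
#' @export
select_atoms <- function(x, criterion) {
  stopifnot(inherits(x, "traj"))
  a <- x$atoms
  if (is.numeric(criterion)) {
    idx <- as.integer(criterion)
    if (anyDuplicated(idx) || is.unsorted(idx) ||
        any(idx < 1L) || any(idx > nrow(a)))
      stop("custom index selection must be unique, ascending and in range",
           call. = FALSE)
    label <- "custom"
  } else if (identical(criterion, "heavy")) {
    idx <- which(a$is_heavy); label <- "heavy"
  } else if (identical(criterion, "calpha")) {
    idx <- which(a$is_calpha); label <- "calpha"
  } else if (is.character(criterion) && grepl("^chain:", criterion)) {
    ch <- sub("^chain:", "", criterion)
    idx <- which(a$chain_id == ch); label <- criterion
  } else {
    stop("unknown selection criterion: ", deparse(criterion), call. = FALSE)
  }
  if (length(idx) == 0L)
    stop("selection '", label, "' matches no atoms", call. = FALSE)
  structure(list(indices = idx, label = label), class = "atom_mask")
}

#' @export
print.atom_mask <- function(x, ...) {
  cat("atom selection '", x$label, "': ", length(x$indices), " atoms\n", sep = "")
  invisible(x)
}

# Normalise a selection argument to an atom_mask.
as_mask <- function(x, selection) {
  if (inherits(selection, "atom_mask")) selection else select_atoms(x, selection)
}

#' Restrict a trajectory to a selection
#'
#' @param x a [traj] object.
#' @param mask an `atom_mask` (from [select_atoms]) or a criterion accepted by
#'   it.
#' @return A [traj] containing only the selected atoms.
#' @export
traj_subset <- function(x, mask) {
  mask <- as_mask(x, mask)
  traj(x$coords[, mask$indices, , drop = FALSE],
       x$atoms[mask$indices, c("atom_name", "element", "residue_index",
                               "residue_name", "chain_id")],
       frame_interval = x$frame_interval, origin_time = x$origin_time)
}

#' Cut the trailing part of a trajectory into equal segments
#'
#' Mirrors the segment-averaging protocol: the trailing `take_last`
#' picoseconds are cut into contiguous, non-overlapping windows of `window`
#' picoseconds, in chronological order.  A 10 ns tail with 200-ps windows
#' yields fifty segments.
#'
#' @param x a [traj] object.
#' @param window segment length, ps.
#' @param take_last length of the trailing analysis window, ps; default the
#'   whole trajectory.
#' @return List of [traj] segments.
#' @export
slice_segments <- function(x, window, take_last = NULL) {
  stopifnot(inherits(x, "traj"))
  dt <- x$frame_interval
  dur <- traj_duration(x)
  if (is.null(take_last)) take_last <- dur
  if (take_last > dur + 1e-9)
    stop("take_last (", take_last, " ps) exceeds trajectory duration (",
         dur, " ps)", call. = FALSE)
  if (window > take_last + 1e-9)
    stop("window (", window, " ps) exceeds take_last (", take_last, " ps)",
         call. = FALSE)
  n_seg <- take_last / window
  if (abs(n_seg - round(n_seg)) > 1e-9)
    stop("window must divide take_last evenly (no silent truncation)",
         call. = FALSE)
  n_seg <- as.integer(round(n_seg))
  fpw <- window / dt
  if (abs(fpw - round(fpw)) > 1e-9)
    stop("window must be a whole number of frame intervals", call. = FALSE)
  fpw <- as.integer(round(fpw))
  nf <- n_frames(x)
  first <- nf - n_seg * fpw + 1L
  lapply(seq_len(n_seg), function(s) {
    rows <- first + (s - 1L) * fpw + seq_len(fpw) - 1L
    traj(x$coords[rows, , , drop = FALSE], x$atoms,
         frame_interval = dt,
         origin_time = x$origin_time + (rows[1] - 1L) * dt)
  })
}
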