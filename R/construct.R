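#' Deterministic builders for unfolded multi-chain starting constructs
#'
#' These functions generate idealized unfolded starting geometries for an
#' intrinsically disordered polypeptide: a fully extended monomer, parallel
#' ("head-to-head", HH) and antiparallel ("head-to-tail", HT) dimers in two
#' side-chain orientations each (HH1/HH2/HT1/HT2, the "#2" variants roll the
#' second chain 180 degrees about its own main-chain axis), and a 2x2 stacked
#' tetramer built from two copies of a base dimer.  The backbone N-CA-C trace
#' of each chain is laid collinearly along its axis with standard bond
#' lengths, so the chain axis is exact by construction and the 180-degree
#' roll leaves backbone positions unchanged; carbonyl oxygens and idealized
#' heavy side-chain atoms extend off-axis.  Identical input always gives
#' bit-identical coordinates.
#'
#' @name construct
NULL

# backbone geometry (Angstrom): N-CA 1.458, CA-C 1.525, C-N(+1) 1.329
.bb <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            step = 1.50)                       # generic side-chain bond step
.pitch <- .bb$n_ca + .bb$ca_c + .bb$c_n        # residue pitch along the axis

# heavy side-chain topology: "ATOM:PARENT" edges, parents precede children
.side_chains <- list(
  ALA = c("CB:CA"),
  ARG = c("CB:CA", "CG:CB", "CD:CG", "NE:CD", "CZ:NE", "NH1:CZ", "NH2:CZ"),
  ASN = c("CB:CA", "CG:CB", "OD1:CG", "ND2:CG"),
  ASP = c("CB:CA", "CG:CB", "OD1:CG", "OD2:CG"),
  CYS = c("CB:CA", "SG:CB"),
  GLN = c("CB:CA", "CG:CB", "CD:CG", "OE1:CD", "NE2:CD"),
  GLU = c("CB:CA", "CG:CB", "CD:CG", "OE1:CD", "OE2:CD"),
  GLY = character(0),
  HIS = c("CB:CA", "CG:CB", "ND1:CG", "CD2:CG", "CE1:ND1", "NE2:CD2"),
  ILE = c("CB:CA", "CG1:CB", "CG2:CB", "CD1:CG1"),
  LEU = c("CB:CA", "CG:CB", "CD1:CG", "CD2:CG"),
  LYS = c("CB:CA", "CG:CB", "CD:CG", "CE:CD", "NZ:CE"),
  MET = c("CB:CA", "CG:CB", "SD:CG", "CE:SD"),
  PHE = c("CB:CA", "CG:CB", "CD1:CG", "CD2:CG", "CE1:CD1", "CE2:CD2", "CZ:CE1"),
  PRO = c("CB:CA", "CG:CB", "CD:CG"),
  SER = c("CB:CA", "OG:CB"),
  THR = c("CB:CA", "OG1:CB", "CG2:CB"),
  TRP = c("CB:CA", "CG:CB", "CD1:CG", "CD2:CG", "NE1:CD1", "CE2:CD2",
          "CE3:CD2", "CZ2:CE2", "CZ3:CE3", "CH2:CZ2"),
  TYR = c("CB:CA", "CG:CB", "CD1:CG", "CD2:CG", "CE1:CD1", "CE2:CD2",
          "CZ:CE1", "OH:CZ"),
  VAL = c("CB:CA", "CG1:CB", "CG2:CB"))

# place one residue's heavy atoms; x0 = x of backbone N (Angstrom)
place_residue <- function(res3, x0) {
  nm <- c("N", "CA", "C", "O")
  xyz <- rbind(c(x0, 0, 0),
               c(x0 + .bb$n_ca, 0, 0),
               c(x0 + .bb$n_ca + .bb$ca_c, 0, 0),
               c(x0 + .bb$n_ca + .bb$ca_c, .bb$c_o, 0))
  edges <- .side_chains[[res3]]
  if (length(edges)) {
    pos <- list(CA = xyz[2, ])
    parents <- sub("^.*:", "", edges)
    children <- sub(":.*$", "", edges)
    for (i in seq_along(children)) {
      sibs <- children[parents == parents[i]]
      nb <- length(sibs)
      b <- match(children[i], sibs)
      spread <- if (nb == 1L) 0 else (2 * b - nb - 1)
      dir <- c(0.45 * spread, -1, 0)
      dir <- dir / sqrt(sum(dir^2))
      pos[[children[i]]] <- pos[[parents[i]]] + .bb$step * dir
      nm <- c(nm, children[i])
      xyz <- rbind(xyz, pos[[children[i]]])
    }
  }
  list(names = nm, xyz = xyz)
}

#' Build a single fully extended chain
#'
#' @param sequence one-letter amino-acid string (standard 20-letter alphabet).
#' @param chain_id chain identifier, default `"A"`.
#' @return A `construct` object with one chain (see [assemble_construct]).
#' @export
build_extended_chain <- function(sequence, chain_id = "A") {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters1) == 0L) stop("empty sequence", call. = FALSE)
  bad <- setdiff(letters1, c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"))
  if (length(bad))
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  res3 <- bio3d::aa123(letters1)
  xyz <- NULL; names <- character(0); resix <- integer(0); resnm <- character(0)
  for (i in seq_along(res3)) {
    r <- place_residue(res3[i], (i - 1) * .pitch)
    xyz <- rbind(xyz, r$xyz)
    names <- c(names, r$names)
    resix <- c(resix, rep(i, length(r$names)))
    resnm <- c(resnm, rep(res3[i], length(r$names)))
  }
  atoms <- data.frame(atom_name = names, residue_index = resix,
                      residue_name = resnm, chain_id = chain_id,
                      stringsAsFactors = FALSE)
  tr <- traj(xyz / 10, atoms)                  # Angstrom -> nm
  axes <- list(list(point = c(0, 0, 0), dir = c(1, 0, 0)))
  names(axes) <- chain_id
  structure(list(structure = tr, axes = axes, alignment = NULL,
                 kind = "monomer", arrangement = NULL, separation = NA_real_,
                 sequence = paste(letters1, collapse = "")),
            class = "construct")
}

# rigid transforms on a chain's rows of a coords matrix (nm), plus its axis
flip_chain <- function(xyz, axis, cx) {
  # 180-degree rotation about the vertical line through the midpoint of the
  # C-alpha trace (x = cx on the chain axis): the axis line maps onto itself
  # with reversed direction, so residue i lands opposite residue n + 1 - i
  y0 <- axis$point[2]
  xyz[, 1] <- 2 * cx - xyz[, 1]
  xyz[, 2] <- 2 * y0 - xyz[, 2]
  axis$point <- c(2 * cx - axis$point[1], y0, axis$point[3])
  axis$dir <- -axis$dir
  list(xyz = xyz, axis = axis)
}

roll_chain <- function(xyz, axis) {
  # 180-degree roll about the chain's own main-chain axis (parallel to x):
  # (y, z) -> (2 y0 - y, 2 z0 - z); backbone atoms on the axis are fixed
  y0 <- axis$point[2]; z0 <- axis$point[3]
  xyz[, 2] <- 2 * y0 - xyz[, 2]
  xyz[, 3] <- 2 * z0 - xyz[, 3]
  list(xyz = xyz, axis = axis)
}

translate_chain <- function(xyz, axis, v) {
  xyz <- sweep(xyz, 2, v, "+")
  axis$point <- axis$point + v
  list(xyz = xyz, axis = axis)
}

#' Assemble a monomer, dimer or tetramer construct
#'
#' Chain 1 lies along the +x axis; in a dimer, chain 2 is displaced by
#' `separation` along +y.  HT arrangements reverse chain 2's N-to-C direction
#' (antiparallel axes); the "#2" variants additionally roll chain 2 by
#' 180 degrees about its own axis, changing only off-axis (side-chain and
#' carbonyl) positions.  The tetramer stacks two copies of the base dimer
#' (default HT2) along +z at the same separation, giving a 2x2 bundle with
#' equal nearest-neighbour axis separations; every unordered chain pair is
#' classified HH or HT from the axis directions.
#'
#' @param kind `"monomer"`, `"dimer"` or `"tetramer"`.
#' @param arrangement dimer arrangement, `"HH1"`, `"HH2"`, `"HT1"` or
#'   `"HT2"` (dimer/tetramer only).
#' @param separation axis-to-axis chain separation in Angstrom (default 14).
#' @param sequence one-letter amino-acid sequence; default the packaged
#'   140-residue human alpha-synuclein sequence.
#' @param tetramer_base base dimer arrangement used twice for the tetramer
#'   (default `"HT2"`).
#' @return A `construct`: a single-frame [traj] with chains `A`, `B`, ...,
#'   per-chain axes (point + unit direction), an `alignment` table of all
#'   unordered chain pairs, and the build parameters.
#' @export
assemble_construct <- function(kind = c("monomer", "dimer", "tetramer"),
                               arrangement = NULL, separation = 14,
                               sequence = alpha_synuclein_sequence(),
                               tetramer_base = "HT2") {
  kind <- match.arg(kind)
  if (separation <= 0) stop("separation must be positive", call. = FALSE)
  if (kind == "monomer") {
    if (!is.null(arrangement))
      stop("'arrangement' is only meaningful for dimers/tetramers",
           call. = FALSE)
    return(build_extended_chain(sequence))
  }
  if (kind == "tetramer") arrangement <- tetramer_base
  if (is.null(arrangement)) arrangement <- "HT2"
  arrangement <- match.arg(arrangement, c("HH1", "HH2", "HT1", "HT2"))
  base <- build_extended_chain(sequence, chain_id = "A")
  xyz1 <- base$structure$coords[1, , ]
  ax1 <- base$axes[["A"]]
  # chain 2
  xyz2 <- xyz1; ax2 <- ax1
  ca_x <- xyz1[base$structure$atoms$is_calpha, 1]
  cx <- (min(ca_x) + max(ca_x)) / 2
  if (grepl("^HT", arrangement)) {
    f <- flip_chain(xyz2, ax2, cx); xyz2 <- f$xyz; ax2 <- f$axis
  }
  t2 <- translate_chain(xyz2, ax2, c(0, separation / 10, 0))
  xyz2 <- t2$xyz; ax2 <- t2$axis
  if (grepl("2$", arrangement)) {
    r <- roll_chain(xyz2, ax2); xyz2 <- r$xyz; ax2 <- r$axis
  }
  chains_xyz <- list(A = xyz1, B = xyz2)
  axes <- list(A = ax1, B = ax2)
  if (kind == "tetramer") {
    t3 <- translate_chain(xyz1, ax1, c(0, 0, separation / 10))
    t4 <- translate_chain(xyz2, ax2, c(0, 0, separation / 10))
    chains_xyz$C <- t3$xyz; axes$C <- t3$axis
    chains_xyz$D <- t4$xyz; axes$D <- t4$axis
  }
  at1 <- base$structure$atoms[c("atom_name", "element", "residue_index",
                                "residue_name", "chain_id")]
  atoms <- do.call(rbind, lapply(names(chains_xyz), function(ch) {
    a <- at1; a$chain_id <- ch; a
  }))
  coords <- do.call(rbind, chains_xyz)
  tr <- traj(coords, atoms)
  cn <- names(chains_xyz)
  pairs <- utils::combn(cn, 2)
  obj <- structure(list(structure = tr, axes = axes, alignment = NULL,
                        kind = kind, arrangement = arrangement,
                        separation = separation, sequence = base$sequence),
                   class = "construct")
  obj$alignment <- data.frame(
    chain_a = pairs[1, ], chain_b = pairs[2, ],
    alignment = vapply(seq_len(ncol(pairs)), function(j)
      classify_pair_alignment(obj, pairs[1, j], pairs[2, j]), character(1)),
    stringsAsFactors = FALSE)
  obj
}

#' The packaged 140-residue human alpha-synuclein sequence
#'
#' Read from the FASTA fixture shipped with the package.
#'
#' @return One-letter amino-acid string of length 140.
#' @export
alpha_synuclein_sequence <- function() {
  path <- system.file("extdata", "alpha_synuclein_1xq8.fasta",
                      package = "ecdyn", mustWork = TRUE)
  lines <- readLines(path)
  paste(lines[!startsWith(lines, ">")], collapse = "")
}

#' Classify a chain pair as head-to-head or head-to-tail
#'
#' HH if the two chains' N-to-C axis directions have positive dot product
#' (parallel), HT if negative (antiparallel).
#'
#' @param model a `construct`.
#' @param chain_a,chain_b distinct chain identifiers.
#' @return `"HH"` or `"HT"`.
#' @export
classify_pair_alignment <- function(model, chain_a, chain_b) {
  stopifnot(inherits(model, "construct"))
  if (identical(chain_a, chain_b))
    stop("chain_a and chain_b must differ", call. = FALSE)
  for (ch in c(chain_a, chain_b))
    if (is.null(model$axes[[ch]])) stop("no such chain: ", ch, call. = FALSE)
  d <- sum(model$axes[[chain_a]]$dir * model$axes[[chain_b]]$dir)
  if (abs(d) < 1e-9)
    stop("chain axes are perpendicular; alignment is ambiguous", call. = FALSE)
  if (d > 0) "HH" else "HT"
}

#' Perpendicular distance between two chain axes
#'
#' @param model a `construct`.
#' @param chain_a,chain_b chain identifiers.
#' @return Distance in Angstrom between the (anti)parallel axis lines.
#' @export
axis_separation <- function(model, chain_a, chain_b) {
  stopifnot(inherits(model, "construct"))
  a <- model$axes[[chain_a]]; b <- model$axes[[chain_b]]
  if (is.null(a) || is.null(b)) stop("no such chain", call. = FALSE)
  v <- b$point - a$point
  perp <- v - sum(v * a$dir) * a$dir
  10 * sqrt(sum(perp^2))                        # nm -> Angstrom
}

#' @export
print.construct <- function(x, ...) {
  cat("construct:", x$kind,
      if (!is.null(x$arrangement)) paste0("(", x$arrangement, ")") else "",
      "\n")
  cat("  chains:", paste(names(x$axes), collapse = ", "),
      "|", nchar(x$sequence), "residues each\n")
  if (!is.na(x$separation))
    cat("  chain separation:", x$separation, "Angstrom\n")
  if (!is.null(x$alignment)) {
    cat("  pair alignments:\n")
    print(x$alignment, row.names = FALSE)
  }
  invisible(x)
}
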