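#' Supporting trajectory analyses
#'
#' Mean shortest-distance maps between residues, RMSD traces, and
#' secondary-structure occupancy statistics computed from externally
#' assigned per-frame DSSP-style code tables (this package parses and
#' analyses assignments; it does not assign secondary structure from
#' coordinates).
#'
#' @name structure-metrics
NULL

#' Mean shortest-distance map between residues
#'
#' For every residue pair, the minimum distance between their selected atoms
#' is taken in each frame and averaged over frames, yielding a symmetric
#' matrix in nanometres covering all intra- and inter-chain pairs.
#'
#' @param x a [traj].
#' @param selection atoms considered (default `"heavy"`); every residue must
#'   contribute at least one selected atom.
#' @return A `distance_map`: symmetric matrix (nm) with `chain:residue`
#'   labels, zero diagonal.
#' @export
mean_shortest_distance_map <- function(x, selection = "heavy") {
  stopifnot(inherits(x, "traj"))
  mask <- as_mask(x, selection)
  at <- x$atoms[mask$indices, , drop = FALSE]
  key <- paste0(at$chain_id, ":", at$residue_index)
  res <- unique(key)
  all_res <- unique(paste0(x$atoms$chain_id, ":", x$atoms$residue_index))
  if (length(setdiff(all_res, res)))
    stop("residue(s) without selected atoms: ",
         paste(utils::head(setdiff(all_res, res), 5), collapse = ", "),
         call. = FALSE)
  ridx <- match(key, res)
  nr <- length(res)
  nf <- n_frames(x)
  acc <- matrix(0, nr, nr)
  for (f in seq_len(nf)) {
    P <- x$coords[f, mask$indices, ]
    d <- as.matrix(stats::dist(P))
    # min over atom pairs within each residue pair
    m <- matrix(Inf, nr, nr)
    for (a in seq_len(nr)) {
      rows <- ridx == a
      m[a, ] <- pmin(m[a, ],
                     vapply(seq_len(nr), function(b)
                       min(d[rows, ridx == b]), numeric(1)))
    }
    diag(m) <- 0
    acc <- acc + m
  }
  acc <- acc / nf
  dimnames(acc) <- list(res, res)
  structure(list(map = acc,
                 residues = data.frame(
                   label = res,
                   chain_id = at$chain_id[!duplicated(key)],
                   residue_index = at$residue_index[!duplicated(key)],
                   stringsAsFactors = FALSE)),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat("mean shortest-distance map:", nrow(x$map), "residues\n")
  off <- x$map[upper.tri(x$map)]
  cat("  distances (nm): min", signif(min(off), 4), "median",
      signif(stats::median(off), 4), "max", signif(max(off), 4), "\n")
  invisible(x)
}

#' @export
plot.distance_map <- function(x, zlim = NULL, ...) {
  m <- x$map
  if (is.null(zlim)) zlim <- c(0, max(m))
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), m, zlim = zlim,
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  xlab = "residue", ylab = "residue",
                  main = "mean shortest distance (nm)", ...)
  ch <- x$residues$chain_id
  bounds <- which(diff(as.integer(factor(ch, levels = unique(ch)))) != 0) + 0.5
  graphics::abline(h = bounds, v = bounds, col = "grey30", lwd = 1.5)
  invisible(x)
}

#' Per-frame RMSD trace against a reference
#'
#' Each frame is optimally superposed onto the reference over
#' `fit_selection` and the RMSD is evaluated over `measure_selection`.
#'
#' @param x a [traj].
#' @param reference frame number (default 1) or a single-frame [traj] with a
#'   compatible atom table.
#' @param fit_selection,measure_selection atom selections (defaults
#'   `"heavy"`).
#' @return Numeric vector of per-frame RMSD values in nm, with the frame
#'   times (ps) as names.
#' @export
rmsd_trace <- function(x, reference = 1, fit_selection = "heavy",
                       measure_selection = fit_selection) {
  stopifnot(inherits(x, "traj"))
  fit <- as_mask(x, fit_selection)
  meas <- as_mask(x, measure_selection)
  if (inherits(reference, "traj")) {
    if (!identical(reference$atoms$atom_name, x$atoms$atom_name) ||
        nrow(reference$atoms) != nrow(x$atoms))
      stop("reference structure is not atom-compatible with the trajectory",
           call. = FALSE)
    ref <- reference$coords[1, , ]
  } else {
    ref <- x$coords[reference, , ]
  }
  check_fit_geometry(ref[fit$indices, ])
  out <- vapply(seq_len(n_frames(x)), function(f) {
    tr <- kabsch(x$coords[f, fit$indices, ], ref[fit$indices, ])
    moved <- sweep(x$coords[f, meas$indices, ] %*% tr$R, 2, tr$t, "+")
    sqrt(mean(rowSums((moved - ref[meas$indices, ])^2)))
  }, numeric(1))
  names(out) <- x$origin_time + (seq_len(n_frames(x)) - 1) * x$frame_interval
  out
}

# DSSP 8-class alphabet; blanks, "-" and "~" are coil
.ss_codes <- c("H", "G", "I", "E", "B", "T", "S", "C")

#' Parse a secondary-structure timeline
#'
#' Reads a frames x residues table of one-letter DSSP codes (H, G, I, E, B,
#' T, S; blank, `-`, `~` or `C` for coil), as produced externally by a DSSP
#' run on each frame.  Accepts either a TSV file written by
#' [write_ss_timeline] (first column `time_ps`, one column per residue,
#' header `chain:residue`) or a character matrix with one row per frame.
#'
#' @param x file path or character matrix.
#' @param frame_times frame times in ps (matrix input only; default
#'   `0, 1, ...`).
#' @param residues optional data frame `chain_id`, `residue_index` labelling
#'   the columns of a matrix input.
#' @return An `ss_timeline`: code matrix, frame times, residue labels.
#' @export
parse_dssp_timeline <- function(x, frame_times = NULL, residues = NULL) {
  if (is.character(x) && length(x) == 1L && !is.matrix(x)) {
    tab <- utils::read.delim(x, check.names = FALSE, colClasses = "character")
    if (names(tab)[1] != "time_ps")
      stop("timeline file must start with a 'time_ps' column", call. = FALSE)
    frame_times <- as.numeric(tab[[1]])
    codes <- as.matrix(tab[, -1, drop = FALSE])
    labs <- colnames(codes)
    residues <- data.frame(
      chain_id = sub(":.*$", "", labs),
      residue_index = as.integer(sub("^.*:", "", labs)),
      stringsAsFactors = FALSE)
  } else {
    codes <- as.matrix(x)
    if (is.null(frame_times)) frame_times <- seq_len(nrow(codes)) - 1
    if (is.null(residues))
      residues <- data.frame(chain_id = "A",
                             residue_index = seq_len(ncol(codes)))
  }
  codes[codes %in% c("", " ", "-", "~")] <- "C"
  bad <- setdiff(unique(as.vector(codes)), .ss_codes)
  if (length(bad))
    stop("unknown secondary-structure code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (length(frame_times) != nrow(codes))
    stop("frame_times length must match the number of frames", call. = FALSE)
  dimnames(codes) <- list(NULL,
                          paste0(residues$chain_id, ":",
                                 residues$residue_index))
  structure(list(codes = codes, frame_times = as.numeric(frame_times),
                 residues = residues),
            class = "ss_timeline")
}

#' @rdname parse_dssp_timeline
#' @param timeline an `ss_timeline`.
#' @param path output TSV file.
#' @export
write_ss_timeline <- function(timeline, path) {
  stopifnot(inherits(timeline, "ss_timeline"))
  tab <- data.frame(time_ps = timeline$frame_times,
                    timeline$codes, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.ss_timeline <- function(x, ...) {
  cat("secondary-structure timeline:", nrow(x$codes), "frames x",
      ncol(x$codes), "residues\n")
  tb <- table(factor(as.vector(x$codes), levels = .ss_codes))
  cat("  code fractions:",
      paste(names(tb), sprintf("%.2f", tb / sum(tb)), collapse = " "), "\n")
  invisible(x)
}

#' Secondary-structure occupancy and stability over a trailing window
#'
#' Occupancy is the fraction of window frames in which a residue carries a
#' code.  A residue is flagged `stable_beta` when its extended-strand (E)
#' occupancy is strictly greater than 0.8, and `stable_alpha` /
#' `stable_310` / `stable_pi` when the H / G / I occupancy is strictly
#' greater than 0.5 (thresholds read literally: exactly 80% or 50% is not
#' stable).  Maximal contiguous runs of stable residues are reported as
#' residue ranges, the form in which such elements are usually tabulated.
#'
#' @param timeline an `ss_timeline`.
#' @param window trailing analysis window, ps; default the whole timeline.
#' @return An `ss_occupancy`: per-residue occupancy table (one column per
#'   code), stability flags, and a `ranges` data frame of contiguous stable
#'   elements.
#' @export
ss_occupancy <- function(timeline, window = NULL) {
  stopifnot(inherits(timeline, "ss_timeline"))
  times <- timeline$frame_times
  if (is.null(window)) window <- diff(range(times)) + 1e-9
  if (window <= 0) stop("analysis window must be positive", call. = FALSE)
  keep <- times > max(times) - window
  if (!any(keep)) stop("analysis window contains no frames", call. = FALSE)
  codes <- timeline$codes[keep, , drop = FALSE]
  occ <- vapply(.ss_codes, function(cl) colMeans(codes == cl),
                numeric(ncol(codes)))
  occ <- matrix(occ, ncol = length(.ss_codes),
                dimnames = list(colnames(timeline$codes), .ss_codes))
  tab <- cbind(timeline$residues, as.data.frame(occ))
  tab$stable_beta <- tab$E > 0.8
  tab$stable_alpha <- tab$H > 0.5
  tab$stable_310 <- tab$G > 0.5
  tab$stable_pi <- tab$I > 0.5
  ranges <- do.call(rbind, lapply(
    c(beta = "stable_beta", alpha = "stable_alpha",
      `310` = "stable_310", pi = "stable_pi"),
    function(fl) stable_runs(tab, fl)))
  structure(list(table = tab, ranges = ranges, window = window,
                 n_frames = sum(keep)),
            class = "ss_occupancy")
}

# maximal contiguous runs of a logical flag, per chain
stable_runs <- function(tab, flag) {
  out <- NULL
  for (ch in unique(tab$chain_id)) {
    sub <- tab[tab$chain_id == ch, ]
    sub <- sub[order(sub$residue_index), ]
    on <- sub[[flag]]
    if (!any(on)) next
    r <- rle(on)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (g in which(r$values)) {
      out <- rbind(out, data.frame(
        class = sub("stable_", "", flag), chain_id = ch,
        from = sub$residue_index[starts[g]],
        to = sub$residue_index[ends[g]],
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' @export
print.ss_occupancy <- function(x, ...) {
  cat("secondary-structure occupancy over the trailing", x$window,
      "ps (", x$n_frames, "frames )\n")
  if (is.null(x$ranges) || !nrow(x$ranges)) {
    cat("  no stable elements\n")
  } else {
    cat("  stable elements:\n")
    print(x$ranges, row.names = FALSE)
  }
  invisible(x)
}

#' Default sequence-region annotation for alpha-synuclein
#'
#' N-terminal region residues 1-60, NAC domain 61-95 (amyloidogenic core
#' 71-82), C-terminal region 96-140.
#'
#' @return Named list of `c(from, to)` residue ranges.
#' @export
synuclein_regions <- function() {
  list(`N-terminal` = c(1, 60), NAC = c(61, 95), `NAC-core` = c(71, 82),
       `C-terminal` = c(96, 140))
}

#' Annotate stable elements with named sequence regions
#'
#' Every stable element is labelled with each named region it overlaps.
#'
#' @param x an `ss_occupancy`.
#' @param regions named list of `c(from, to)` residue ranges; default
#'   [synuclein_regions()].
#' @return The `ss_occupancy` with a `regions` column added to `ranges`.
#' @export
annotate_regions <- function(x, regions = synuclein_regions()) {
  stopifnot(inherits(x, "ss_occupancy"))
  if (anyDuplicated(names(regions)))
    stop("duplicate region names", call. = FALSE)
  for (rg in regions)
    if (length(rg) != 2 || rg[1] > rg[2])
      stop("each region must be c(from, to) with from <= to", call. = FALSE)
  if (!is.null(x$ranges) && nrow(x$ranges)) {
    x$ranges$regions <- vapply(seq_len(nrow(x$ranges)), function(i) {
      hit <- vapply(regions, function(rg)
        x$ranges$from[i] <= rg[2] && x$ranges$to[i] >= rg[1], logical(1))
      paste(names(regions)[hit], collapse = ",")
    }, character(1))
  }
  x$region_defs <- regions
  x
}
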