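#' Essential collective dynamics: segment PCA and descriptors
#'
#' The central computation of the package.  A trajectory segment is viewed as
#' a time series in 3N-dimensional configuration space; its covariance matrix
#' `C_ij = <(X_i - <X_i>)(X_j - <X_j>)>` (plain time average, population
#' normalisation 1/T) is diagonalised and the eigenvectors `E^k`, ordered by
#' decreasing eigenvalue, define the essential coordinates.  For each atom
#' `i` a projected image `r_i` of length `3 k_max` concatenates the triplets
#' `(E^k_{i,x}, E^k_{i,y}, E^k_{i,z})` over the first `k_max` principal
#' components.  Distances in image space are the descriptors: pair
#' correlations `d_ij = |r_i - r_j|` (small = coherent motion) and the
#' main-chain flexibility `F_Ca(i) = |r_i - eps|` with `eps` the centroid of
#' all C-alpha images (low = strongly coupled to the collective main-chain
#' motion).
#'
#' @name ecd-core
NULL

new_ecd_cov <- function(mean_coords, covariance, eigenvalues, eigenvectors,
                        atoms, selection_label, total_variance, n_frames) {
  structure(list(mean_coords = mean_coords, covariance = covariance,
                 eigenvalues = eigenvalues, eigenvectors = eigenvectors,
                 atoms = atoms, selection_label = selection_label,
                 total_variance = total_variance, n_frames = n_frames),
            class = "ecd_cov")
}

# deterministic sign convention: flip each eigenvector so its
# largest-magnitude component (ties: lowest index) is positive
fix_eigenvector_signs <- function(V) {
  for (k in seq_len(ncol(V))) {
    a <- abs(V[, k])
    # ties in the largest magnitude (exact or within FP noise) break to the
    # lowest index
    i <- which(a >= max(a) * (1 - 1e-12))[1]
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  V
}

# within runs of numerically equal eigenvalues, order the sign-fixed
# eigenvectors lexicographically so degenerate spectra decompose
# deterministically
order_degenerate <- function(values, V, rel_tol = 1e-10) {
  if (length(values) < 2L) return(list(values = values, V = V))
  scale <- max(abs(values), .Machine$double.eps)
  grp <- cumsum(c(TRUE, abs(diff(values)) > rel_tol * scale))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) > 1L) {
      o <- do.call(order, lapply(seq_len(nrow(V)), function(r) V[r, idx]))
      V[, idx] <- V[, idx[o], drop = FALSE]
    }
  }
  list(values = values, V = V)
}

#' Least-squares superposition of trajectory frames
#'
#' Each frame is rigid-body fitted (optimal rotation + translation, Kabsch)
#' onto the reference over the fit selection; the transform is applied to all
#' atoms.  With `reference = "mean"` the fit is iterated once: fit to the raw
#' mean, recompute the mean, refit.
#'
#' @param x a [traj] segment.
#' @param reference `"mean"` (segment mean structure) or `"first"` frame.
#' @param fit_selection selection used for the fit (default `"heavy"`); at
#'   least 3 non-collinear atoms.
#' @return The superposed [traj].
#' @export
superpose_frames <- function(x, reference = c("mean", "first"),
                             fit_selection = "heavy") {
  stopifnot(inherits(x, "traj"))
  reference <- match.arg(reference)
  mask <- as_mask(x, fit_selection)
  fit_one_pass <- function(coords, ref_fit) {
    nf <- dim(coords)[1]
    for (f in seq_len(nf)) {
      tr <- kabsch(coords[f, mask$indices, ], ref_fit)
      coords[f, , ] <- sweep(coords[f, , ] %*% tr$R, 2, tr$t, "+")
    }
    coords
  }
  check_fit_geometry(x$coords[1, mask$indices, ])
  coords <- x$coords
  if (reference == "first") {
    coords <- fit_one_pass(coords, coords[1, mask$indices, ])
  } else {
    ref <- colMeans2_frames(coords, mask$indices)
    check_fit_geometry(ref)
    coords <- fit_one_pass(coords, ref)
    ref <- colMeans2_frames(coords, mask$indices)
    coords <- fit_one_pass(coords, ref)
  }
  out <- x
  out$coords <- coords
  out
}

# mean structure over frames restricted to given atoms -> n x 3
colMeans2_frames <- function(coords, idx) {
  apply(coords[, idx, , drop = FALSE], c(2, 3), mean)
}

check_fit_geometry <- function(P) {
  if (nrow(P) < 3L)
    stop("fit selection needs at least 3 atoms", call. = FALSE)
  s <- svd(sweep(P, 2, colMeans(P)))$d
  if (s[2] < 1e-8 * max(s[1], 1e-12))
    stop("fit selection is (nearly) collinear; superposition is degenerate",
         call. = FALSE)
}

# optimal rotation R and translation t such that P %*% R + t ~ Q (row vectors)
kabsch <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  A <- crossprod(sweep(P, 2, pc), sweep(Q, 2, qc))
  sv <- svd(A)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(R = R, t = qc - as.numeric(pc %*% R))
}

#' Covariance model of a trajectory segment
#'
#' Builds the 3N x 3N configuration-space covariance of the selected atoms
#' (plain time average, 1/T normalisation) and its eigendecomposition, with
#' a deterministic eigenvector sign convention and a deterministic ordering
#' inside numerically degenerate eigenvalue clusters.
#'
#' For large selections the spectrum is obtained from the frames x frames
#' Gram matrix (mathematically identical for a rank-deficient sample
#' covariance); the full covariance matrix is then not stored and only the
#' top `n_vectors` eigenvectors are materialised.
#'
#' @param x a [traj] segment (usually already superposed).
#' @param selection atoms entering the PCA (default `"heavy"`).
#' @param method `"auto"`, `"dense"` or `"gram"`.
#' @param n_vectors number of eigenvectors materialised in the gram path.
#' @return An `ecd_cov`: mean structure, covariance (dense path only),
#'   descending eigenvalues, sign-fixed orthonormal eigenvectors, the atom
#'   table of the selection, and the total variance (trace).
#' @export
compute_covariance <- function(x, selection = "heavy",
                               method = c("auto", "dense", "gram"),
                               n_vectors = 50) {
  stopifnot(inherits(x, "traj"))
  method <- match.arg(method)
  mask <- as_mask(x, selection)
  sub <- x$coords[, mask$indices, , drop = FALSE]
  if (!all(is.finite(sub))) stop("non-finite coordinates", call. = FALSE)
  nf <- dim(sub)[1]; na <- dim(sub)[2]
  X <- matrix(aperm(sub, c(1, 3, 2)), nrow = nf)  # columns x1,y1,z1,x2,...
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  total <- sum(Xc^2) / nf
  if (method == "auto")
    method <- if (3 * na <= max(1200, nf)) "dense" else "gram"
  if (method == "dense") {
    C <- crossprod(Xc) / nf
    C <- (C + t(C)) / 2
    e <- eigen(C, symmetric = TRUE)
    vals <- e$values
    V <- fix_eigenvector_signs(e$vectors)
    od <- order_degenerate(vals, V)
    vals <- od$values; V <- od$V
  } else {
    G <- tcrossprod(Xc) / nf
    G <- (G + t(G)) / 2
    e <- eigen(G, symmetric = TRUE)
    vals <- pmax(e$values, 0)
    tolr <- max(vals) * 1e-12
    nv <- min(n_vectors, sum(vals > tolr))
    V <- crossprod(Xc, e$vectors[, seq_len(nv), drop = FALSE])
    V <- sweep(V, 2, sqrt(nf * vals[seq_len(nv)]), "/")
    V <- fix_eigenvector_signs(V)
    C <- NULL
  }
  mean_coords <- matrix(mu, ncol = 3, byrow = TRUE)
  new_ecd_cov(mean_coords = mean_coords, covariance = C,
              eigenvalues = vals, eigenvectors = V,
              atoms = x$atoms[mask$indices, , drop = FALSE],
              selection_label = mask$label,
              total_variance = total, n_frames = nf)
}

#' @export
print.ecd_cov <- function(x, ...) {
  cat("configuration-space covariance model:", nrow(x$atoms), "atoms (",
      x$selection_label, "), 3N =", 3 * nrow(x$atoms), "\n")
  cat("  total variance (trace):", signif(x$total_variance, 6), "nm^2;",
      "stored eigenvectors:", ncol(x$eigenvectors), "\n")
  if (length(x$eigenvalues))
    cat("  top eigenvalues:",
        paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Fraction of total displacement variance captured by the top k components
#'
#' @param model an `ecd_cov`.
#' @param k number of leading principal components.
#' @return Fraction in `[0, 1]`: sum of the top-k eigenvalues over the trace.
#' @export
variance_captured <- function(model, k) {
  stopifnot(inherits(model, "ecd_cov"))
  n3 <- 3 * nrow(model$atoms)
  if (k < 1 || k > n3) stop("k must be in 1..3N", call. = FALSE)
  if (model$total_variance <= 0)
    stop("total variance is zero; captured fraction undefined", call. = FALSE)
  sum(utils::head(model$eigenvalues, k)) / model$total_variance
}

#' Projected atomic images in principal-component space
#'
#' For each atom the triplets of its x, y, z eigenvector components are
#' concatenated over the first `k_max` principal components, giving a
#' dimensionless image vector of length `3 k_max`.  Eigenvector
#' orthonormality forces `sum_i |r_i|^2 = k_max`.
#'
#' @param model an `ecd_cov`.
#' @param k_max number of principal components (default 20); must not exceed
#'   the number of strictly positive eigenvalues.
#' @return An `ecd_image`: `n_atoms x 3 k_max` image matrix plus the atom
#'   table.
#' @export
project_images <- function(model, k_max = 20) {
  stopifnot(inherits(model, "ecd_cov"))
  vals <- model$eigenvalues
  tol <- max(vals, 0) * 1e-10
  rank <- sum(vals > tol)
  if (k_max < 1 || k_max > rank)
    stop("k_max (", k_max, ") exceeds the positive-spectrum rank (", rank,
         ")", call. = FALSE)
  if (ncol(model$eigenvectors) < k_max)
    stop("only ", ncol(model$eigenvectors), " eigenvectors stored; rebuild ",
         "the covariance with a larger n_vectors", call. = FALSE)
  if (k_max < length(vals) && vals[k_max + 1] > 0 &&
      abs(vals[k_max] - vals[k_max + 1]) <= 1e-8 * max(vals))
    warning("k_max cuts through a numerically degenerate eigenvalue cluster;",
            " descriptors may be unstable", call. = FALSE)
  n <- nrow(model$atoms)
  V <- model$eigenvectors[, seq_len(k_max), drop = FALSE]
  img <- matrix(0, n, 3 * k_max)
  for (k in seq_len(k_max))
    img[, 3 * (k - 1) + 1:3] <- matrix(V[, k], ncol = 3, byrow = TRUE)
  structure(list(images = img, k_max = k_max, atoms = model$atoms,
                 selection_label = model$selection_label),
            class = "ecd_image")
}

#' @export
print.ecd_image <- function(x, ...) {
  cat("projected atomic images:", nrow(x$images), "atoms in",
      ncol(x$images), "-dimensional PC space (k_max =", x$k_max, ")\n")
  invisible(x)
}

#' Main-chain flexibility profile
#'
#' `F_Ca(i) = |r_i - eps|` where `eps` is the centroid of the C-alpha
#' images.  Low values mark residues whose motion is strongly correlated
#' with the collective motion of the entire main chain; high values mark
#' mobile parts.
#'
#' @param image an `ecd_image` (must contain C-alpha atoms).
#' @return An `ecd_flex`: per-residue data frame (`chain_id`,
#'   `residue_index`, `residue_name`, `F`), plus the centroid.
#' @export
flexibility_profile <- function(image) {
  stopifnot(inherits(image, "ecd_image"))
  ca <- which(image$atoms$is_calpha)
  if (!length(ca)) stop("no C-alpha atoms in the image selection", call. = FALSE)
  imgs <- image$images[ca, , drop = FALSE]
  centroid <- colMeans(imgs)
  dev <- sweep(imgs, 2, centroid)
  profile <- data.frame(
    chain_id = image$atoms$chain_id[ca],
    residue_index = image$atoms$residue_index[ca],
    residue_name = image$atoms$residue_name[ca],
    F = sqrt(rowSums(dev^2)),
    stringsAsFactors = FALSE)
  structure(list(profile = profile, centroid = centroid,
                 k_max = image$k_max, n_segments = 1L),
            class = "ecd_flex")
}

#' @export
print.ecd_flex <- function(x, ...) {
  cat("main-chain flexibility profile:", nrow(x$profile), "C-alpha atoms",
      "(k_max =", x$k_max, ",", x$n_segments, "segment(s))\n")
  cat("  F range:", signif(min(x$profile$F), 4), "-",
      signif(max(x$profile$F), 4), "\n")
  invisible(x)
}

#' Pair-correlation map
#'
#' `d_ij = |r_i - r_j|`, the dimensionless distance between atomic images;
#' low values mean coherent motion.  The map is a metric: symmetric, zero on
#' the diagonal, and obeying the triangle inequality.
#'
#' @param image an `ecd_image`.
#' @param selection atoms to include, as an `atom_mask` over the parent
#'   trajectory or a criterion string; default all C-alpha atoms of the
#'   image.  Must be a subset of the image's atoms.
#' @return An `ecd_map`: labelled symmetric matrix plus the atom table.
#' @export
pair_correlations <- function(image, selection = NULL) {
  stopifnot(inherits(image, "ecd_image"))
  if (is.null(selection)) {
    rows <- which(image$atoms$is_calpha)
    if (!length(rows)) stop("no C-alpha atoms in image", call. = FALSE)
  } else {
    idx <- if (inherits(selection, "atom_mask")) selection$indices
           else as.integer(selection)
    rows <- match(idx, image$atoms$atom_index)
    if (anyNA(rows))
      stop("selection contains atoms absent from the image", call. = FALSE)
  }
  d <- as.matrix(stats::dist(image$images[rows, , drop = FALSE]))
  at <- image$atoms[rows, , drop = FALSE]
  labs <- paste0(at$chain_id, ":", at$residue_index)
  dimnames(d) <- list(labs, labs)
  structure(list(map = d, atoms = at, k_max = image$k_max, n_segments = 1L),
            class = "ecd_map")
}

#' @export
print.ecd_map <- function(x, ...) {
  cat("pair-correlation map:", nrow(x$map), "x", ncol(x$map),
      "atoms (k_max =", x$k_max, ",", x$n_segments, "segment(s))\n")
  off <- x$map[upper.tri(x$map)]
  if (length(off))
    cat("  d_ij range:", signif(min(off), 4), "-", signif(max(off), 4), "\n")
  invisible(x)
}

# one-segment descriptor pipeline
segment_descriptor <- function(seg, selection, descriptor_selection, k_max,
                               which, superpose, reference = "mean") {
  if (superpose) seg <- superpose_frames(seg, reference = reference,
                                         fit_selection = selection)
  cov <- compute_covariance(seg, selection = selection,
                            n_vectors = max(50, k_max))
  img <- project_images(cov, k_max = k_max)
  out <- switch(which,
    flexibility = flexibility_profile(img),
    correlation = pair_correlations(img,
      selection = if (is.null(descriptor_selection)) NULL
                  else as_mask(seg, descriptor_selection)))
  list(descriptor = out, captured = variance_captured(cov, k_max))
}

#' Segment-averaged ECD descriptors
#'
#' Runs the per-segment pipeline (superpose, covariance, images, descriptor)
#' on each segment and returns the unweighted elementwise mean, with the
#' per-element standard deviation across segments retained.
#'
#' @param segments list of [traj] segments sharing one atom table (e.g. from
#'   [slice_segments]).
#' @param selection PCA selection (default `"heavy"`).
#' @param descriptor_selection atoms for the correlation map (default the
#'   C-alpha atoms).
#' @param k_max number of principal components (default 20).
#' @param which `"flexibility"` or `"correlation"`.
#' @param superpose superpose each segment onto its mean first (default).
#' @return An `ecd_flex` or `ecd_map` with mean values, `sd`, and
#'   `n_segments`.
#' @export
average_descriptors <- function(segments, selection = "heavy",
                                descriptor_selection = NULL, k_max = 20,
                                which = c("flexibility", "correlation"),
                                superpose = TRUE) {
  which <- match.arg(which)
  if (!length(segments)) stop("no segments supplied", call. = FALSE)
  a1 <- segments[[1]]$atoms
  for (s in segments)
    if (!identical(s$atoms, a1))
      stop("segments have differing atom tables", call. = FALSE)
  res <- lapply(segments, segment_descriptor, selection = selection,
                descriptor_selection = descriptor_selection, k_max = k_max,
                which = which, superpose = superpose)
  caps <- vapply(res, `[[`, numeric(1), "captured")
  out <- if (which == "flexibility")
    pool_flex(lapply(res, function(r) r$descriptor))
  else pool_maps(lapply(res, function(r) r$descriptor))
  out$captured <- caps
  out
}

# elementwise mean and sd across per-segment descriptors
pool_flex <- function(flexes) {
  first <- flexes[[1]]
  Fm <- matrix(vapply(flexes, function(f) f$profile$F,
                      numeric(nrow(first$profile))), ncol = length(flexes))
  first$profile$F <- rowMeans(Fm)
  first$profile$F_sd <- if (length(flexes) > 1) apply(Fm, 1, stats::sd)
                        else rep(0, nrow(Fm))
  first$n_segments <- length(flexes)
  first
}

pool_maps <- function(mapl) {
  first <- mapl[[1]]
  maps <- lapply(mapl, `[[`, "map")
  first$map <- Reduce(`+`, maps) / length(maps)
  if (length(maps) > 1) {
    sq <- Reduce(`+`, lapply(maps, function(m) m^2)) / length(maps)
    v <- pmax(sq - first$map^2, 0)
    first$sd <- sqrt(v * length(maps) / (length(maps) - 1))
  } else first$sd <- first$map * 0
  first$n_segments <- length(maps)
  first
}

#' Fit the full ECD analysis to a trajectory
#'
#' The package's main entry point: slices the trailing analysis window into
#' equal segments, runs the segment-wise PCA pipeline on each (superposition,
#' covariance, projected images) and averages the flexibility profile and the
#' C-alpha pair-correlation map over segments.  Defaults mirror the standard
#' protocol: 200-ps segments over a trailing 10-ns window, 20 principal
#' components, PCA over heavy atoms, C-alpha descriptors.
#'
#' @param x a [traj].
#' @param selection PCA atom selection (default `"heavy"`).
#' @param descriptor_selection atoms for the correlation map (default
#'   C-alpha).
#' @param k_max number of principal components (default 20).
#' @param window segment length, ps; `NULL` analyses `x` as one segment.
#' @param take_last trailing analysis window, ps (default: whole trajectory).
#' @param superpose rigid-body fit frames onto each segment mean (default
#'   `TRUE`; set `FALSE` to analyse raw coordinates).
#' @return An object of class `ecd` with components `flexibility`
#'   (`ecd_flex`), `map` (`ecd_map`), `captured` (per-segment fraction of
#'   variance in the top `k_max` components), and the analysis parameters.
#' @export
ecd <- function(x, selection = "heavy", descriptor_selection = NULL,
                k_max = 20, window = NULL, take_last = NULL,
                superpose = TRUE) {
  stopifnot(inherits(x, "traj"))
  segments <- if (is.null(window)) {
    if (!is.null(take_last))
      slice_segments(x, window = take_last, take_last = take_last)
    else list(x)
  } else slice_segments(x, window = window, take_last = take_last)
  # one PCA pass per segment, both descriptors from the same images
  res <- lapply(segments, function(seg) {
    if (superpose) seg <- superpose_frames(seg, fit_selection = selection)
    cov <- compute_covariance(seg, selection = selection,
                              n_vectors = max(50, k_max))
    img <- project_images(cov, k_max = k_max)
    list(flex = flexibility_profile(img),
         map = pair_correlations(img,
           selection = if (is.null(descriptor_selection)) NULL
                       else as_mask(seg, descriptor_selection)),
         captured = variance_captured(cov, k_max))
  })
  caps <- vapply(res, `[[`, numeric(1), "captured")
  flex <- pool_flex(lapply(res, `[[`, "flex"))
  map <- pool_maps(lapply(res, `[[`, "map"))
  flex$captured <- caps
  structure(list(flexibility = flex, map = map, captured = caps,
                 k_max = k_max, selection = flex_label(selection),
                 n_segments = length(segments),
                 window = if (is.null(window)) traj_duration(segments[[1]])
                          else window,
                 call = match.call()),
            class = "ecd")
}

flex_label <- function(selection) {
  if (inherits(selection, "atom_mask")) selection$label
  else if (is.character(selection)) selection else "custom"
}

#' @export
print.ecd <- function(x, ...) {
  cat("essential collective dynamics analysis\n")
  cat("  ", x$n_segments, " segment(s) of ", x$window, " ps; k_max = ",
      x$k_max, "; PCA selection: ", x$selection, "\n", sep = "")
  cat("  variance captured by top ", x$k_max, " PCs: mean ",
      sprintf("%.1f%%", 100 * mean(x$captured)),
      if (x$n_segments > 1)
        sprintf(" (range %.1f-%.1f%%)", 100 * min(x$captured),
                100 * max(x$captured)), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ecd <- function(object, ...) {
  p <- object$flexibility$profile
  cat("ECD analysis of", nrow(p), "C-alpha atoms over",
      object$n_segments, "segment(s)\n")
  print(object)
  for (ch in unique(p$chain_id)) {
    sel <- p$chain_id == ch
    i_min <- which.min(p$F[sel]); i_max <- which.max(p$F[sel])
    cat(sprintf("  chain %s: F in [%.3f, %.3f]; most rigid residue %d (%s),",
                ch, min(p$F[sel]), max(p$F[sel]),
                p$residue_index[sel][i_min], p$residue_name[sel][i_min]),
        sprintf(" most mobile residue %d (%s)\n",
                p$residue_index[sel][i_max], p$residue_name[sel][i_max]))
  }
  off <- object$map$map[upper.tri(object$map$map)]
  cat(sprintf("  pair correlations d_ij: median %.3f, min %.3f, max %.3f\n",
              stats::median(off), min(off), max(off)))
  invisible(object)
}

#' Plot ECD results
#'
#' @param x an `ecd` object.
#' @param type `"flexibility"` (per-residue profile, one panel line per
#'   chain), `"map"` (pair-correlation heat map with chain partition lines)
#'   or `"scree"` (per-segment captured-variance fractions).
#' @param ... passed to the underlying base-graphics calls.
#' @return `x`, invisibly.
#' @export
plot.ecd <- function(x, type = c("flexibility", "map", "scree"), ...) {
  type <- match.arg(type)
  if (type == "flexibility") {
    plot_flexibility(x$flexibility, ...)
  } else if (type == "map") {
    plot_correlation_map(x$map, ...)
  } else {
    graphics::plot(seq_along(x$captured), 100 * x$captured, type = "b",
                   xlab = "segment", ylab = "% variance in top PCs",
                   main = sprintf("variance captured by %d PCs", x$k_max), ...)
  }
  invisible(x)
}

#' @rdname plot.ecd
#' @param flex an `ecd_flex`.
#' @export
plot_flexibility <- function(flex, ...) {
  p <- flex$profile
  chains <- unique(p$chain_id)
  cols <- grDevices::hcl.colors(max(2L, length(chains)), "Dark 2")
  graphics::plot(NULL, xlim = range(p$residue_index),
                 ylim = range(c(0, p$F)), xlab = "residue",
                 ylab = expression(F[C * alpha]),
                 main = "main-chain flexibility", ...)
  for (i in seq_along(chains)) {
    sel <- p$chain_id == chains[i]
    graphics::lines(p$residue_index[sel], p$F[sel], col = cols[i])
  }
  graphics::legend("topright", legend = chains, col = cols[seq_along(chains)],
                   lty = 1, bty = "n")
  invisible(flex)
}

#' @rdname plot.ecd
#' @param map an `ecd_map`.
#' @param zlim fixed colour-scale bounds (shared across chains/figures).
#' @export
plot_correlation_map <- function(map, zlim = NULL, ...) {
  m <- map$map
  if (is.null(zlim)) zlim <- c(0, max(m))
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), m, zlim = zlim,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "atom", ylab = "atom",
                  main = expression(paste("pair correlations ", d[ij])), ...)
  ch <- map$atoms$chain_id
  bounds <- which(diff(as.integer(factor(ch, levels = unique(ch)))) != 0) + 0.5
  graphics::abline(h = bounds, v = bounds, col = "grey30", lwd = 1.5)
  invisible(map)
}
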