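#' Harmonic-network Langevin models of peptide fluctuations
#'
#' A `hnm` is an elastic network of isotropic springs on C-alpha sites whose
#' overdamped Langevin dynamics produce stationary, equilibrated fluctuation
#' trajectories with *known* correlation structure.  The potential is
#' `V = 1/2 sum_k k_ij |u_i - u_j|^2` over spring edges (displacements `u`
#' from the reference geometry), so the Hessian is the spring-graph Laplacian
#' acting identically on x, y and z, its null space is exactly the three
#' rigid translations for a connected graph, and the stationary covariance is
#' `kT` times the Hessian pseudo-inverse - a closed form against which
#' trajectory-PCA estimates can be validated.
#'
#' Rigid correlated blocks are modelled by dense stiff springs (all site
#' pairs within a cutoff), flexible linkers by weak chain-sequential springs,
#' and inter-chain coupling by springs between matched residue ranges of two
#' chains.
#'
#' @name hnm
NULL

# kT at 310 K in kJ/mol
.kT_310 <- 2.577

#' Build a harmonic-network model from a construct
#'
#' Sites sit at the C-alpha positions of the construct.  Every
#' chain-sequential residue pair is connected (stiffness `k_block` when both
#' residues lie in the same rigid block, else `k_linker`); additionally all
#' same-block site pairs within `cutoff` are connected at `k_block`.  Each
#' residue of an inter-chain coupling range is tethered to its spatially
#' nearest partner residue in the paired range at the coupling stiffness.
#' Remaining heavy atoms of the construct are carried as satellites that ride
#' rigidly with their residue's site during simulation (plus optional
#' small-amplitude jitter, a fixture feature rather than physics).
#'
#' @param construct a `construct` from [assemble_construct].
#' @param blocks data frame `chain`, `from`, `to`: rigid-block residue
#'   ranges; residues outside every block are linker.  Default: the whole of
#'   each chain is one rigid block.
#' @param couplings optional data frame `chain_a`, `from_a`, `to_a`,
#'   `chain_b`, `from_b`, `to_b`, `k` of inter-chain couplings.
#' @param k_block,k_linker spring stiffnesses, kJ mol^-1 nm^-2.
#' @param cutoff dense intra-block spring cutoff, nm.
#' @param kT thermal energy, kJ mol^-1; default 2.577 (310 K).
#' @param gamma drag coefficient, kJ mol^-1 nm^-2 ps; `lambda/gamma` is a
#'   relaxation rate in ps^-1.
#' @param jitter_sd isotropic satellite jitter standard deviation, nm.
#' @return An object of class `hnm`.
#' @export
hnm_from_construct <- function(construct, blocks = NULL, couplings = NULL,
                               k_block = 2000, k_linker = 40,
                               cutoff = 1.0, kT = .kT_310,
                               gamma = 1.2, jitter_sd = 0.005) {
  stopifnot(inherits(construct, "construct"))
  atoms <- construct$structure$atoms
  coords <- construct$structure$coords[1, , ]
  ca <- which(atoms$is_calpha)
  sites <- coords[ca, , drop = FALSE]
  site_tab <- atoms[ca, c("residue_index", "chain_id")]
  n <- nrow(sites)
  chains <- unique(site_tab$chain_id)
  n_res <- vapply(chains, function(ch) sum(site_tab$chain_id == ch), integer(1))
  if (is.null(blocks))
    blocks <- data.frame(chain = chains, from = 1L, to = n_res,
                         stringsAsFactors = FALSE)
  for (col in c("from", "to"))
    if (any(blocks[[col]] < 1L) ||
        any(blocks[[col]] > n_res[match(blocks$chain, chains)]))
      stop("block range outside chain length", call. = FALSE)
  site_id <- function(chain, res)
    which(site_tab$chain_id == chain & site_tab$residue_index %in% res)
  block_of <- rep(NA_integer_, n)
  for (b in seq_len(nrow(blocks))) {
    ids <- site_id(blocks$chain[b], blocks$from[b]:blocks$to[b])
    if (any(!is.na(block_of[ids])))
      stop("overlapping rigid blocks", call. = FALSE)
    block_of[ids] <- b
  }
  edges <- list()
  # chain-sequential springs
  for (ch in chains) {
    ids <- which(site_tab$chain_id == ch)
    ids <- ids[order(site_tab$residue_index[ids])]
    i <- ids[-length(ids)]; j <- ids[-1]
    same_block <- !is.na(block_of[i]) & !is.na(block_of[j]) &
      block_of[i] == block_of[j]
    edges[[length(edges) + 1L]] <-
      data.frame(i = i, j = j, k = ifelse(same_block, k_block, k_linker))
  }
  # dense intra-block springs within cutoff
  for (b in seq_len(nrow(blocks))) {
    ids <- which(!is.na(block_of) & block_of == b)
    if (length(ids) > 1L) {
      d <- as.matrix(stats::dist(sites[ids, , drop = FALSE]))
      pr <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
      if (nrow(pr))
        edges[[length(edges) + 1L]] <-
          data.frame(i = ids[pr[, 1]], j = ids[pr[, 2]], k = k_block)
    }
  }
  # inter-chain couplings: nearest partner in the paired range
  if (!is.null(couplings)) for (cc in seq_len(nrow(couplings))) {
    ia <- site_id(couplings$chain_a[cc], couplings$from_a[cc]:couplings$to_a[cc])
    ib <- site_id(couplings$chain_b[cc], couplings$from_b[cc]:couplings$to_b[cc])
    if (!length(ia) || !length(ib))
      stop("coupling range outside chain length", call. = FALSE)
    for (i in ia) {
      dd <- colSums((t(sites[ib, , drop = FALSE]) - sites[i, ])^2)
      edges[[length(edges) + 1L]] <-
        data.frame(i = i, j = ib[which.min(dd)], k = couplings$k[cc])
    }
  }
  springs <- do.call(rbind, edges)
  springs <- springs[springs$i != springs$j, ]
  key <- paste(pmin(springs$i, springs$j), pmax(springs$i, springs$j))
  springs <- springs[!duplicated(key), ]
  if (any(springs$k <= 0)) stop("spring stiffness must be positive", call. = FALSE)
  model <- structure(list(
    sites = sites, springs = springs, site_tab = site_tab,
    block_of = block_of, kT = kT, gamma = gamma, jitter_sd = jitter_sd,
    atoms = atoms, ref_coords = coords, site_of_atom = site_of_atom(atoms)),
    class = "hnm")
  comp <- graph_components(n, springs)
  if (max(comp) > 1L)
    stop("spring graph is disconnected (", max(comp), " components); add ",
         "inter-chain couplings or linker springs", call. = FALSE)
  model
}

# map every atom to the C-alpha site of its residue+chain
site_of_atom <- function(atoms) {
  ca <- which(atoms$is_calpha)
  key <- paste(atoms$chain_id, atoms$residue_index)
  m <- match(key, key[ca])
  if (anyNA(m)) stop("residue without a C-alpha atom", call. = FALSE)
  m
}

graph_components <- function(n, springs) {
  comp <- integer(n); cur <- 0L
  adj <- split(c(springs$j, springs$i), c(springs$i, springs$j))
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v]) next
      comp[v] <- cur
      nb <- adj[[as.character(v)]]
      queue <- c(queue, nb[comp[nb] == 0L])
    }
  }
  comp
}

# spring-graph Laplacian (site space, n x n)
hnm_laplacian <- function(model) {
  n <- nrow(model$sites)
  L <- matrix(0, n, n)
  for (r in seq_len(nrow(model$springs))) {
    i <- model$springs$i[r]; j <- model$springs$j[r]; k <- model$springs$k[r]
    L[i, j] <- L[i, j] - k
    L[j, i] <- L[j, i] - k
    L[i, i] <- L[i, i] + k
    L[j, j] <- L[j, j] + k
  }
  L
}

# eigen-decomposition of the Laplacian with the translational zero mode
# identified; errors if the model is singular beyond it
hnm_modes <- function(model) {
  L <- hnm_laplacian(model)
  e <- eigen(L, symmetric = TRUE)
  lam <- rev(e$values)                      # ascending
  V <- e$vectors[, rev(seq_along(lam)), drop = FALSE]
  tol <- max(lam) * 1e-10
  n_null <- sum(lam < tol)
  if (n_null != 1L)
    stop("network Hessian is singular beyond the translational null space",
         call. = FALSE)
  list(lambda = lam[-1], V = V[, -1, drop = FALSE])
}

#' Closed-form stationary covariance of a harmonic network
#'
#' Returns `kT` times the pseudo-inverse of the network Hessian (the
#' translational null space projected out) as an `ecd_cov` object over the
#' C-alpha sites - the exact stationary covariance of the overdamped process
#' and the oracle against which trajectory-PCA covariance estimates are
#' validated.
#'
#' @param model a [hnm] model.
#' @return An `ecd_cov` (see [compute_covariance]) with the exact covariance,
#'   eigenvalues and eigenvectors.
#' @export
equilibrium_covariance <- function(model) {
  stopifnot(inherits(model, "hnm"))
  md <- hnm_modes(model)
  n <- nrow(model$sites)
  var_site <- model$kT / md$lambda          # per-mode, per-axis
  C_site <- md$V %*% (var_site * t(md$V))
  C <- kronecker(C_site, diag(3))           # (x1,y1,z1,x2,...) ordering
  # eigenpairs: each graph mode appears once per axis
  ord <- order(rep(var_site, each = 3), decreasing = TRUE)
  vals <- rep(var_site, each = 3)[ord]
  vecs <- matrix(0, 3 * n, length(vals))
  col <- 0L
  for (m in seq_along(var_site)) for (ax in 1:3) {
    col <- col + 1L
    v <- numeric(3 * n)
    v[seq(ax, by = 3, length.out = n)] <- md$V[, m]
    vecs[, col] <- v
  }
  vecs <- vecs[, ord, drop = FALSE]
  vecs <- fix_eigenvector_signs(vecs)
  new_ecd_cov(mean_coords = model$sites, covariance = C,
              eigenvalues = vals, eigenvectors = vecs,
              atoms = cbind(model$atoms[model$atoms$is_calpha, ,
                                        drop = FALSE]),
              selection_label = "calpha",
              total_variance = 3 * sum(var_site), n_frames = NA_integer_)
}

#' Simulate a stationary fluctuation trajectory
#'
#' Draws an exact discretisation of the overdamped Langevin dynamics
#' `gamma du = -H u dt + sqrt(2 kT gamma) dW` in the Hessian eigenbasis: each
#' mode is an Ornstein-Uhlenbeck process advanced with its exact transition
#' kernel, started from the stationary distribution, so the sampled process
#' has no step-size bias and cannot become unstable.  The translational null
#' space carries no motion (rigid-body drift removed by construction).
#' Satellite heavy atoms, when the model was built from an all-atom
#' construct, ride rigidly with their residue's site plus optional isotropic
#' jitter.
#'
#' @param object a [hnm] model.
#' @param nsim number of trajectories (only 1 supported).
#' @param seed integer seed; required, recorded in the output metadata.
#' @param n_frames number of frames to return (>= 2).
#' @param frame_interval frame spacing, ps.
#' @param burn_in_frames frames discarded before recording (the stationary
#'   start makes this redundant; retained for protocol compatibility).
#' @param satellites logical: carry non-site heavy atoms (default) or return
#'   the C-alpha sites only.
#' @param ... unused.
#' @return A [traj] with attribute `sim_meta` (seed, parameters).
#' @export
simulate.hnm <- function(object, nsim = 1, seed = NULL, n_frames = 1000,
                         frame_interval = 0.1, burn_in_frames = 0,
                         satellites = TRUE, ...) {
  if (nsim != 1) stop("only nsim = 1 is supported", call. = FALSE)
  if (is.null(seed)) stop("a 'seed' is required for reproducibility", call. = FALSE)
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a positive number of ps", call. = FALSE)
  md <- hnm_modes(object)
  n <- nrow(object$sites)
  m <- length(md$lambda)
  nt <- n_frames + burn_in_frames
  alpha <- exp(-md$lambda * frame_interval / object$gamma)
  sd_stat <- sqrt(object$kT / md$lambda)
  sd_inn <- sd_stat * sqrt(1 - alpha^2)
  set.seed(seed)
  site_disp <- array(0, dim = c(n_frames, n, 3))
  for (ax in 1:3) {
    c0 <- stats::rnorm(m) * sd_stat
    inn <- matrix(stats::rnorm(nt * m), nt, m) * rep(sd_inn, each = nt)
    cmat <- vapply(seq_len(m), function(k) {
      as.numeric(stats::filter(inn[, k], alpha[k], method = "recursive")) +
        alpha[k]^seq_len(nt) * c0[k]
    }, numeric(nt))
    if (burn_in_frames > 0) cmat <- cmat[-seq_len(burn_in_frames), , drop = FALSE]
    site_disp[, , ax] <- cmat %*% t(md$V)
  }
  if (satellites && nrow(object$atoms) > nrow(object$sites)) {
    na <- nrow(object$atoms)
    coords <- array(0, dim = c(n_frames, na, 3))
    soa <- object$site_of_atom
    for (ax in 1:3)
      coords[, , ax] <- rep(object$ref_coords[, ax], each = n_frames) +
        site_disp[, soa, ax]
    if (object$jitter_sd > 0) {
      sat <- which(!object$atoms$is_calpha)
      coords[, sat, ] <- coords[, sat, ] +
        stats::rnorm(n_frames * length(sat) * 3, sd = object$jitter_sd)
    }
    atoms <- object$atoms
  } else {
    coords <- array(0, dim = c(n_frames, n, 3))
    for (ax in 1:3)
      coords[, , ax] <- rep(object$sites[, ax], each = n_frames) +
        site_disp[, , ax]
    atoms <- object$atoms[object$atoms$is_calpha, , drop = FALSE]
  }
  if (any(abs(coords) > 1e3))
    stop("simulated coordinates exceeded 1000 nm; reduce stiffness contrast ",
         "or check the model", call. = FALSE)
  tr <- traj(coords, atoms[, c("atom_name", "element", "residue_index",
                               "residue_name", "chain_id")],
             frame_interval = frame_interval)
  attr(tr, "sim_meta") <- list(seed = seed, n_frames = n_frames,
                               frame_interval = frame_interval,
                               burn_in_frames = burn_in_frames,
                               kT = object$kT, gamma = object$gamma,
                               jitter_sd = object$jitter_sd)
  tr
}

#' @export
print.hnm <- function(x, ...) {
  cat("harmonic-network model:", nrow(x$sites), "sites,",
      nrow(x$springs), "springs\n")
  cat("  kT =", x$kT, "kJ/mol; gamma =", x$gamma, "kJ/mol/nm^2 ps;",
      "satellite jitter sd =", x$jitter_sd, "nm\n")
  nb <- sum(!is.na(x$block_of))
  cat("  rigid-block sites:", nb, "| linker sites:", nrow(x$sites) - nb, "\n")
  invisible(x)
}

#' Default two-chain fluctuation plan
#'
#' The package's reference study condition for synthetic dynamics: an HT2
#' dimer of the packaged 140-residue alpha-synuclein sequence at 14-Angstrom
#' separation, two rigid blocks per chain (residues 1-60 and 75-140) joined
#' by a flexible linker (61-74), and an inter-chain coupling across the NAC
#' ranges (61-95) of the two chains.
#'
#' @param construct optionally, a pre-built construct (defaults to the HT2
#'   dimer above).
#' @param ... overrides passed on to [hnm_from_construct].
#' @return A [hnm] model.
#' @export
default_dimer_model <- function(construct = NULL, ...) {
  if (is.null(construct))
    construct <- assemble_construct("dimer", arrangement = "HT2")
  chains <- unique(construct$structure$atoms$chain_id)
  blocks <- do.call(rbind, lapply(chains, function(ch)
    data.frame(chain = ch, from = c(1L, 75L), to = c(60L, 140L))))
  couplings <- data.frame(chain_a = chains[1], from_a = 61, to_a = 95,
                          chain_b = chains[2], from_b = 61, to_b = 95,
                          k = 400)
  hnm_from_construct(construct, blocks = blocks, couplings = couplings, ...)
}
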