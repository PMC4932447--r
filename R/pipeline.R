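#' Full synthetic-study pipeline
#'
#' [run_pipeline] composes the whole analysis: build a starting construct,
#' attach a harmonic-network fluctuation model, simulate a stationary
#' trajectory, slice the trailing analysis window into segments, compute the
#' segment-averaged ECD descriptors and supporting metrics, and write a
#' report bundle (TSV tables, PDF figures, JSON metadata) that regenerates
#' identically from the resolved configuration and seed.
#'
#' @name pipeline
NULL

#' Read and validate a pipeline configuration
#'
#' The configuration is a single YAML file; an explicit `seed` is mandatory
#' (the pipeline has no hidden randomness).  See the packaged example
#' `system.file("extdata", "example_run.yaml", package = "ecdyn")`.
#'
#' @param path YAML file.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$seed))
    stop("config must specify an integer 'seed'", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$construct)) cfg$construct <- list()
  cfg$construct$kind <- cfg$construct$kind %||% "dimer"
  cfg$construct$arrangement <- cfg$construct$arrangement %||%
    (if (cfg$construct$kind == "monomer") NULL else "HT2")
  cfg$construct$separation <- cfg$construct$separation %||% 14
  cfg$simulation <- cfg$simulation %||% list()
  cfg$simulation$n_frames <- cfg$simulation$n_frames %||% 4000L
  cfg$simulation$frame_interval <- cfg$simulation$frame_interval %||% 0.1
  cfg$simulation$burn_in_frames <- cfg$simulation$burn_in_frames %||% 0L
  cfg$simulation$satellites <- cfg$simulation$satellites %||% FALSE
  cfg$analysis <- cfg$analysis %||% list()
  cfg$analysis$selection <- cfg$analysis$selection %||%
    (if (isTRUE(cfg$simulation$satellites)) "heavy" else "calpha")
  cfg$analysis$k_max <- cfg$analysis$k_max %||% 20L
  cfg$analysis$window <- cfg$analysis$window %||% 200
  cfg$analysis$superpose <- cfg$analysis$superpose %||% TRUE
  cfg$plan <- cfg$plan %||% list()
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

plan_blocks <- function(plan) {
  if (is.null(plan$blocks)) return(NULL)
  do.call(rbind, lapply(plan$blocks, function(b)
    data.frame(chain = b$chain, from = b$from, to = b$to,
               stringsAsFactors = FALSE)))
}

plan_couplings <- function(plan) {
  if (is.null(plan$couplings)) return(NULL)
  do.call(rbind, lapply(plan$couplings, function(cc)
    data.frame(chain_a = cc$chain_a, from_a = cc$from_a, to_a = cc$to_a,
               chain_b = cc$chain_b, from_b = cc$from_b, to_b = cc$to_b,
               k = cc$k, stringsAsFactors = FALSE)))
}

#' Run the full pipeline
#'
#' @param config a `run_config` (from [read_run_config] /
#'   [validate_run_config]) or the path to a YAML config file.
#' @param output_dir report directory; overrides the config entry.
#' @return Invisibly, a list with the construct, model, trajectory, `ecd`
#'   fit, distance map, pair views and the paths written.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  out <- output_dir %||% config$output_dir %||%
    stop("no output directory given", call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out, "run.log"), "w")
  on.exit(close(log_con))
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    writeLines(sprintf("%-12s %8.2f s", name,
                       proc.time()[["elapsed"]] - t0), log_con)
    r
  }
  construct <- t_stage("construct", do.call(assemble_construct, c(
    list(kind = config$construct$kind),
    if (!is.null(config$construct$arrangement))
      list(arrangement = config$construct$arrangement),
    list(separation = config$construct$separation),
    if (!is.null(config$construct$sequence))
      list(sequence = config$construct$sequence))))
  hnm_args <- config$plan[intersect(names(config$plan),
    c("k_block", "k_linker", "cutoff", "kT", "gamma", "jitter_sd"))]
  model <- t_stage("model", do.call(hnm_from_construct, c(
    list(construct = construct, blocks = plan_blocks(config$plan),
         couplings = plan_couplings(config$plan)), hnm_args)))
  trj <- t_stage("simulate", simulate(
    model, seed = config$seed, n_frames = config$simulation$n_frames,
    frame_interval = config$simulation$frame_interval,
    burn_in_frames = config$simulation$burn_in_frames,
    satellites = config$simulation$satellites))
  fit <- t_stage("ecd", ecd(
    trj, selection = config$analysis$selection, k_max = config$analysis$k_max,
    window = config$analysis$window, take_last = config$analysis$take_last,
    superpose = config$analysis$superpose))
  dmap <- t_stage("distance_map", {
    segs <- slice_segments(trj, window = config$analysis$window,
                           take_last = config$analysis$take_last)
    mean_shortest_distance_map(segs[[length(segs)]], selection = "calpha")
  })
  views <- t_stage("pair_views", {
    al <- construct$alignment
    if (is.null(al)) list() else
      lapply(seq_len(nrow(al)), function(i)
        pair_view(fit$flexibility, al$chain_a[i], al$chain_b[i],
                  construct = construct))
  })
  occ <- NULL
  if (!is.null(config$ss_timeline))
    occ <- t_stage("ss_occupancy", annotate_regions(ss_occupancy(
      parse_dssp_timeline(config$ss_timeline),
      window = config$analysis$take_last)))
  paths <- t_stage("report", write_report(out, config, construct, fit, dmap,
                                          views, occ))
  invisible(list(construct = construct, model = model, trajectory = trj,
                 ecd = fit, distance_map = dmap, pair_views = views,
                 occupancy = occ, paths = paths))
}

write_report <- function(out, config, construct, fit, dmap, views, occ) {
  paths <- character(0)
  wtsv <- function(x, name) {
    p <- file.path(out, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  prof <- fit$flexibility$profile
  wtsv(prof, "flexibility.tsv")
  map <- fit$map$map
  wtsv(data.frame(atom = rownames(map), map, check.names = FALSE),
       "correlation_map.tsv")
  wtsv(data.frame(segment = seq_along(fit$captured),
                  captured = fit$captured), "variance_captured.tsv")
  wtsv(data.frame(residue = rownames(dmap$map), dmap$map,
                  check.names = FALSE), "distance_map.tsv")
  for (v in views)
    wtsv(v$table, sprintf("pair_view_%s_%s.tsv", v$chain_a, v$chain_b))
  if (!is.null(occ)) {
    wtsv(occ$table, "ss_occupancy.tsv")
    if (!is.null(occ$ranges)) wtsv(occ$ranges, "ss_stable_elements.tsv")
  }
  zlim <- c(0, max(map))
  wfig <- function(name, expr) {
    p <- file.path(out, name)
    grDevices::pdf(p, width = 7, height = 6)
    on.exit(grDevices::dev.off(), add = TRUE, after = FALSE)
    force(expr)
    paths <<- c(paths, p)
  }
  wfig("flexibility.pdf", plot_flexibility(fit$flexibility))
  wfig("correlation_map.pdf", plot_correlation_map(fit$map, zlim = zlim))
  wfig("distance_map.pdf", plot(dmap))
  meta <- list(config = unclass(config), seed = config$seed,
               k_max = fit$k_max, n_segments = fit$n_segments,
               correlation_zlim = zlim,
               package_version = as.character(utils::packageVersion("ecdyn")))
  p <- file.path(out, "run_metadata.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("declared outputs missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  paths
}

#' Side-by-side flexibility view of a chain pair
#'
#' Overlays the flexibility profiles of two chains the way dimer profiles
#' are compared: head-to-tail (HT) pairs have the second chain's residue
#' axis reversed (so spatially adjacent residues share an x position), and
#' the second chain may be shifted by an integer residue offset.  When no
#' offset is given it is chosen to minimise the mean C-alpha-to-C-alpha
#' distance between axis-paired residues in the construct's reference
#' geometry.  The underlying flexibility values are never modified.
#'
#' @param flex an `ecd_flex` containing both chains.
#' @param chain_a,chain_b chain identifiers (first chain keeps its axis).
#' @param alignment `"HH"` or `"HT"`; taken from the construct when `NULL`.
#' @param offset integer residue shift of the second chain's axis; derived
#'   from the construct geometry when `NULL`.
#' @param construct the `construct` the trajectory came from (needed to
#'   derive `alignment`/`offset` defaults).
#' @return A `chain_pair_view`: a table with columns `position` (shared
#'   axis), `chain`, `residue_index`, `F`, plus the recorded `alignment`,
#'   `reversed` flag and `offset`.
#' @export
pair_view <- function(flex, chain_a, chain_b, alignment = NULL,
                      offset = NULL, construct = NULL) {
  stopifnot(inherits(flex, "ecd_flex"))
  p <- flex$profile
  pa <- p[p$chain_id == chain_a, ]
  pb <- p[p$chain_id == chain_b, ]
  if (!nrow(pa) || !nrow(pb))
    stop("both chains must be present in the flexibility profile",
         call. = FALSE)
  if (is.null(alignment)) {
    if (is.null(construct))
      stop("give 'alignment' or a 'construct' to derive it from", call. = FALSE)
    alignment <- classify_pair_alignment(construct, chain_a, chain_b)
  }
  if (!alignment %in% c("HH", "HT"))
    stop("alignment must be 'HH' or 'HT'", call. = FALSE)
  reversed <- alignment == "HT"
  nb <- max(pb$residue_index)
  pos_b <- function(j, s) (if (reversed) nb + 1 - j else j) + s
  if (is.null(offset)) {
    if (is.null(construct))
      stop("give 'offset' or a 'construct' to derive it from", call. = FALSE)
    offset <- best_offset(construct, chain_a, chain_b, reversed)
  }
  tab <- rbind(
    data.frame(position = pa$residue_index, chain = chain_a,
               residue_index = pa$residue_index, F = pa$F,
               stringsAsFactors = FALSE),
    data.frame(position = pos_b(pb$residue_index, offset), chain = chain_b,
               residue_index = pb$residue_index, F = pb$F,
               stringsAsFactors = FALSE))
  structure(list(table = tab, chain_a = chain_a, chain_b = chain_b,
                 alignment = alignment, reversed = reversed,
                 offset = offset),
            class = "chain_pair_view")
}

# offset minimising the mean inter-chain C-alpha distance between residues
# paired by equal axis position; ties resolved toward the smallest |offset|
best_offset <- function(construct, chain_a, chain_b, reversed) {
  at <- construct$structure$atoms
  xyz <- construct$structure$coords[1, , ]
  ca_a <- xyz[at$is_calpha & at$chain_id == chain_a, , drop = FALSE]
  ca_b <- xyz[at$is_calpha & at$chain_id == chain_b, , drop = FALSE]
  na <- nrow(ca_a); nb <- nrow(ca_b)
  shifts <- seq(-(nb - 1), na - 1)
  shifts <- shifts[order(abs(shifts), shifts)]
  score <- vapply(shifts, function(s) {
    i <- seq_len(na)
    j <- if (reversed) nb + 1 - (i - s) else i - s
    ok <- j >= 1 & j <= nb
    if (sum(ok) < min(5, na)) return(Inf)
    mean(sqrt(rowSums((ca_a[i[ok], , drop = FALSE] -
                         ca_b[j[ok], , drop = FALSE])^2)))
  }, numeric(1))
  shifts[which.min(score)]
}

#' @export
print.chain_pair_view <- function(x, ...) {
  cat("chain-pair flexibility view:", x$chain_a, "vs", x$chain_b,
      "(", x$alignment, ")\n")
  cat("  second chain reversed:", x$reversed, "; offset:", x$offset,
      "residues\n")
  invisible(x)
}

#' @export
plot.chain_pair_view <- function(x, ...) {
  tab <- x$table
  cols <- grDevices::hcl.colors(2, "Dark 2")
  chains <- c(x$chain_a, x$chain_b)
  graphics::plot(NULL, xlim = range(tab$position), ylim = range(c(0, tab$F)),
                 xlab = "aligned residue position",
                 ylab = expression(F[C * alpha]),
                 main = sprintf("%s vs %s (%s, offset %d)", x$chain_a,
                                x$chain_b, x$alignment, x$offset), ...)
  for (i in 1:2) {
    sel <- tab$chain == chains[i]
    graphics::lines(tab$position[sel], tab$F[sel], col = cols[i])
  }
  graphics::legend("topright", legend = chains, col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}
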