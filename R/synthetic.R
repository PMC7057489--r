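#' Parameters for the synthetic-region generator
#'
#' Defaults describe a sparse rural region: an 8x8 road lattice at 25-km
#' spacing with ~15% of redundant links missing, design speeds of 50-90 km/h,
#' 15 population centres with log-normal populations (median ~9000),
#' 150 small population blocks, and 5 health facilities of which at least one
#' qualifies as a palliative care centre (bed counts are log-normal, so large
#' hospitals are rare apart from the one guaranteed regional hospital).
#'
#' @param n_grid Nodes per side of the base grid.
#' @param edge_keep_prob Probability a grid edge is kept (edges are only ever
#'   dropped when the network stays connected).
#' @param speed_range Two km/h values bounding uniform edge design speeds.
#' @param n_centres,n_blocks,n_facilities Entity counts (each `>= 1`).
#' @param pop_lognormal_params `c(meanlog, sdlog)` for centre populations;
#'   block populations use the same `sdlog` with a smaller `meanlog`.
#' @param demographic_beta_params Named list of `c(alpha, beta)` for
#'   `over75`, `female`, `alone` proportions.
#' @param readiness_prob Probability each binary readiness flag is "yes".
#' @param seed Master seed; every random layer derives its own sub-stream
#'   from it, so adding a layer does not shift the others.
#' @return A validated list of class `synth_params`.
#' @export
synth_params <- function(n_grid = 8,
                         edge_keep_prob = 0.85,
                         speed_range = c(50, 90),
                         n_centres = 15,
                         n_blocks = 150,
                         n_facilities = 5,
                         pop_lognormal_params = c(log(9000), 0.7),
                         demographic_beta_params = list(
                           over75 = c(3, 27),
                           female = c(60, 60),
                           alone = c(4, 26)),
                         readiness_prob = 0.5,
                         seed = 1) {
  if (!is_count(n_grid) || n_grid < 2) ssm_abort("n_grid must be >= 2")
  if (edge_keep_prob < 0 || edge_keep_prob > 1) {
    ssm_abort("edge_keep_prob must lie in [0, 1]")
  }
  if (length(speed_range) != 2 || any(speed_range <= 0) ||
      speed_range[1] > speed_range[2]) {
    ssm_abort("speed_range must be two positive km/h values, low <= high")
  }
  for (nm in c("n_centres", "n_blocks", "n_facilities")) {
    if (!is_count(get(nm)) || get(nm) < 1) ssm_abort(nm, " must be >= 1")
  }
  if (n_centres > n_grid^2) {
    ssm_abort("more centres than network nodes (", n_centres, " > ",
              n_grid^2, ")")
  }
  if (readiness_prob < 0 || readiness_prob > 1) {
    ssm_abort("readiness_prob must lie in [0, 1]")
  }
  structure(list(n_grid = n_grid, edge_keep_prob = edge_keep_prob,
                 speed_range = speed_range, n_centres = n_centres,
                 n_blocks = n_blocks, n_facilities = n_facilities,
                 pop_lognormal_params = pop_lognormal_params,
                 demographic_beta_params = demographic_beta_params,
                 readiness_prob = readiness_prob, seed = seed),
            class = "synth_params")
}

# one RNG sub-stream per generation layer, derived from the master seed
with_substream <- function(seed, layer, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed((as.integer(seed) %% 1000000L) * 1000L + layer)
  code
}

#' Generate a seeded synthetic region
#'
#' Builds a complete, internally consistent region dataset: a connected
#' perturbed-grid road network with speed-attributed edges, population blocks
#' scattered around network nodes, population centres with demographic
#' proportions, deprivation indicators, physician counts and binary readiness
#' flags, and facilities of two kinds with bed counts — the first facility is
#' always a large hospital so at least one palliative care centre exists.
#' Output is identical for identical parameters (including seed).
#'
#' @param params A [synth_params()] object.
#' @return An `ssm_dataset`.
#' @export
generate_region <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  n <- params$n_grid
  seed <- params$seed
  spacing <- 25000  # metres between grid nodes: sparse rural inter-community scale

  grid_xy <- with_substream(seed, 1L, {
    gx <- rep(seq_len(n), times = n) * spacing
    gy <- rep(seq_len(n), each = n) * spacing
    cbind(x = gx + stats::runif(n^2, -2000, 2000),
          y = gy + stats::runif(n^2, -2000, 2000))
  })
  node_of <- function(i, j) (j - 1) * n + i

  # full lattice edges (2 * n * (n - 1) of them), then thin while connected
  from <- integer(0); to <- integer(0)
  for (j in seq_len(n)) for (i in seq_len(n - 1)) {
    from <- c(from, node_of(i, j)); to <- c(to, node_of(i + 1, j))
  }
  for (j in seq_len(n - 1)) for (i in seq_len(n)) {
    from <- c(from, node_of(i, j)); to <- c(to, node_of(i, j + 1))
  }
  keep <- rep(TRUE, length(from))
  with_substream(seed, 2L, {
    drop_candidates <- which(stats::runif(length(from)) > params$edge_keep_prob)
    for (e in sample(drop_candidates)) {
      keep[e] <- FALSE
      g <- igraph::graph_from_edgelist(cbind(from[keep], to[keep]),
                                       directed = FALSE)
      g <- igraph::add_vertices(g, max(0, n^2 - igraph::vcount(g)))
      if (!igraph::is_connected(g)) keep[e] <- TRUE
    }
  })
  from <- from[keep]; to <- to[keep]

  segments <- with_substream(seed, 3L, {
    euclid_km <- sqrt((grid_xy[from, "x"] - grid_xy[to, "x"])^2 +
                      (grid_xy[from, "y"] - grid_xy[to, "y"])^2) / 1000
    data.frame(
      x1 = grid_xy[from, "x"], y1 = grid_xy[from, "y"],
      x2 = grid_xy[to, "x"], y2 = grid_xy[to, "y"],
      length_km = euclid_km * stats::runif(length(from), 1.0, 1.3),
      speed_kmh = stats::runif(length(from), params$speed_range[1],
                               params$speed_range[2]))
  })
  network <- build_graph(segments)

  centres <- with_substream(seed, 4L, {
    idx <- sample(n^2, params$n_centres)
    nc <- params$n_centres
    bp <- params$demographic_beta_params
    data.frame(
      community_id = sprintf("C%03d", seq_len(nc)),
      name = sprintf("Community %d", seq_len(nc)),
      x = grid_xy[idx, "x"], y = grid_xy[idx, "y"],
      population = pmax(100, round(stats::rlnorm(
        nc, params$pop_lognormal_params[1], params$pop_lognormal_params[2]))),
      pct_over75 = stats::rbeta(nc, bp$over75[1], bp$over75[2]),
      pct_female = stats::rbeta(nc, bp$female[1], bp$female[2]),
      pct_alone = stats::rbeta(nc, bp$alone[1], bp$alone[2]),
      fp_count = stats::rpois(nc, 5),
      vx_1 = stats::runif(nc, 0.05, 0.45),   # incomplete high school
      vx_2 = stats::runif(nc, 0.03, 0.20),   # unemployment rate
      vx_3 = stats::runif(nc, 0.05, 0.30),   # lone-parent families
      vx_4 = stats::runif(nc, 30000, 90000), # average total income
      vx_5 = stats::runif(nc, 0.40, 0.90),   # homeownership
      vx_6 = stats::runif(nc, 0.40, 0.80),   # employment ratio
      vx_7 = stats::runif(nc, 0.05, 0.45),   # configurable seventh slot
      aware = stats::runif(nc) < params$readiness_prob,
      education = stats::runif(nc) < params$readiness_prob,
      telemedicine = stats::runif(nc) < params$readiness_prob,
      fp_adequate_override = NA,
      momentum = stats::runif(nc) < params$readiness_prob,
      stringsAsFactors = FALSE)
  })

  blocks <- with_substream(seed, 5L, {
    nb <- params$n_blocks
    anchor <- sample(n^2, nb, replace = TRUE)
    data.frame(
      block_id = sprintf("B%04d", seq_len(nb)),
      x = grid_xy[anchor, "x"] + stats::runif(nb, -3000, 3000),
      y = grid_xy[anchor, "y"] + stats::runif(nb, -3000, 3000),
      population = pmax(1, round(stats::rlnorm(
        nb, params$pop_lognormal_params[1] - 3,
        params$pop_lognormal_params[2]))),
      stringsAsFactors = FALSE)
  })

  facilities <- with_substream(seed, 6L, {
    nf <- params$n_facilities
    idx <- sample(n^2, nf, replace = TRUE)
    kind <- sample(c("hospital", "hospice"), nf, replace = TRUE)
    # rural hospitals are mostly small; >500-bed centres are rare
    beds <- ifelse(kind == "hospital",
                   round(stats::rlnorm(nf, log(150), 0.8)),
                   round(stats::runif(nf, 1, 12)))
    # guarantee at least one qualifying palliative care centre
    kind[1] <- "hospital"
    beds[1] <- round(stats::runif(1, 550, 900))
    data.frame(
      facility_id = sprintf("F%02d", seq_len(nf)),
      name = sprintf("Facility %d", seq_len(nf)),
      x = grid_xy[idx, "x"], y = grid_xy[idx, "y"],
      kind = kind, beds = beds, stringsAsFactors = FALSE)
  })

  structure(list(centres = centres, blocks = blocks, network = network,
                 facilities = facilities),
            class = "ssm_dataset")
}

#' Write a dataset to the on-disk input formats
#'
#' Serializes an `ssm_dataset` into the file set [read_dataset()] consumes:
#' `centres.csv`, `blocks.csv`, `network.geojson`, `facilities.csv`. Readiness
#' flags are written as yes/no. The network must carry its source segments
#' (as networks built by [build_graph()] do).
#'
#' @param dataset An `ssm_dataset`.
#' @param dir Target directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_region <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ssm_dataset"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) ssm_abort("cannot create directory: ", dir,
                       class = "ssm_io_error")
  }
  centres <- dataset$centres
  for (col in c(READINESS_COLS, "fp_adequate_override")) {
    if (col %in% names(centres)) {
      centres[[col]] <- ifelse(is.na(centres[[col]]), "",
                               ifelse(centres[[col]], "yes", "no"))
    }
  }
  centres$centre_node <- NULL
  centres$nearest_centre_minutes <- NULL
  paths <- c(centres = file.path(dir, "centres.csv"),
             blocks = file.path(dir, "blocks.csv"),
             network = file.path(dir, "network.geojson"),
             facilities = file.path(dir, "facilities.csv"))
  utils::write.csv(centres, paths["centres"], row.names = FALSE)
  utils::write.csv(dataset$blocks, paths["blocks"], row.names = FALSE)
  utils::write.csv(dataset$facilities, paths["facilities"], row.names = FALSE)

  seg <- dataset$network$segments
  if (is.null(seg)) ssm_abort("network carries no source segments to write")
  features <- lapply(seq_len(nrow(seg)), function(i) {
    list(type = "Feature",
         geometry = list(
           type = "LineString",
           coordinates = list(c(seg$x1[i], seg$y1[i]),
                              c(seg$x2[i], seg$y2[i]))),
         properties = list(length_km = seg$length_km[i],
                           speed_kmh = seg$speed_kmh[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       paths["network"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
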