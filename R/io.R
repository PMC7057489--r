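VANDIX_COLS <- paste0("vx_", 1:7)
READINESS_COLS <- c("aware", "education", "telemedicine", "momentum")

parse_yes_no <- function(x, col) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("yes", "y", "true", "1")] <- TRUE
  out[v %in% c("no", "n", "false", "0")] <- FALSE
  bad <- !is.na(v) & v != "" & is.na(out)
  if (any(bad)) {
    ssm_abort("column '", col, "' must be yes/no, got: ",
              paste(unique(v[bad]), collapse = ", "))
  }
  out
}

require_cols <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    ssm_abort(what, " missing mandatory column(s): ",
              paste(missing_cols, collapse = ", "))
  }
}

check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    ssm_abort("duplicate ", what, ": ", paste(dup, collapse = ", "))
  }
}

read_centres <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("community_id", "name", "x", "y", "population",
                     "pct_over75", "pct_female", "pct_alone", "fp_count",
                     VANDIX_COLS), "centres table")
  check_unique(df$community_id, "community_id")
  if (any(df$population < 0, na.rm = TRUE)) {
    ssm_abort("centres table: population must be >= 0")
  }
  for (col in c("pct_over75", "pct_female", "pct_alone")) {
    v <- df[[col]]
    if (any(!is.finite(v) | v < 0 | v > 1)) {
      ssm_abort("centres table: ", col, " must be a proportion in [0, 1]")
    }
  }
  if (any(df$fp_count < 0 | df$fp_count != trunc(df$fp_count), na.rm = TRUE)) {
    ssm_abort("centres table: fp_count must be a non-negative integer")
  }
  # flags compiled by hand may be incomplete: absent column or blank cell
  # defaults to "no" with a warning rather than an error
  for (col in READINESS_COLS) {
    if (!col %in% names(df)) {
      ssm_warn("centres table: readiness column '", col,
               "' absent; defaulting to no")
      df[[col]] <- FALSE
    } else {
      v <- parse_yes_no(df[[col]], col)
      if (anyNA(v)) {
        ssm_warn("centres table: blank '", col,
                 "' flag(s); defaulting to no")
        v[is.na(v)] <- FALSE
      }
      df[[col]] <- v
    }
  }
  if ("fp_adequate_override" %in% names(df)) {
    df$fp_adequate_override <- parse_yes_no(df$fp_adequate_override,
                                            "fp_adequate_override")
  } else {
    df$fp_adequate_override <- NA
  }
  df$community_id <- as.character(df$community_id)
  df
}

read_blocks <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    feats <- gj$features %||% list()
    df <- do.call(rbind, lapply(feats, function(f) {
      if (!identical(f$geometry$type, "Point")) {
        ssm_abort("blocks GeoJSON must contain Point features")
      }
      data.frame(block_id = as.character(f$properties$block_id %||% NA),
                 x = f$geometry$coordinates[[1]],
                 y = f$geometry$coordinates[[2]],
                 population = as.numeric(f$properties$population %||% NA),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(df)) df <- data.frame(block_id = character(), x = numeric(),
                                      y = numeric(), population = numeric())
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  require_cols(df, c("block_id", "x", "y", "population"), "blocks table")
  check_unique(df$block_id, "block_id")
  if (any(!is.finite(df$population) | df$population < 0)) {
    ssm_abort("blocks table: population must be >= 0")
  }
  df$block_id <- as.character(df$block_id)
  df
}

read_facilities <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(df, c("facility_id", "name", "x", "y", "kind", "beds"),
               "facilities table")
  check_unique(df$facility_id, "facility_id")
  bad <- !df$kind %in% c("hospital", "hospice")
  if (any(bad)) {
    ssm_abort("facilities table: kind must be 'hospital' or 'hospice' (row ",
              which(bad)[1], ": '", df$kind[which(bad)[1]], "')")
  }
  if (any(!is.finite(df$beds) | df$beds < 0)) {
    ssm_abort("facilities table: beds must be >= 0")
  }
  df$facility_id <- as.character(df$facility_id)
  df
}

# GeoJSON LineString FeatureCollection -> segment table for build_graph().
# Only the two endpoints of each LineString define nodes.
read_network_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features %||% list()
  if (length(feats) == 0) ssm_abort("network file contains no features")
  rows <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "LineString")) {
      ssm_abort("network GeoJSON must contain LineString features")
    }
    coords <- f$geometry$coordinates
    a <- coords[[1]]
    b <- coords[[length(coords)]]
    props <- f$properties
    if (is.null(props$length_km) || is.null(props$speed_kmh)) {
      ssm_abort("network feature missing length_km or speed_kmh property")
    }
    data.frame(x1 = a[[1]], y1 = a[[2]], x2 = b[[1]], y2 = b[[2]],
               length_km = as.numeric(props$length_km),
               speed_kmh = as.numeric(props$speed_kmh))
  })
  do.call(rbind, rows)
}

#' Read a complete model dataset
#'
#' Loads the four input artifacts — community attribute table, population
#' blocks, road network, facilities — validates them, and bundles them into a
#' single dataset object. All coordinates are assumed to share one planar
#' metric coordinate system; the package never reprojects.
#'
#' @param centres_path CSV of population centres: `community_id, name, x, y,
#'   population, pct_over75, pct_female, pct_alone, fp_count, vx_1..vx_7`,
#'   plus yes/no readiness columns `aware, education, telemedicine, momentum`
#'   and optionally `fp_adequate_override`.
#' @param blocks_path Population blocks as CSV (`block_id, x, y, population`)
#'   or a GeoJSON Point FeatureCollection with those properties.
#' @param network_path Road network as a GeoJSON LineString FeatureCollection
#'   with `length_km` and `speed_kmh` properties per feature.
#' @param facilities_path CSV of health facilities: `facility_id, name, x, y,
#'   kind` (`hospital` or `hospice`) and `beds`.
#' @return An object of class `ssm_dataset`: a list with `centres`, `blocks`,
#'   `network` (a [road_network][build_graph]) and `facilities`.
#' @export
read_dataset <- function(centres_path, blocks_path, network_path,
                         facilities_path) {
  for (p in c(centres_path, blocks_path, network_path, facilities_path)) {
    if (!file.exists(p)) ssm_abort("input file not found: ", p)
  }
  structure(
    list(
      centres = read_centres(centres_path),
      blocks = read_blocks(blocks_path),
      network = build_graph(read_network_geojson(network_path)),
      facilities = read_facilities(facilities_path)
    ),
    class = "ssm_dataset"
  )
}

#' @export
print.ssm_dataset <- function(x, ...) {
  cat(sprintf(
    "<ssm_dataset> %d centres, %d blocks, %d facilities; network: %d nodes / %d edges\n",
    nrow(x$centres), nrow(x$blocks), nrow(x$facilities),
    nrow(x$network$nodes), nrow(x$network$edges)))
  invisible(x)
}

#' Write the ranked suitability table
#'
#' Serializes a result table (see [run_ssm()]) to CSV with scores formatted at
#' `display_decimals` decimal places using half-away-from-zero rounding, the
#' convention under which the published score tables reproduce. Full-precision
#' scores are rounded only here, at the serialization boundary.
#'
#' @param results A results data frame sorted by rank, as returned by
#'   [run_ssm()] or [rank_and_flag()].
#' @param path Output CSV path.
#' @param display_decimals Decimal places for score columns.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(results, path, display_decimals = 2) {
  cols <- c("community_id", "name", "population_score", "isolation_score",
            "vulnerability_score", "readiness_score", "ssm_score",
            "eligible", "rank")
  require_cols(results, cols, "results table")
  if (nrow(results) > 0 && is.unsorted(results$rank)) {
    ssm_abort("results must be sorted by rank before writing")
  }
  out <- results[, cols]
  score_cols <- c("population_score", "isolation_score", "vulnerability_score",
                  "readiness_score", "ssm_score")
  for (col in score_cols) {
    out[[col]] <- vapply(out[[col]], round_display, character(1),
                         dp = display_decimals)
  }
  out$eligible <- tolower(as.character(out$eligible))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) ssm_abort("cannot write ranking to: ", path, class = "ssm_io_error")
  invisible(path)
}
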