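#' Does a facility qualify as a palliative care centre?
#'
#' A facility provides specialized palliative care, for the purposes of the
#' isolation filter, when it is a general hospital with strictly more than
#' `hospital_min_beds` beds (default 500) or a dedicated hospice with strictly
#' more than `hospice_min_beds` hospice beds (default 3). Both boundaries are
#' exclusive: a 500-bed hospital and a 3-bed hospice do not qualify.
#'
#' @param facility A list or one-row data frame with `kind` and `beds`.
#' @param config An `ssm_config`.
#' @return Logical scalar.
#' @export
is_palliative_centre <- function(facility, config = model_config()) {
  stopifnot(inherits(config, "ssm_config"))
  kind <- as.character(facility$kind)
  beds <- as.numeric(facility$beds)
  (kind == "hospital" & beds > config$hospital_min_beds) |
    (kind == "hospice" & beds > config$hospice_min_beds)
}

#' Network nodes hosting palliative care centres
#'
#' Filters the facility table to qualifying palliative care centres and snaps
#' each to its nearest network node. May be empty.
#'
#' @param facilities Facility data frame (`facility_id, x, y, kind, beds`).
#' @param network A `road_network`.
#' @param config An `ssm_config`.
#' @return Character vector of unique node identifiers (possibly empty).
#' @export
palliative_centre_nodes <- function(facilities, network,
                                    config = model_config()) {
  stopifnot(inherits(network, "road_network"))
  if (nrow(facilities) == 0) return(character(0))
  keep <- is_palliative_centre(facilities, config)
  qualifying <- facilities[keep, , drop = FALSE]
  if (nrow(qualifying) == 0) return(character(0))
  nodes <- vapply(seq_len(nrow(qualifying)), function(i) {
    snap_to_node(network, c(qualifying$x[i], qualifying$y[i]))
  }, character(1))
  unique(nodes)
}

#' Select candidate communities
#'
#' Applies the two selection filters in sequence: keep communities with
#' population strictly greater than `min_population`, then keep those whose
#' travel time to the nearest palliative care centre strictly exceeds
#' `catchment_minutes` (communities that cannot reach any centre at all count
#' as maximally isolated and are retained). Input order is preserved.
#'
#' When no facility qualifies as a palliative care centre the isolation filter
#' is vacuous: all population-qualified communities are retained, with a
#' warning.
#'
#' @param dataset An `ssm_dataset`.
#' @param config An `ssm_config`.
#' @return The `centres` data frame restricted to candidates, with an added
#'   `centre_node` column (snapped node) and `nearest_centre_minutes` column.
#' @export
select_candidates <- function(dataset, config = model_config()) {
  stopifnot(inherits(dataset, "ssm_dataset"), inherits(config, "ssm_config"))
  centres <- dataset$centres
  centres$centre_node <- vapply(seq_len(nrow(centres)), function(i) {
    snap_to_node(dataset$network, c(centres$x[i], centres$y[i]))
  }, character(1))

  pop_ok <- centres$population > config$min_population
  centres <- centres[pop_ok, , drop = FALSE]

  sites <- palliative_centre_nodes(dataset$facilities, dataset$network, config)
  if (length(sites) == 0) {
    ssm_warn("no facility qualifies as a palliative care centre; ",
             "isolation filter not applied")
    centres$nearest_centre_minutes <- Inf
    return(centres)
  }
  centres$nearest_centre_minutes <- vapply(centres$centre_node, function(nd) {
    nearest_site_minutes(dataset$network, nd, sites)$minutes
  }, numeric(1))
  centres[centres$nearest_centre_minutes > config$catchment_minutes, ,
          drop = FALSE]
}
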