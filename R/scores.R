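# default direction vector for the deprivation composite: TRUE marks
# indicators where a HIGH raw value means LESS deprivation (average income,
# homeownership, employment ratio); those are complemented after scaling.
# Slot 7 is a user-configurable indicator and defaults to deprivation-direction.
DEFAULT_VANDIX_DIRECTIONS <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)

#' Population within a drive-time catchment
#'
#' Sums the population of every block whose nearest network node lies inside
#' the origin community's drive-time service area. Blocks attach to the
#' network at their nearest node with zero access cost.
#'
#' @param network A `road_network`.
#' @param centre_node Node identifier of the community.
#' @param blocks Block data frame (`block_id, x, y, population`), optionally
#'   pre-snapped via a `block_node` column.
#' @param limit_minutes Drive-time budget in minutes (inclusive `<=`).
#' @return Total persons (numeric scalar).
#' @export
catchment_population <- function(network, centre_node, blocks, limit_minutes) {
  if (nrow(blocks) == 0) return(0)
  if (is.null(blocks$block_node)) {
    blocks$block_node <- vapply(seq_len(nrow(blocks)), function(i) {
      snap_to_node(network, c(blocks$x[i], blocks$y[i]))
    }, character(1))
  }
  reach <- service_area(network, centre_node, limit_minutes)
  sum(blocks$population[blocks$block_node %in% reach])
}

#' Population component score
#'
#' The community with the largest catchment population scores 1; every other
#' community scores its catchment population as a proportion of that maximum.
#' If every catchment is empty all scores are 0.
#'
#' @param catchment_pops Named numeric vector, community -> persons.
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
#' @examples
#' population_component(c(A = 60000, B = 30000))  # A = 1, B = 0.5
population_component <- function(catchment_pops) {
  if (length(catchment_pops) == 0) ssm_abort("at least one community required")
  if (any(catchment_pops < 0)) ssm_abort("catchment populations must be >= 0")
  m <- max(catchment_pops)
  if (m == 0) return(catchment_pops * 0)
  catchment_pops / m
}

#' Isolation component score
#'
#' Travel time to the nearest palliative care centre, scaled linearly against
#' the isolation cap: communities at or beyond `cap_minutes` (default 4 h)
#' score 1, closer communities score proportionally. Unreachable (`Inf`) is
#' maximal isolation, score 1.
#'
#' @param minutes_to_nearest Non-negative minutes (vectorized); `Inf` allowed.
#' @param cap_minutes Saturation cap in minutes.
#' @return Scores in `[0, 1]`.
#' @export
isolation_component <- function(minutes_to_nearest, cap_minutes = 240) {
  stopifnot_scalar_number(cap_minutes, "cap_minutes", positive = TRUE)
  if (any(is.na(minutes_to_nearest)) || any(minutes_to_nearest < 0)) {
    ssm_abort("minutes_to_nearest must be non-negative (Inf for unreachable)")
  }
  pmin(minutes_to_nearest / cap_minutes, 1)
}

#' Scale raw values to sub-scores
#'
#' The scaling applied to each vulnerability variable over its reference set:
#' `"max"` divides by the reference maximum (the highest community scores 1;
#' all-zero input stays all 0), `"minmax"` maps the reference range onto
#' `[0, 1]` (a degenerate range collapses to all 0, with a warning), `"none"`
#' passes values through clipped to `[0, 1]`.
#'
#' @param values Named numeric vector (finite; non-negative for `"max"`).
#' @param mode `"max"`, `"minmax"` or `"none"`.
#' @return Named numeric vector of sub-scores in `[0, 1]`.
#' @export
scale_subscores <- function(values, mode = c("max", "minmax", "none")) {
  mode <- match.arg(mode)
  if (any(!is.finite(values))) ssm_abort("values must be finite")
  switch(mode,
    max = {
      if (any(values < 0)) ssm_abort("mode 'max' requires non-negative values")
      m <- max(values)
      if (m == 0) values * 0 else values / m
    },
    minmax = {
      lo <- min(values)
      hi <- max(values)
      if (hi == lo) {
        if (length(values) == 1) {
          ssm_warn("single-value reference under minmax scaling; sub-scores 0")
        }
        values * 0
      } else {
        (values - lo) / (hi - lo)
      }
    },
    none = pmin(pmax(values, 0), 1)
  )
}

#' Deprivation composite (VANDIX) score
#'
#' A census-based socio-economic deprivation composite over seven
#' dissemination-area indicators (incomplete high school, unemployment, lone
#' parenthood, average income, homeownership, employment ratio, plus one
#' configurable slot). Each indicator is scaled over the reference set of
#' communities; indicators where a high raw value is protective (marked
#' `TRUE` in `directions`) are complemented (`1 - scaled`) so that higher
#' always means more deprived; the score is the unweighted mean of the seven
#' adjusted values.
#'
#' @param indicators Numeric vector of the community's seven raw indicators.
#' @param reference Matrix or data frame (communities x 7) of raw indicators
#'   defining the scaling range; must include comparable columns in the same
#'   order. Non-empty.
#' @param directions Logical vector of length 7; `TRUE` where high raw value
#'   means less deprivation.
#' @param mode Scaling mode, as in [scale_subscores()].
#' @return Score in `[0, 1]`.
#' @export
vandix_score <- function(indicators, reference,
                         directions = DEFAULT_VANDIX_DIRECTIONS,
                         mode = c("max", "minmax", "none")) {
  mode <- match.arg(mode)
  if (length(indicators) != 7) ssm_abort("exactly 7 indicators required")
  reference <- as.matrix(reference)
  if (nrow(reference) == 0 || ncol(reference) != 7) {
    ssm_abort("reference must be a non-empty communities x 7 table")
  }
  if (length(directions) != 7 || !is.logical(directions)) {
    ssm_abort("directions must be 7 logicals")
  }
  adjusted <- vapply(1:7, function(j) {
    ref <- reference[, j]
    x <- indicators[j]
    scaled <- switch(mode,
      max = {
        if (any(ref < 0) || x < 0) {
          ssm_abort("mode 'max' requires non-negative indicator values")
        }
        m <- max(ref)
        if (m == 0) 0 else x / m
      },
      minmax = {
        lo <- min(ref)
        hi <- max(ref)
        if (hi == lo) {
          if (nrow(reference) == 1) {
            ssm_warn("single-community reference under minmax; sub-score 0")
          }
          0
        } else {
          (x - lo) / (hi - lo)
        }
      },
      none = x
    )
    scaled <- min(max(scaled, 0), 1)
    if (directions[j]) 1 - scaled else scaled
  }, numeric(1))
  mean(adjusted)
}

#' Vulnerability (palliative care index) score
#'
#' The mean of four equally weighted sub-scores, each in `[0, 1]`: percentage
#' of the population over 75, percentage female, percentage living alone, and
#' the deprivation composite. `(age + sex + alone + vandix) / 4`.
#'
#' @param sub Named list or data frame with `age`, `sex`, `alone`, `vandix`,
#'   each in `[0, 1]` (vectorized over communities).
#' @return Score(s) in `[0, 1]`.
#' @export
#' @examples
#' pcix_vulnerability(list(age = 0.11, sex = 0.49, alone = 0.09, vandix = 0.47))
pcix_vulnerability <- function(sub) {
  vals <- cbind(sub$age, sub$sex, sub$alone, sub$vandix)
  if (anyNA(vals)) ssm_abort("sub-scores must include age, sex, alone, vandix")
  if (any(vals < 0 | vals > 1)) ssm_abort("sub-scores must lie in [0, 1]")
  as.numeric((vals[, 1] + vals[, 2] + vals[, 3] + vals[, 4]) / 4)
}

#' Is the family-physician supply adequate?
#'
#' Adequate when the community has at most `ratio_max` persons per family
#' physician (inclusive boundary). A community with people but no physician is
#' never adequate; an empty community is vacuously adequate.
#'
#' @param population Persons (vectorized).
#' @param fp_count Family physicians (vectorized).
#' @param ratio_max Persons per physician, inclusive `<=` (default 1307).
#' @return Logical.
#' @export
#' @examples
#' physician_supply_adequate(13070, 10)  # exactly at the benchmark: TRUE
physician_supply_adequate <- function(population, fp_count,
                                      ratio_max = 1307) {
  if (any(population < 0) || any(fp_count < 0)) {
    ssm_abort("population and fp_count must be >= 0")
  }
  ifelse(population == 0, TRUE,
         ifelse(fp_count == 0, FALSE, population / fp_count <= ratio_max))
}

#' Community readiness score
#'
#' Five binary indicators of willingness and capacity — a local hospice
#' society (awareness), a college or university within reach (education),
#' regular telemedicine use, adequate family-physician supply, and momentum
#' towards a local hospice — each worth 0.2 when present. Computed as
#' `sum(flags) / 5` so the result is exact on the 0.2 grid.
#'
#' @param flags Logical vector of the five flags, or a list/data frame with
#'   `aware`, `education`, `telemedicine`, `fp_adequate`, `momentum`
#'   (vectorized over communities when a data frame).
#' @return Score(s) in `{0, 0.2, 0.4, 0.6, 0.8, 1}`.
#' @export
readiness_component <- function(flags) {
  if (is.list(flags)) {
    m <- cbind(flags$aware, flags$education, flags$telemedicine,
               flags$fp_adequate, flags$momentum)
    if (anyNA(m)) {
      ssm_abort("flags must include aware, education, telemedicine, ",
                "fp_adequate, momentum with no missing values")
    }
    return(as.numeric(rowSums(m) / 5))
  }
  if (!is.logical(flags) || length(flags) != 5 || anyNA(flags)) {
    ssm_abort("flags must be five non-missing logicals")
  }
  sum(flags) / 5
}
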