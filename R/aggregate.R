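#' Combine component scores into a final suitability score
#'
#' Weighted mean of the four components, `sum(w * s) / sum(w)`, so any
#' non-negative weight vector with positive sum yields a score in `[0, 1]`.
#' With equal weights this is exactly the sum of the four components divided
#' by four, the published scoring rule.
#'
#' @param components Numeric vector of the four component scores (population,
#'   isolation, vulnerability, readiness), or a matrix / data frame with those
#'   four columns for vectorized use.
#' @param weights Four non-negative weights with positive sum.
#' @return Score(s) in `[0, 1]`, at full precision (no rounding).
#' @export
#' @examples
#' combine_components(c(0.81, 0.94, 0.29, 0.80))  # 0.71
combine_components <- function(components, weights = c(1, 1, 1, 1)) {
  if (!is.numeric(weights) || length(weights) != 4 || any(weights < 0)) {
    ssm_abort("weights must be four non-negative numbers")
  }
  if (sum(weights) <= 0) ssm_abort("weights must have a positive sum")
  m <- if (is.null(dim(components)) && !is.data.frame(components)) {
    matrix(components, nrow = 1)
  } else {
    as.matrix(components)
  }
  if (ncol(m) != 4) ssm_abort("exactly four component scores required")
  if (anyNA(m) || any(m < 0 | m > 1)) {
    ssm_abort("component scores must lie in [0, 1]")
  }
  as.numeric(m %*% weights / sum(weights))
}

#' Round to a fixed number of decimals, half away from zero
#'
#' Decimal rounding as done by hand in published score tables: ties go away
#' from zero (0.325 -> "0.33"), decided on the decimal representation of the
#' value rather than on binary floating point, so values that are exact
#' decimals round the way a reader expects. Used only at the display /
#' serialization boundary.
#'
#' @param x Finite numeric (vectorized).
#' @param dp Decimal places, `>= 0`.
#' @return Character vector of fixed-point decimal strings.
#' @export
#' @examples
#' round_display(0.325, 2)  # "0.33"
round_display <- function(x, dp = 2) {
  if (!is_count(dp)) ssm_abort("dp must be a non-negative integer")
  vapply(x, function(xi) {
    if (!is.finite(xi)) ssm_abort("round_display requires finite input")
    neg <- xi < 0
    # 12 decimals is far beyond score precision; printing first recovers the
    # intended decimal value from the nearest double (0.325 -> "0.325000...")
    s <- sprintf("%.12f", abs(xi))
    parts <- strsplit(s, ".", fixed = TRUE)[[1]]
    int_part <- parts[1]
    frac <- parts[2]
    keep <- if (dp > 0) substr(frac, 1, dp) else ""
    next_digit <- as.integer(substr(frac, dp + 1, dp + 1))
    scaled <- as.numeric(paste0(int_part, keep))
    if (next_digit >= 5) scaled <- scaled + 1
    int_out <- scaled %/% 10^dp
    frac_out <- scaled %% 10^dp
    out <- if (dp > 0) {
      sprintf("%d.%0*d", int_out, dp, frac_out)
    } else {
      sprintf("%d", int_out)
    }
    if (neg && scaled > 0) paste0("-", out) else out
  }, character(1))
}

#' Rank communities and flag eligibility
#'
#' Sorts by final score descending; ties are broken by the population
#' component descending, then by community identifier ascending (a
#' deterministic convention — the model itself does not order exact ties).
#' Rank is the 1-based position. A community is eligible when its score
#' strictly exceeds the cut-point; boundary equality is ineligible.
#'
#' @param results Data frame with at least `community_id`, `ssm_score` and
#'   `population_score`.
#' @param cutpoint Eligibility cut-point in `[0, 1]` (default 0.6).
#' @return The data frame sorted, with `eligible` and `rank` columns.
#' @export
rank_and_flag <- function(results, cutpoint = 0.6) {
  require_cols(results, c("community_id", "ssm_score", "population_score"),
               "results table")
  ord <- order(-results$ssm_score, -results$population_score,
               results$community_id)
  out <- results[ord, , drop = FALSE]
  out$eligible <- out$ssm_score > cutpoint
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the full site suitability model
#'
#' The end-to-end pipeline: select candidate communities (population and
#' isolation filters), then per candidate compute the catchment population,
#' isolation minutes, vulnerability index and readiness score, combine the
#' four components under the configured weights, and rank with the
#' eligibility cut-point. Deterministic for fixed inputs.
#'
#' The vulnerability sub-scores are scaled over a reference set: the supplied
#' province-wide `reference` table when given, otherwise the candidate set
#' itself.
#'
#' @param dataset An `ssm_dataset`.
#' @param config An `ssm_config`.
#' @param reference Optional data frame with columns `pct_over75, pct_female,
#'   pct_alone, vx_1..vx_7` defining the scaling reference for vulnerability;
#'   defaults to the candidate set.
#' @param vandix_directions Logical vector of length 7 passed to
#'   [vandix_score()].
#' @return Data frame of class `ssm_result`: one row per candidate with
#'   `community_id, name, catchment_population, nearest_centre_minutes,
#'   population_score, isolation_score, vulnerability_score, readiness_score,
#'   ssm_score, eligible, rank`, sorted by rank.
#' @export
run_ssm <- function(dataset, config = model_config(), reference = NULL,
                    vandix_directions = DEFAULT_VANDIX_DIRECTIONS) {
  stopifnot(inherits(dataset, "ssm_dataset"), inherits(config, "ssm_config"))
  cand <- select_candidates(dataset, config)
  if (nrow(cand) == 0) {
    ssm_warn("no community passes the selection filters")
    empty <- data.frame(
      community_id = character(), name = character(),
      catchment_population = numeric(), nearest_centre_minutes = numeric(),
      population_score = numeric(), isolation_score = numeric(),
      vulnerability_score = numeric(), readiness_score = numeric(),
      ssm_score = numeric(), eligible = logical(), rank = integer())
    class(empty) <- c("ssm_result", "data.frame")
    return(empty)
  }

  blocks <- dataset$blocks
  if (nrow(blocks) > 0) {
    blocks$block_node <- vapply(seq_len(nrow(blocks)), function(i) {
      snap_to_node(dataset$network, c(blocks$x[i], blocks$y[i]))
    }, character(1))
  }

  pops <- vapply(cand$centre_node, function(nd) {
    catchment_population(dataset$network, nd, blocks,
                         config$catchment_minutes)
  }, numeric(1))
  names(pops) <- cand$community_id
  pop_score <- population_component(pops)

  iso_score <- isolation_component(cand$nearest_centre_minutes,
                                   config$isolation_cap_minutes)

  ref <- if (is.null(reference)) cand else reference
  require_cols(ref, c("pct_over75", "pct_female", "pct_alone", VANDIX_COLS),
               "vulnerability reference table")
  mode <- config$pcix_scaling_mode
  age <- scale_against_ref(cand$pct_over75, ref$pct_over75, mode)
  sex <- scale_against_ref(cand$pct_female, ref$pct_female, mode)
  alone <- scale_against_ref(cand$pct_alone, ref$pct_alone, mode)
  vandix <- vapply(seq_len(nrow(cand)), function(i) {
    vandix_score(as.numeric(cand[i, VANDIX_COLS]),
                 ref[, VANDIX_COLS, drop = FALSE],
                 directions = vandix_directions, mode = mode)
  }, numeric(1))
  vuln_score <- pcix_vulnerability(
    list(age = age, sex = sex, alone = alone, vandix = vandix))

  fp_adequate <- ifelse(
    !is.na(cand$fp_adequate_override), cand$fp_adequate_override,
    physician_supply_adequate(cand$population, cand$fp_count,
                              config$physician_ratio_max))
  ready_score <- readiness_component(list(
    aware = cand$aware, education = cand$education,
    telemedicine = cand$telemedicine, fp_adequate = fp_adequate,
    momentum = cand$momentum))

  comp <- cbind(pop_score, iso_score, vuln_score, ready_score)
  ssm <- combine_components(comp, config$weights)

  res <- data.frame(
    community_id = cand$community_id, name = cand$name,
    catchment_population = unname(pops),
    nearest_centre_minutes = cand$nearest_centre_minutes,
    population_score = unname(pop_score), isolation_score = iso_score,
    vulnerability_score = vuln_score, readiness_score = ready_score,
    ssm_score = ssm, stringsAsFactors = FALSE)
  res <- rank_and_flag(res, config$cutpoint)
  class(res) <- c("ssm_result", "data.frame")
  res
}

# scale candidate values against a (possibly external) reference set: the
# reference defines max / range; candidates outside it are clipped to [0, 1]
scale_against_ref <- function(x, ref_values, mode) {
  if (mode == "none") return(pmin(pmax(x, 0), 1))
  if (mode == "max") {
    if (any(ref_values < 0) || any(x < 0)) {
      ssm_abort("mode 'max' requires non-negative values")
    }
    m <- max(ref_values)
    out <- if (m == 0) x * 0 else x / m
    return(pmin(out, 1))
  }
  lo <- min(ref_values)
  hi <- max(ref_values)
  if (hi == lo) return(x * 0)
  pmin(pmax((x - lo) / (hi - lo), 0), 1)
}
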