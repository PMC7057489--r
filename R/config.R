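#' Model configuration
#'
#' Every threshold and weight of the site suitability model, with the defaults
#' used in the published provincial applications of the model: a 60-minute
#' drive-time catchment, a 240-minute isolation cap (at or beyond which a
#' community is maximally isolated), a 0.6 eligibility cut-point, a strict
#' `> 5000` resident filter, palliative-centre definitions of `> 500` hospital
#' beds or `> 3` hospice beds, an adequate-physician-supply benchmark of at
#' most 1307 persons per family physician (inclusive), and equal component
#' weights.
#'
#' @param catchment_minutes Drive-time radius, in minutes, of the population
#'   catchment and of the "too close to existing care" exclusion filter.
#' @param isolation_cap_minutes Travel time, in minutes, at or beyond which the
#'   isolation component saturates at 1.
#' @param cutpoint Lower bound (exclusive) on the final score for eligibility,
#'   in `[0, 1]`.
#' @param min_population Minimum community population (strict `>`) for
#'   candidacy.
#' @param hospital_min_beds A hospital counts as a palliative care centre when
#'   its bed count strictly exceeds this.
#' @param hospice_min_beds A hospice counts as a palliative care centre when
#'   its (hospice) bed count strictly exceeds this.
#' @param physician_ratio_max Persons per family physician at or under which
#'   (inclusive `<=`) supply is adequate.
#' @param weights Four non-negative component weights (population, isolation,
#'   vulnerability, readiness); need not sum to 1.
#' @param pcix_scaling_mode How vulnerability sub-scores are scaled over the
#'   reference set: `"max"` (relative to the maximum), `"minmax"`, or `"none"`.
#' @param display_decimals Decimal places used when serializing scores.
#'
#' @return An object of class `ssm_config` (a validated named list).
#' @export
#' @examples
#' model_config()
#' model_config(catchment_minutes = 90, weights = c(2, 1, 1, 1))
model_config <- function(catchment_minutes = 60,
                         isolation_cap_minutes = 240,
                         cutpoint = 0.6,
                         min_population = 5000,
                         hospital_min_beds = 500,
                         hospice_min_beds = 3,
                         physician_ratio_max = 1307,
                         weights = c(1, 1, 1, 1),
                         pcix_scaling_mode = c("max", "minmax", "none"),
                         display_decimals = 2) {
  pcix_scaling_mode <- match.arg(pcix_scaling_mode)
  for (nm in c("catchment_minutes", "isolation_cap_minutes", "min_population",
               "hospital_min_beds", "hospice_min_beds", "physician_ratio_max")) {
    stopifnot_scalar_number(get(nm), nm, positive = TRUE)
  }
  stopifnot_scalar_number(cutpoint, "cutpoint")
  if (cutpoint < 0 || cutpoint > 1) {
    ssm_abort("cutpoint must lie in [0, 1], got ", cutpoint)
  }
  if (!is.numeric(weights) || length(weights) != 4L || anyNA(weights)) {
    ssm_abort("weights must be four numbers (population, isolation, ",
              "vulnerability, readiness)")
  }
  if (any(weights < 0)) ssm_abort("weights must be non-negative")
  if (sum(weights) <= 0) ssm_abort("weights must have a positive sum")
  if (!is_count(display_decimals)) {
    ssm_abort("display_decimals must be a non-negative integer")
  }
  structure(
    list(
      catchment_minutes = as.numeric(catchment_minutes),
      isolation_cap_minutes = as.numeric(isolation_cap_minutes),
      cutpoint = as.numeric(cutpoint),
      min_population = as.numeric(min_population),
      hospital_min_beds = as.numeric(hospital_min_beds),
      hospice_min_beds = as.numeric(hospice_min_beds),
      physician_ratio_max = as.numeric(physician_ratio_max),
      weights = as.numeric(weights),
      pcix_scaling_mode = pcix_scaling_mode,
      display_decimals = as.integer(display_decimals)
    ),
    class = "ssm_config"
  )
}

#' @export
print.ssm_config <- function(x, ...) {
  cat("<ssm_config>\n")
  cat(sprintf("  catchment: %g min | isolation cap: %g min | cutpoint: %g\n",
              x$catchment_minutes, x$isolation_cap_minutes, x$cutpoint))
  cat(sprintf("  min population: > %g | hospital beds: > %g | hospice beds: > %g\n",
              x$min_population, x$hospital_min_beds, x$hospice_min_beds))
  cat(sprintf("  physician ratio: <= %g persons/FP\n", x$physician_ratio_max))
  cat(sprintf("  weights (pop, iso, vuln, ready): %s | scaling: %s\n",
              paste(x$weights, collapse = ", "), x$pcix_scaling_mode))
  invisible(x)
}

#' Read a model configuration file
#'
#' The file is a flat key-value document (YAML or JSON). Any key absent from
#' the file falls back to the [model_config()] default; an unknown key is a
#' hard error naming the key. The only list-valued key is `weights`.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return An `ssm_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) ssm_abort("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) ssm_abort("config file must be a key-value document")
  known <- names(formals(model_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown) > 0) {
    ssm_abort("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(doc$weights)) doc$weights <- unlist(doc$weights)
  do.call(model_config, doc)
}

#' Write a model configuration file
#'
#' Serializes an `ssm_config` to YAML such that `read_config()` round-trips it.
#'
#' @param config An `ssm_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ssm_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
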