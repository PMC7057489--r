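#' Deterministic six-community line fixture
#'
#' A fixed, fully hand-traceable region: six communities strung along a
#' single road at 60 km/h, with a 600-bed hospital at the first community's
#' node (and a non-qualifying 2-bed hospice further along). Every
#' intermediate quantity — travel times, selection, catchment populations,
#' all four component scores and the final ranking — was worked out by hand
#' and is frozen in [line_region_expectations()].
#'
#' Layout (edge traversal minutes): C1 -40- C2 -50- C3 -70- C4 -60- C5 -90- C6.
#' Cumulative minutes from the hospital at C1: 0, 40, 90, 160, 220, 310.
#' Under the default 60-minute filter C1 and C2 are too close to the
#' hospital, C3 fails the `> 5000` population filter, so the candidates are
#' C4, C5 and C6.
#'
#' @return An `ssm_dataset`.
#' @export
generate_line_region <- function() {
  # positions in metres; 60 km/h everywhere so length_km == traversal minutes
  xs <- c(0, 40000, 90000, 160000, 220000, 310000)
  segments <- data.frame(
    x1 = xs[1:5], y1 = 0, x2 = xs[2:6], y2 = 0,
    length_km = c(40, 50, 70, 60, 90),
    speed_kmh = 60)
  network <- build_graph(segments)

  centres <- data.frame(
    community_id = paste0("C", 1:6),
    name = paste("Lineville", 1:6),
    x = xs, y = 0,
    population = c(20000, 8000, 4800, 9000, 12000, 6000),
    pct_over75 = c(0.09, 0.11, 0.12, 0.10, 0.20, 0.15),
    pct_female = c(0.50, 0.49, 0.51, 0.50, 0.52, 0.48),
    pct_alone = c(0.09, 0.10, 0.11, 0.10, 0.12, 0.08),
    fp_count = c(15, 5, 3, 7, 8, 5),
    # candidates C4/C5/C6 carry 1 : 2 : 2 (deprivation-direction) and
    # 1 : 0.5 : 0.75 (protective-direction) ratios for easy hand-scaling
    vx_1 = c(0.30, 0.30, 0.30, 0.20, 0.40, 0.40),
    vx_2 = c(0.10, 0.10, 0.10, 0.20, 0.40, 0.40),
    vx_3 = c(0.15, 0.15, 0.15, 0.20, 0.40, 0.40),
    vx_4 = c(50000, 50000, 50000, 40000, 20000, 30000),
    vx_5 = c(0.70, 0.70, 0.70, 0.80, 0.40, 0.60),
    vx_6 = c(0.60, 0.60, 0.60, 0.60, 0.30, 0.45),
    vx_7 = c(0.25, 0.25, 0.25, 0.20, 0.40, 0.40),
    aware = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    education = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    telemedicine = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
    fp_adequate_override = NA,
    momentum = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)

  blocks <- data.frame(
    block_id = paste0("B", 1:6),
    x = xs, y = 0,
    population = c(15000, 6000, 4000, 9000, 11000, 5000),
    stringsAsFactors = FALSE)

  facilities <- data.frame(
    facility_id = c("F01", "F02"),
    name = c("Regional Hospital", "Small Hospice"),
    x = c(0, 160000), y = 0,
    kind = c("hospital", "hospice"),
    beds = c(600, 2),
    stringsAsFactors = FALSE)

  structure(list(centres = centres, blocks = blocks, network = network,
                 facilities = facilities),
            class = "ssm_dataset")
}

#' Hand-computed expectations for the line fixture
#'
#' The companion expectation table for [generate_line_region()] under the
#' default configuration (60-minute catchment, 240-minute cap, equal weights,
#' cut-point 0.6, max-scaling over the candidate set). Every number below was
#' derived by hand from the fixture's construction, independently of the
#' package's computation path:
#'
#' * Travel minutes from the hospital: C4 = 160, C5 = 220, C6 = 310.
#' * 60-minute catchments: C4 reaches C4+C5 blocks (20000 persons), C5
#'   reaches C5+C4 (20000), C6 reaches only itself (5000).
#' * Vulnerability sub-scores scale over the candidate set `{C4, C5, C6}`;
#'   e.g. C4 age = 0.10/0.20, C4 deprivation composite =
#'   (4 x 0.5 + 3 x 0) / 7.
#' * Readiness: C4 physicians 9000/7 ~ 1286 <= 1307 (adequate), C5 12000/8 =
#'   1500 (not), C6 6000/5 = 1200 (adequate).
#'
#' @return Data frame with one row per candidate, ordered by expected rank.
#' @export
line_region_expectations <- function() {
  vuln_c4 <- (0.10 / 0.20 + 0.50 / 0.52 + 0.10 / 0.12 + 2 / 7) / 4
  vuln_c5 <- (1 + 1 + 1 + 5.5 / 7) / 4
  vuln_c6 <- (0.15 / 0.20 + 0.48 / 0.52 + 0.08 / 0.12 + 4.75 / 7) / 4
  df <- data.frame(
    community_id = c("C5", "C4", "C6"),
    nearest_centre_minutes = c(220, 160, 310),
    catchment_population = c(20000, 20000, 5000),
    population_score = c(1, 1, 0.25),
    isolation_score = c(220 / 240, 160 / 240, 1),
    vulnerability_score = c(vuln_c5, vuln_c4, vuln_c6),
    readiness_score = c(0.8, 0.6, 0.4),
    stringsAsFactors = FALSE)
  df$ssm_score <- (df$population_score + df$isolation_score +
                     df$vulnerability_score + df$readiness_score) / 4
  df$eligible <- df$ssm_score > 0.6
  df$rank <- 1:3
  df
}
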