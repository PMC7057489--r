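#' Worked-example score tables for 12 rural Ontario communities
#'
#' Component and sub-score tables from a provincial-scale application of the
#' model to 12 candidate communities in Ontario, shipped as plain CSV under
#' `inst/extdata/`. They serve as worked examples for the aggregation layer:
#' feeding the printed components through [combine_components()],
#' [pcix_vulnerability()] and [readiness_component()] reproduces the printed
#' final scores (up to three vulnerability rows whose printed totals differ
#' from their own sub-scores at two decimals; see the methods vignette).
#'
#' @param table One of:
#'   * `"components"` — the four component scores and final score per
#'     community (`population, isolation, vulnerability, readiness, ssm`);
#'   * `"pcix"` — the vulnerability sub-scores (`age, sex, alone, vandix`)
#'     and the printed vulnerability score;
#'   * `"readiness"` — the five yes/no readiness flags and the printed
#'     readiness score.
#' @return A data frame with a `community` column plus the table's columns.
#' @export
#' @examples
#' tab <- ontario_example("components")
#' combine_components(tab[, c("population", "isolation",
#'                            "vulnerability", "readiness")])
ontario_example <- function(table = c("components", "pcix", "readiness")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("ontario_", table, ".csv"),
                      package = "hubsite", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (table == "readiness") {
    for (col in c("aware", "education", "telemedicine", "fp_adequate",
                  "momentum")) {
      df[[col]] <- parse_yes_no(df[[col]], col)
    }
  }
  df
}
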