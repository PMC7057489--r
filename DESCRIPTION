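Package: hubsite
Title: Site Suitability Modelling for Rural Secondary Palliative Care Hubs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a four-component Site Suitability Model (SSM) for
    ranking rural communities as candidate secondary palliative care hubs.
    Builds a drive-time graph from speed-attributed road segments, computes
    travel-time service areas and nearest-facility queries, filters candidate
    communities by population and spatial isolation from existing palliative
    care centres, scores each candidate on catchment population, isolation,
    vulnerability (a palliative care index built from demographic proportions
    and a census-based deprivation composite) and community readiness, and
    combines the components into a weighted 0-1 suitability score with an
    eligibility cut-point and ranking. Includes a seeded synthetic-region
    generator for end-to-end testing without licensed census or road data,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
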