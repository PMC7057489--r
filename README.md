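# hubsite

Site suitability modelling for rural secondary palliative care hubs.

Rural communities rarely sustain stand-alone specialist palliative care. A
practical alternative is to enhance an existing community's health services
into a *secondary palliative care hub* (SPCH) backed by remote specialists.
`hubsite` answers the siting question: given a region's communities, road
network, health facilities and census-style attributes, it filters, scores
and ranks communities by their suitability as SPCH candidates, for health
planners and health-geography researchers.

## The model

Candidates are population centres with more than 5000 residents lying more
than a 60-minute drive from the nearest palliative care centre (a hospital
with > 500 beds or a hospice with > 3 hospice beds), with drive times
computed over an undirected travel-time road graph. Each candidate *i* gets
four component scores in [0, 1]:

- **Population** P<sub>i</sub> = pop<sub>i</sub> / max<sub>j</sub> pop<sub>j</sub>,
  where pop<sub>i</sub> is the total block population within a 60-minute
  drive;
- **Isolation** I<sub>i</sub> = min(t<sub>i</sub> / 240, 1), where
  t<sub>i</sub> is the drive time in minutes to the nearest palliative care
  centre (unreachable ⇒ 1);
- **Vulnerability** V<sub>i</sub> = (age + sex + alone + vandix) / 4, the
  mean of four scaled sub-scores: % over 75, % female, % living alone, and a
  seven-indicator census deprivation composite;
- **Readiness** R<sub>i</sub> = 0.2 × (number of "yes" flags) over five
  binary indicators: hospice society, nearby college/university,
  telemedicine use, ≤ 1307 persons per family physician, local hospice
  momentum.

The final score is the weighted mean S<sub>i</sub> = Σ w<sub>k</sub>
s<sub>ik</sub> / Σ w<sub>k</sub> (equal weights by default, so S = (P + I +
V + R) / 4). Communities with S > 0.6 are flagged eligible, and the table is
ranked. Every threshold and weight is configurable; see the methods
vignette (`vignettes/site-suitability-model.Rmd`) for the model's
assumptions and design choices.

## Worked example

The package ships a deterministic six-community fixture whose every
intermediate quantity is hand-traced (`line_region_expectations()`):

```r
library(hubsite)
ds  <- generate_line_region()
res <- run_ssm(ds)   # default config: 60-min catchment, 240-min cap, 0.6 cut-point
res[, c("community_id", "catchment_population", "nearest_centre_minutes",
        "ssm_score", "eligible", "rank")]
#>   community_id catchment_population nearest_centre_minutes ssm_score eligible rank
#> 1           C5                20000                    220    0.9158     TRUE    1
#> 2           C4                20000                    160    0.7280     TRUE    2
#> 3           C6                 5000                    310    0.6011     TRUE    3
```

Three of the six communities survive selection (two are within an hour of
the regional hospital, one is under 5000 residents). C5 ranks first: it
shares the largest 60-minute catchment (20 000 persons, population score
1.00), is 220 minutes from existing palliative care (isolation 220/240 =
0.92), and holds four of five readiness flags (0.8).

The aggregation layer also reproduces a published 12-community worked
example shipped under `inst/extdata/`:

```r
tab <- ontario_example("components")
round_display(combine_components(tab[, c("population", "isolation",
                                         "vulnerability", "readiness")]), 2)
#> [1] "0.71" "0.52" "0.76" "0.34" "0.48" "0.33" ...
```

matching the printed final scores for all 12 communities, with exactly 3
eligible at the 0.6 cut-point (Fort Frances 0.76, Dryden 0.71, Kenora 0.63).

## Command line

```sh
Rscript inst/cli/hubsite.R synth --seed 42 --out-dir region/
Rscript inst/cli/hubsite.R run --centres region/centres.csv \
    --blocks region/blocks.csv --network region/network.geojson \
    --facilities region/facilities.csv --out results/
```

`run` writes `ranking.csv` and a reproducibility `manifest.json` (resolved
configuration, input digests, package version); logs — stage timings and the
candidate funnel — go to standard error. Exit codes: 0 success, 2
validation/usage error, 1 unexpected error.

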