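test_that("combine_components is the weighted mean of four scores", {
  # worked examples from the 12-community table
  expect_equal(combine_components(c(0.81, 0.94, 0.29, 0.80)), 0.71)
  d <- combine_components(c(1.00, 0.93, 0.30, 0.80))
  expect_equal(d, 0.7575)
  expect_equal(round_display(d, 2), "0.76")
  expect_equal(combine_components(c(1, 1, 1, 1), c(0.3, 2, 1, 0.01)), 1)
  # weighting generalization normalizes by the weight sum
  expect_equal(combine_components(c(1, 0, 0, 0), c(3, 1, 1, 1)), 0.5)
  expect_error(combine_components(c(1, 1, 1, 1), c(0, 0, 0, 0)),
               class = "ssm_validation_error")
  expect_error(combine_components(c(1, 1, 1)), "four",
               class = "ssm_validation_error")
  expect_error(combine_components(c(1, 1, 1, 1.2)),
               class = "ssm_validation_error")
  # with equal weights the score is exactly the arithmetic mean
  set.seed(7)
  m <- matrix(stats::runif(400), ncol = 4)
  expect_equal(combine_components(m), rowMeans(m), tolerance = 1e-12)
})

test_that("round_display rounds half away from zero on decimal digits", {
  expect_equal(round_display(0.325, 2), "0.33")
  expect_equal(round_display(0.71, 2), "0.71")
  expect_equal(round_display(-0.005, 2), "-0.01")
  expect_equal(round_display(0.335, 2), "0.34")
  expect_equal(round_display(0.4075, 2), "0.41")
  expect_equal(round_display(0.995, 2), "1.00")   # carry into the integer
  expect_equal(round_display(2.5, 0), "3")
  expect_equal(round_display(-2.5, 0), "-3")
  expect_equal(round_display(0.3175, 2), "0.32")
  expect_equal(round_display(c(0.125, 0.875), 2), c("0.13", "0.88"))
  expect_equal(round_display(-0.0004, 2), "0.00")  # no negative zero
  expect_error(round_display(Inf, 2))
})

test_that("rank_and_flag sorts, breaks ties deterministically, flags strictly", {
  res <- data.frame(
    community_id = c("B", "A", "C", "D"),
    population_score = c(0.5, 0.9, 0.5, 0.2),
    ssm_score = c(0.7, 0.7, 0.7, 0.6))
  out <- rank_and_flag(res, 0.6)
  # ties on the score: population component descending, then id ascending
  expect_equal(out$community_id, c("A", "B", "C", "D"))
  expect_equal(out$rank, 1:4)
  # boundary equality with the cut-point is ineligible
  expect_equal(out$eligible, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(nrow(rank_and_flag(res[0, ], 0.6)), 0)
})

test_that("ranking is invariant to input order and monotone in components", {
  tab <- ontario_example("components")
  res <- data.frame(community_id = tab$community,
                    population_score = tab$population,
                    ssm_score = combine_components(tab[, ontario_component_cols]))
  base <- rank_and_flag(res, 0.6)
  set.seed(13)
  for (i in 1:5) {
    shuffled <- rank_and_flag(res[sample(nrow(res)), ], 0.6)
    expect_equal(shuffled$community_id, base$community_id)
    expect_equal(shuffled$rank, base$rank)
  }
  # raising one community's component never worsens its rank
  bumped <- tab
  bumped$isolation[bumped$community == "Goderich"] <- 0.9
  res2 <- data.frame(community_id = bumped$community,
                     population_score = bumped$population,
                     ssm_score = combine_components(bumped[, ontario_component_cols]))
  after <- rank_and_flag(res2, 0.6)
  expect_lte(after$rank[after$community_id == "Goderich"],
             base$rank[base$community_id == "Goderich"])
  expect_gte(after$ssm_score[after$community_id == "Goderich"],
             base$ssm_score[base$community_id == "Goderich"])
})

test_that("run_ssm reproduces the hand-traced line-fixture expectation table", {
  ds <- generate_line_region()
  res <- run_ssm(ds)
  exp <- line_region_expectations()
  expect_equal(res$community_id, exp$community_id)
  expect_equal(res$rank, exp$rank)
  expect_equal(res$eligible, exp$eligible)
  expect_equal(res$nearest_centre_minutes, exp$nearest_centre_minutes)
  expect_equal(res$catchment_population, exp$catchment_population)
  expect_equal(res$population_score, exp$population_score, tolerance = 1e-12)
  expect_equal(res$isolation_score, exp$isolation_score, tolerance = 1e-12)
  expect_equal(res$vulnerability_score, exp$vulnerability_score,
               tolerance = 1e-12)
  expect_equal(res$readiness_score, exp$readiness_score, tolerance = 1e-12)
  expect_equal(res$ssm_score, exp$ssm_score, tolerance = 1e-12)
})

test_that("run_ssm degenerate weights and dominance behave as expected", {
  ds <- generate_line_region()
  # weights (1,0,0,0): ranking equals the population-component ordering
  cfg <- model_config(weights = c(1, 0, 0, 0))
  res <- run_ssm(ds, cfg)
  expect_equal(res$ssm_score, res$population_score)
  expect_true(all(diff(res$population_score) <= 0))

  # a candidate dominating every component ranks 1 with score 1
  ds2 <- ds
  ds2$centres$pct_over75[5] <- 0.5   # C5 already dominates; make it extreme
  ds2$centres$pct_alone[5] <- 0.5
  ds2$centres$pct_female[5] <- 0.9
  ds2$centres$vx_1[5] <- 0.9; ds2$centres$vx_2[5] <- 0.9
  ds2$centres$vx_3[5] <- 0.9; ds2$centres$vx_7[5] <- 0.9
  ds2$centres$vx_4[5] <- 0; ds2$centres$vx_5[5] <- 0; ds2$centres$vx_6[5] <- 0
  ds2$centres$aware[5] <- TRUE; ds2$centres$education[5] <- TRUE
  ds2$centres$telemedicine[5] <- TRUE; ds2$centres$momentum[5] <- TRUE
  ds2$centres$fp_adequate_override[5] <- TRUE
  ds2$centres$population[5] <- 12000
  ds2$blocks$population[5] <- 25000   # largest catchment
  # push C5 beyond the isolation cap by lengthening the C3-C4 and C4-C5 roads
  ds2$network <- build_graph(within(ds2$network$segments, {
    length_km[3] <- 150; length_km[4] <- 150
  }))
  res2 <- run_ssm(ds2)
  expect_equal(res2$community_id[1], "C5")
  expect_equal(res2$ssm_score[1], 1.0, tolerance = 1e-12)

  # empty candidate set: empty result with a warning
  ds3 <- ds
  ds3$centres$population <- 100
  expect_warning(res3 <- run_ssm(ds3), "no community")
  expect_equal(nrow(res3), 0)
})

test_that("run_ssm accepts an external vulnerability reference table", {
  ds <- generate_line_region()
  cand <- ds$centres[4:6, ]
  # reference equal to the candidate set reproduces the default
  res_default <- run_ssm(ds)
  res_ref <- run_ssm(ds, reference = cand)
  expect_equal(res_ref$vulnerability_score, res_default$vulnerability_score)
  # a wider reference (with a more extreme community) lowers relative scores
  wide <- rbind(cand, transform(make_centre("EXT", 0, 0, 9000),
                                pct_over75 = 0.4, pct_alone = 0.3,
                                pct_female = 0.6))
  res_wide <- run_ssm(ds, reference = wide)
  expect_true(all(res_wide$vulnerability_score <=
                    res_default$vulnerability_score + 1e-12))
})
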