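test_that("catchment_population sums blocks inside the drive-time area", {
  ds <- generate_line_region()
  net <- ds$network
  nodes <- vapply(seq_len(nrow(ds$centres)), function(i) {
    snap_to_node(net, c(ds$centres$x[i], ds$centres$y[i]))
  }, character(1))
  # hand-traced 60-minute reaches: C4 covers C4+C5 blocks, C6 only itself
  expect_equal(catchment_population(net, nodes[4], ds$blocks, 60), 20000)
  expect_equal(catchment_population(net, nodes[5], ds$blocks, 60), 20000)
  expect_equal(catchment_population(net, nodes[6], ds$blocks, 60), 5000)
  # no blocks -> 0; infinite budget -> everything in the component
  expect_equal(catchment_population(net, nodes[1], empty_blocks(), 60), 0)
  expect_equal(catchment_population(net, nodes[1], ds$blocks, Inf),
               sum(ds$blocks$population))
})

test_that("population_component scores proportionally to the largest catchment", {
  expect_equal(population_component(c(A = 60000, B = 30000)),
               c(A = 1.0, B = 0.5))
  expect_equal(population_component(c(only = 12345)), c(only = 1.0))
  expect_equal(population_component(c(A = 0, B = 0)), c(A = 0, B = 0))
  expect_error(population_component(numeric(0)), "at least one")
  # scale invariance: multiplying every catchment by k changes nothing
  set.seed(5)
  pops <- stats::runif(10, 100, 90000)
  for (k in c(0.001, 3, 1e6)) {
    expect_equal(population_component(pops * k), population_component(pops))
  }
})

test_that("isolation_component is proportional, capped, and maximal when unreachable", {
  expect_equal(isolation_component(240, 240), 1.0)
  expect_equal(isolation_component(120, 240), 0.5)
  expect_equal(isolation_component(Inf, 240), 1.0)
  expect_equal(isolation_component(0, 240), 0)
  expect_error(isolation_component(-1, 240), "non-negative",
               class = "ssm_validation_error")
  # non-decreasing in minutes; constant at 1 beyond the cap
  m <- c(0, 30, 100, 239, 240, 500, Inf)
  s <- isolation_component(m, 240)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s[m >= 240] == 1))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("scale_subscores implements max, minmax and none modes", {
  expect_equal(scale_subscores(c(A = 0.18, B = 0.09), "max"),
               c(A = 1.0, B = 0.5))
  expect_equal(scale_subscores(c(A = 5, B = 3, C = 1), "minmax"),
               c(A = 1, B = 0.5, C = 0))
  v <- c(A = 0.3, B = 0.9)
  expect_equal(scale_subscores(v, "none"), v)
  expect_equal(scale_subscores(c(1.7, -0.2), "none"), c(1, 0))  # clipped
  expect_equal(scale_subscores(c(0, 0), "max"), c(0, 0))
  expect_equal(scale_subscores(c(2, 2, 2), "minmax"), c(0, 0, 0))
  expect_error(scale_subscores(c(-1, 2), "max"), "non-negative",
               class = "ssm_validation_error")
  expect_warning(scale_subscores(c(A = 3), "minmax"), "single")
})

test_that("vandix_score scales, complements protective indicators, averages", {
  ref <- rbind(
    A = c(0.4, 0.2, 0.1, 50000, 0.8, 0.6, 0.3),
    B = c(0.2, 0.1, 0.2, 25000, 0.4, 0.3, 0.15),
    C = c(0.1, 0.05, 0.05, 40000, 0.6, 0.45, 0.075))
  # hand-computed under max-scaling with default directions:
  # A scaled (1,1,.5,1,1,1,1) -> adjusted (1,1,.5,0,0,0,1) -> 3.5/7
  # B scaled (.5,.5,1,.5,.5,.5,.5) -> adjusted (.5,.5,1,.5,.5,.5,.5) -> 4/7
  # C scaled (.25,.25,.25,.8,.75,.75,.25) -> adj (.25,.25,.25,.2,.25,.25,.25)
  expect_equal(vandix_score(ref["A", ], ref), 3.5 / 7)
  expect_equal(vandix_score(ref["B", ], ref), 4.0 / 7)
  expect_equal(vandix_score(ref["C", ], ref), 1.7 / 7)

  # all indicators at maximum deprivation -> 1 (deprivation-direction at the
  # reference max, protective at zero)
  extreme <- c(0.4, 0.2, 0.2, 0, 0, 0, 0.3)
  expect_equal(vandix_score(extreme, rbind(ref, extreme)), 1.0)
  # all at minimum deprivation under minmax -> 0
  mild <- c(0.1, 0.05, 0.05, 50000, 0.8, 0.6, 0.075)
  expect_equal(vandix_score(mild, rbind(ref, mild), mode = "minmax"), 0)

  # direction vector is overridable
  expect_equal(vandix_score(ref["A", ], ref, directions = rep(FALSE, 7)),
               6.5 / 7)
  expect_error(vandix_score(ref["A", 1:6], ref), "7 indicators")
  expect_error(vandix_score(ref["A", ], ref[0, ]), "non-empty")
})

test_that("pcix_vulnerability averages the four sub-scores", {
  expect_equal(
    round_display(pcix_vulnerability(
      list(age = 0.11, sex = 0.49, alone = 0.09, vandix = 0.47))),
    "0.29")  # worked example: Goderich
  expect_equal(
    round_display(pcix_vulnerability(
      list(age = 0.08, sex = 0.43, alone = 0.08, vandix = 0.49))),
    "0.27")  # worked example: Perth
  expect_equal(pcix_vulnerability(
    list(age = 0, sex = 0, alone = 0, vandix = 0)), 0)
  expect_equal(pcix_vulnerability(
    list(age = 1, sex = 1, alone = 1, vandix = 1)), 1)
  expect_error(pcix_vulnerability(list(age = 1.2, sex = 0, alone = 0,
                                       vandix = 0)),
               class = "ssm_validation_error")
})

test_that("physician supply adequacy uses an inclusive 1307:1 benchmark", {
  expect_true(physician_supply_adequate(13070, 10))   # exactly at the ratio
  expect_false(physician_supply_adequate(13071, 10))
  expect_false(physician_supply_adequate(5000, 0))    # no physicians
  expect_true(physician_supply_adequate(0, 0))        # vacuously adequate
  expect_true(physician_supply_adequate(1307, 1))
  expect_error(physician_supply_adequate(-1, 2), class = "ssm_validation_error")
})

test_that("readiness_component counts 0.2 per yes, exactly on the 0.2 grid", {
  # worked examples: flags (no,no,yes,yes,no) -> 0.4; all yes -> 1; none -> 0
  expect_identical(readiness_component(c(FALSE, FALSE, TRUE, TRUE, FALSE)),
                   0.4)
  expect_identical(readiness_component(rep(TRUE, 5)), 1)
  expect_identical(readiness_component(rep(FALSE, 5)), 0)
  expect_identical(readiness_component(c(TRUE, TRUE, TRUE, FALSE, FALSE)),
                   0.6)  # exact: sum/5, not 3 * 0.2 in binary floats
  # vectorized over a flag table
  flags <- data.frame(aware = c(TRUE, FALSE), education = c(TRUE, FALSE),
                      telemedicine = c(TRUE, TRUE),
                      fp_adequate = c(TRUE, TRUE), momentum = c(TRUE, FALSE))
  expect_identical(readiness_component(flags), c(1, 0.4))
  expect_error(readiness_component(c(TRUE, NA, TRUE, TRUE, TRUE)),
               class = "ssm_validation_error")
})

test_that("component scores stay in [0,1] for arbitrary valid inputs", {
  set.seed(99)
  for (i in 1:20) {
    pops <- stats::runif(6, 0, 1e5)
    expect_true(all(population_component(pops) >= 0 &
                      population_component(pops) <= 1))
    mins <- c(stats::runif(5, 0, 600), Inf)
    s <- isolation_component(mins, 240)
    expect_true(all(s >= 0 & s <= 1))
    ref <- matrix(stats::runif(21, 0, 10), 3, 7)
    v <- vandix_score(ref[1, ], ref)
    expect_true(v >= 0 && v <= 1)
  }
})
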