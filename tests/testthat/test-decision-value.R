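scen <- increase_scenarios()

test_that("scenario table encodes concentration and reduction", {
  expect_equal(scen$concentration, c(14.4, 13.2, 12.6))
  expect_equal(scen$reduction, c(2.4, 1.2, 0.6))
  expect_error(increase_scenarios(standard = 0), "positive")
})

test_that("mass conversion is micrograms to metric tons times volume", {
  expect_equal(mass_to_reduce(2.4, 1), 2.4e-12)
  expect_equal(mass_to_reduce(0, 5), 0)
  expect_equal(mass_to_reduce(1, 1e12), 1)
  expect_error(mass_to_reduce(1, 0), "positive")
  expect_error(mass_to_reduce(-1, 1), "non-negative")
})

test_that("per-scenario monetary values match the published table", {
  alts <- paper_alternatives()
  ref <- alts[[2]]
  mv <- scenario_monetary_value(ref, scen)
  expect_equal(signif(unname(mv["High"]), 3), 6.66e-7)
  expect_equal(unname(mv["High"]), 0.75 * 370000 * 2.4e-12)
  # zero success probability zeroes the value
  dead <- mitigation_alternative("dead", 1000,
                                 c(High = 0.5, Medium = 0.4, Low = 0.1),
                                 c(High = 0, Medium = 0, Low = 0))
  expect_equal(unname(scenario_monetary_value(dead, scen)), c(0, 0, 0))
})

test_that("EMV reproduces all three published sector values at 3 s.f.", {
  alts <- paper_alternatives()
  got <- vapply(alts, emv, 0, scen)
  expect_equal(signif(got, 3), c(7.64e-8, 4.86e-7, 1.37e-7))
})

test_that("EMV equals the dot-product oracle on random problems", {
  for (seed in 1:30) {
    prob <- random_decision_problem(generator_config(seed))
    for (a in prob$alternatives) {
      mv <- a$success_prob[prob$scenarios$label] * a$dollars_per_ton *
        prob$scenarios$reduction * 1e-12
      expect_equal(emv(a, prob$scenarios),
                   sum(a$scenario_prob[prob$scenarios$label] * mv),
                   tolerance = 1e-12)
    }
  }
})

test_that("EMV and monetary values are homogeneous of degree 1 in V", {
  prob <- random_decision_problem(generator_config(99))
  a <- prob$alternatives[[1]]
  for (v in c(1, 10, 1e6)) {
    expect_equal(emv(a, prob$scenarios, volume = v),
                 v * emv(a, prob$scenarios, volume = 1),
                 tolerance = 1e-12)
    expect_equal(scenario_monetary_value(a, prob$scenarios, volume = v),
                 v * scenario_monetary_value(a, prob$scenarios,
                                             volume = 1),
                 tolerance = 1e-12)
  }
})

test_that("expected utility reproduces the published refineries column", {
  ref <- paper_alternatives()[[2]]
  eu5 <- expected_utility(ref, scen, R = 5)
  expect_equal(signif(as.numeric(eu5), 3), 9.72e-8)
  expect_equal(signif(unname(attr(eu5, "utilities")["High"]), 3),
               1.33e-7)
  expect_equal(signif(as.numeric(expected_utility(ref, scen, R = 100)),
                      3), 4.86e-9)
  expect_equal(signif(as.numeric(expected_utility(ref, scen, R = 200)),
                      3), 2.43e-9)
  expect_error(expected_utility(ref, scen, R = 0), "positive")
})

test_that("per-scenario and aggregate utility modes agree at 3 s.f. on
           the published problem", {
  for (a in paper_alternatives()) {
    for (R in c(5, 100, 200)) {
      per <- as.numeric(expected_utility(a, scen, R = R))
      agg <- expected_utility(a, scen, R = R, mode = "aggregate")
      expect_equal(signif(per, 3), signif(agg, 3))
    }
  }
})

test_that("utilities are bounded, monotone in value and decreasing in R", {
  prob <- random_decision_problem(generator_config(7))
  a <- prob$alternatives[[1]]
  u <- attr(expected_utility(a, prob$scenarios, R = 1e-6), "utilities")
  expect_true(all(u >= 0 & u < 1))
  eus <- vapply(c(1e-9, 1e-7, 1e-5), function(R)
    as.numeric(expected_utility(a, prob$scenarios, R = R)), 0)
  expect_true(all(diff(eus) < 0))  # larger R, smaller EU
  # strictly increasing in each monetary value via dollars_per_ton
  bigger <- mitigation_alternative(a$name, a$dollars_per_ton * 2,
                                   a$scenario_prob, a$success_prob)
  expect_gt(as.numeric(expected_utility(bigger, prob$scenarios, R = 1)),
            as.numeric(expected_utility(a, prob$scenarios, R = 1)))
})

test_that("R * EU approaches EMV in the high-tolerance limit", {
  for (seed in 1:20) {
    prob <- random_decision_problem(generator_config(seed))
    for (a in prob$alternatives) {
      mv <- scenario_monetary_value(a, prob$scenarios)
      R <- max(mv) / 1e-7  # max(MV)/R = 1e-7 < 1e-6
      eu <- as.numeric(expected_utility(a, prob$scenarios, R = R))
      expect_equal(R * eu, emv(a, prob$scenarios),
                   tolerance = 1e-5)
    }
  }
})

test_that("rankings are descending with stable ties, matching sort", {
  alts <- paper_alternatives()
  val <- valuation_table(alts, scen, R = c(5, 100, 200))
  expect_equal(as.character(rank_alternatives(val$summary, "emv")),
               c("refineries", "electricity-generating units",
                 "ocean-going vessels"))
  # EMV and EU orderings coincide here (small MV/R regime)
  for (cr in c("eu_R5", "eu_R100", "eu_R200"))
    expect_equal(as.character(rank_alternatives(val$summary, cr)),
                 as.character(rank_alternatives(val$summary, "emv")))
  single <- valuation_table(alts[1], scen)
  expect_equal(as.character(rank_alternatives(single$summary)),
               "ocean-going vessels")
  for (seed in 1:10) {
    set.seed(seed)
    s <- data.frame(alternative = letters[1:5], emv = runif(5))
    expect_equal(as.character(rank_alternatives(s)),
                 s$alternative[order(-s$emv)])
  }
  tied <- data.frame(alternative = c("a", "b"), emv = c(1, 1))
  r <- rank_alternatives(tied)
  expect_equal(as.character(r), c("a", "b"))
  expect_length(attr(r, "ties"), 1)
})

test_that("EMV ratios reproduce the published headline multiples", {
  val <- valuation_table(paper_alternatives(), scen)
  r_e <- emv_ratio("refineries", "electricity-generating units",
                   val$summary)
  r_o <- emv_ratio("refineries", "ocean-going vessels", val$summary)
  expect_equal(attr(r_e, "rounded"), 3.5)
  expect_equal(attr(r_o, "rounded"), 6.4)
  expect_equal(as.numeric(emv_ratio("refineries", "refineries",
                                    val$summary)), 1)
  expect_error(emv_ratio("refineries", "nope", val$summary), "unknown")
})

test_that("probability validation can be overridden for verbatim data", {
  expect_error(
    mitigation_alternative("x", 1, c(A = 0.5, B = 0.6), c(A = 1, B = 1)),
    "sum to")
  ok <- mitigation_alternative("x", 1, c(A = 0.5, B = 0.6),
                               c(A = 1, B = 1), check_probs = FALSE)
  expect_s3_class(ok, "mitigation_alternative")
})
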