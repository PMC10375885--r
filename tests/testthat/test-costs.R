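test_that("direct cost per person is factor times GDP per capita", {
  fact <- toy_factors()
  expect_equal(direct_cost_per_person(10000, "upper_middle", fact), 600)
  expect_equal(direct_cost_per_person(2 * 10000, "upper_middle", fact),
               2 * direct_cost_per_person(10000, "upper_middle", fact))
  # low-income anchor: imputed GDP 2327 prices out near 223 USD per person
  expect_equal(round(direct_cost_per_person(2327, "low", fact)), 223)
  bad <- fact[fact$income_class != "high", ]
  expect_error(direct_cost_per_person(10000, "high", bad), class = "coi_config_error")
  expect_error(direct_cost_per_person(NA_real_, "low", fact), class = "coi_validation_error")
})

test_that("total direct cost scales with the 50+ case count", {
  expect_equal(total_direct(223, 0), 0)
  expect_equal(total_direct(223, 1000), 223000)
  s <- run_synth(12, n = 7L)
  expect_rel_equal(s$res$costs$direct_total,
                   s$res$costs$direct_per_person * s$res$summaries$cases_50plus,
                   tol = 1e-12)
})

test_that("indirect cost is wage x hours x days x community share x cases", {
  best <- default_scenarios()$best
  worst <- default_scenarios()$worst
  expect_equal(indirect_cost(1000, 0, best), 0)
  expect_equal(indirect_cost(1000, 2, best), 2 * 1.6 * 365 * 0.90 * 1000)
  # worst/best ratio is (3.7 * 0.99) / (1.6 * 0.90) = 2.54375 exactly
  expect_equal(indirect_cost(777, 3.3, worst) / indirect_cost(777, 3.3, best), 2.54375)
  # strictly increasing in each argument
  expect_gt(indirect_cost(1001, 2, best), indirect_cost(1000, 2, best))
  expect_gt(indirect_cost(1000, 2.1, best), indirect_cost(1000, 2, best))
  expect_gt(indirect_cost(1000, 2, care_scenario("x", 1.7, 0.90)),
            indirect_cost(1000, 2, best))
  expect_gt(indirect_cost(1000, 2, care_scenario("x", 1.6, 0.95)),
            indirect_cost(1000, 2, best))
  expect_error(care_scenario("x", 0, 0.9), class = "coi_config_error")
  expect_error(care_scenario("x", 1.6, 1.2), class = "coi_config_error")
})

test_that("mean scenario is the midpoint and scenario order is enforced", {
  expect_equal(mean_indirect(0, 0), 0)
  expect_equal(mean_indirect(100, 300), 200)
  expect_error(mean_indirect(300, 100), class = "coi_scenario_error")
  b <- runif(20, 0, 1e6); w <- b * 2.54375
  m <- mean_indirect(b, w)
  expect_true(all(m >= b & m <= w))
})

test_that("percent of GDP handles boundary cases and missing GDP", {
  expect_equal(pct_of_gdp(5e9, 5e9), 100)
  expect_equal(pct_of_gdp(0, 5e9), 0)
  expect_true(is.na(pct_of_gdp(1e9, NA)))
  expect_error(pct_of_gdp(1, -1), class = "coi_validation_error")
})

test_that("pooled region percent of GDP differs from the mean of country percentages", {
  # two-country toy: same cost, very different GDPs
  costs <- data.frame(total = c(10, 10), gdp = c(100, 1000))
  pooled <- 100 * sum(costs$total) / sum(costs$gdp)
  mean_of <- mean(pct_of_gdp(costs$total, costs$gdp))
  expect_equal(pooled, 100 * 20 / 1100)
  expect_equal(mean_of, (10 + 1) / 2)
  expect_false(isTRUE(all.equal(pooled, mean_of)))
})

test_that("country cost tables respect the scenario ordering and identities", {
  for (seed in c(1, 13)) {
    s <- run_synth(seed, n = 9L)
    costs <- s$res$costs
    expect_true(all(costs$total_best <= costs$total_mean + 1e-9))
    expect_true(all(costs$total_mean <= costs$total_worst + 1e-9))
    expect_rel_equal(costs$total_best, costs$direct_total + costs$indirect_best, 1e-12)
    expect_rel_equal(costs$indirect_mean,
                     (costs$indirect_best + costs$indirect_worst) / 2, 1e-12)
    expect_rel_equal(costs$indirect_worst / costs$indirect_best,
                     rep(2.54375, nrow(costs)), 1e-12)
  }
})

test_that("costs are equivariant under a common currency rescaling", {
  s <- run_synth(14, n = 6L)
  k <- 3.5
  econ2 <- s$res$economics  # already imputed, no NA left
  econ2$gdp_pc_ppp <- econ2$gdp_pc_ppp * k
  econ2$monthly_wage <- econ2$monthly_wage * k
  econ2$gdp_total <- econ2$gdp_total * k
  costs2 <- compute_costs(s$res$summaries, econ2, s$inp$factors)
  expect_rel_equal(costs2$total_mean, k * s$res$costs$total_mean, 1e-12)
  expect_rel_equal(costs2$pct_gdp_mean, s$res$costs$pct_gdp_mean, 1e-12)
})

test_that("region sums conserve country-level costs", {
  s <- run_synth(15, n = 22L)
  reg <- s$res$region
  costs <- s$res$costs
  expect_rel_equal(reg$direct_total, sum(costs$direct_total), 1e-9)
  expect_rel_equal(reg$indirect_best, sum(costs$indirect_best), 1e-9)
  expect_rel_equal(reg$total_worst, sum(costs$total_worst), 1e-9)
})
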