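test_that("harmonization sums nested bands and rejects straddlers", {
  pop <- as_population_table(data.frame(
    country = "A", sex = rep(c("male", "female"), each = 2L),
    age_start = rep(c(60L, 65L), 2L), age_end = rep(c(64L, 69L), 2L),
    population = c(100, 50, 100, 50)))
  target <- data.frame(age_start = 60L, age_end = 69L)
  out <- harmonize_bands(pop, target)
  expect_equal(out$population, c(150, 150))

  straddler <- as_population_table(data.frame(
    country = "A", sex = "male", age_start = 58L, age_end = 62L, population = 10))
  expect_error(harmonize_bands(straddler, target), class = "coi_alignment_error")
})

test_that("harmonization conserves totals, including the open band", {
  for (seed in c(2, 9)) {
    inp <- generate_inputs(synth_config(seed = seed, n_countries = 6))
    h <- harmonize_bands(inp$population, default_target_bands(inp$schedule))
    expect_equal(sum(h$population), sum(inp$population$population))
    by_cs <- function(df) tapply(df$population, paste(df$country, df$sex), sum)
    expect_equal(by_cs(h)[names(by_cs(inp$population))], by_cs(inp$population))
    expect_true(any(is.na(h$age_end)))  # open band survives
  }
})

test_that("case estimation multiplies counts by the schedule and handles edges", {
  pop <- harmonize_bands(toy_population(), default_target_bands(toy_schedule()))
  sched <- toy_schedule()

  zero <- sched; zero$prevalence[] <- 0
  expect_true(all(estimate_cases(pop, zero)$cases == 0))

  one <- sched; one$prevalence[] <- 1
  ec <- estimate_cases(pop, one)
  expect_equal(ec$cases[ec$age_start >= 50], ec$population[ec$age_start >= 50])
  expect_true(all(ec$cases[ec$age_start < 50] == 0))  # below schedule onset

  # 2-band toy: 1000 at p=0.02 plus 500 at p=0.10 gives 70 cases
  pop2 <- as_population_table(data.frame(
    country = "A", sex = "male",
    age_start = c(50L, 60L), age_end = c(59L, NA), population = c(1000, 500)))
  expect_equal(sum(estimate_cases(pop2, sched)$cases), 70)

  # unharmonized band above schedule onset is a coverage error
  bad <- as_population_table(data.frame(
    country = "A", sex = "male", age_start = 55L, age_end = 64L, population = 10))
  expect_error(estimate_cases(bad, sched), class = "coi_coverage_error")
})

test_that("aggregation matches a per-stratum loop and guards thresholds", {
  s <- run_synth(4, n = 6L)
  cases <- s$res$cases
  # brute-force loop oracle
  for (cn in unique(cases$country)) {
    for (t in c(50, 60)) {
      sel <- cases$country == cn & cases$age_start >= t
      expect_rel_equal(
        s$res$summaries[[paste0("cases_", t, "plus")]][s$res$summaries$country == cn],
        sum(cases$cases[sel]), tol = 1e-12)
    }
  }
  expect_error(aggregate_cases(cases, thresholds = 55L), class = "coi_boundary_error")
})

test_that("zero population above a threshold yields NA prevalence, not zero", {
  pop <- as_population_table(data.frame(
    country = "A", sex = "male", age_start = 50L, age_end = 59L, population = 0))
  sched <- toy_schedule()
  summ <- aggregate_cases(estimate_cases(pop, sched), thresholds = c(50L, 60L))
  expect_true(is.na(summ$prev_50plus))
  expect_true(is.na(summ$prev_60plus))
})

test_that("all population in 60+ makes 50+ and 60+ prevalence coincide", {
  pop <- as_population_table(data.frame(
    country = "A", sex = c("male", "female"),
    age_start = 60L, age_end = NA, population = c(400, 600)))
  summ <- aggregate_cases(estimate_cases(pop, toy_schedule()))
  expect_equal(summ$prev_50plus, summ$prev_60plus)
})

test_that("region case total sums countries and rejects duplicates", {
  summ <- data.frame(country = c("A", "B"), cases_50plus = c(10, 20))
  expect_equal(region_case_total(summ), 30)
  expect_equal(region_case_total(summ[1, ]), 10)
  dup <- rbind(summ, summ[1, ])
  expect_error(region_case_total(dup), class = "coi_aggregation_error")

  s <- run_synth(5, n = 22L)
  expect_rel_equal(region_case_total(s$res$summaries),
                   sum(s$gt$country$cases_50plus), tol = 1e-12)
})

test_that("case counts are linear in population and prevalence is scale-free", {
  s <- run_synth(6, n = 5L)
  pop2 <- s$inp$population
  pop2$population <- pop2$population * 2
  res2 <- estimate_burden(pop2, s$inp$schedule, s$inp$economics, s$inp$factors,
                          gdp_group_values = s$inp$truth$gdp_group_values,
                          wage_group_values = s$inp$truth$wage_group_values)
  expect_rel_equal(res2$summaries$cases_50plus, 2 * s$res$summaries$cases_50plus, tol = 1e-12)
  expect_rel_equal(res2$summaries$prev_50plus, s$res$summaries$prev_50plus, tol = 1e-12)
})

test_that("with age-increasing schedules 60+ prevalence is at least 50+ prevalence", {
  for (seed in 1:5) {
    s <- run_synth(seed, n = 8L)
    expect_true(all(s$res$summaries$prev_60plus >= s$res$summaries$prev_50plus - 1e-12))
  }
})
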