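# Shared toy fixtures, built in code.

toy_schedule <- function() {
  as_prevalence_schedule(data.frame(
    age_start = rep(c(50L, 60L), 2L),
    age_end   = rep(c(59L, NA), 2L),
    sex = rep(c("male", "female"), each = 2L),
    prevalence = c(0.02, 0.10, 0.02, 0.10)))
}

# one-country pyramid on 5-year bands from 40 to an open 70+ band
toy_population <- function(country = "A", counts = c(800, 700, 600, 500, 400, 300, 100)) {
  starts <- c(40L, 45L, 50L, 55L, 60L, 65L, 70L)
  ends <- c(44L, 49L, 54L, 59L, 64L, 69L, NA)
  as_population_table(data.frame(
    country = country,
    sex = rep(c("male", "female"), each = length(starts)),
    age_start = rep(starts, 2L), age_end = rep(ends, 2L),
    population = rep(counts, 2L)), year = 2021L)
}

toy_factors <- function() {
  as_cost_factors(data.frame(
    income_class = c("low", "lower_middle", "upper_middle", "high"),
    factor = c(0.0958, 0.08, 0.06, 0.044)))
}

toy_economics <- function() {
  as_country_economics(data.frame(
    country = c("A", "B", "C"),
    gdp_pc_ppp = c(2327, NA, 48894),
    income_class = c("low", "upper_middle", "high"),
    monthly_wage = c(104, NA, 3943.33),
    gdp_total = c(2e10, 5e10, NA)))
}

# full synthetic run shared by several tests
run_synth <- function(seed, n = 10L, ...) {
  inp <- generate_inputs(synth_config(seed = seed, n_countries = n, ...))
  res <- estimate_burden(inp$population, inp$schedule, inp$economics, inp$factors,
                         gdp_group_values = inp$truth$gdp_group_values,
                         wage_group_values = inp$truth$wage_group_values)
  list(inp = inp, res = res, gt = ground_truth(inp))
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  expect_true(all(abs(actual - expected) <=
                    tol * pmax(abs(expected), 1e-12) | (is.na(actual) & is.na(expected))))
}
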