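# End-to-end driver tying the stages together: harmonize -> estimate cases ->
# aggregate -> impute economics -> cost models -> region roll-up.

#' Run the full burden-estimation pipeline
#'
#' @param population population table (any band granularity that nests in the
#'   schedule bands).
#' @param schedule prevalence schedule.
#' @param economics economics table; missing GDP/wages are imputed here.
#' @param factors direct-cost factor table.
#' @param gdp_group_values named vector, income class -> GDP per capita donor
#'   value, used for countries with missing GDP (required if any GDP is
#'   missing).
#' @param wage_group_values named vector, income class -> monthly wage donor.
#'   If `NULL`, class averages of the observed wages in `economics` are used
#'   (see [group_average_wage()]).
#' @param scenarios named list of [care_scenario()]s including `best` and
#'   `worst`.
#' @param convention a [wage_convention()].
#' @param case_threshold age cutoff for the priced case count (default 50).
#' @return list with `cases`, `summaries`, `economics` (post-imputation),
#'   `costs`, `region`.
#' @export
estimate_burden <- function(population, schedule, economics, factors,
                            gdp_group_values = NULL,
                            wage_group_values = NULL,
                            scenarios = default_scenarios(),
                            convention = wage_convention(),
                            case_threshold = 50L) {
  pop_h <- harmonize_bands(population, default_target_bands(schedule))
  cases <- estimate_cases(pop_h, schedule)
  summaries <- aggregate_cases(cases, thresholds = sort(unique(c(50L, 60L, case_threshold))))

  if (any(is.na(economics$gdp_pc_ppp))) {
    if (is.null(gdp_group_values)) {
      abort_imputation("gdp_pc_ppp has gaps but no gdp_group_values supplied")
    }
    economics <- impute_gdp(economics, gdp_group_values)
  }
  if (any(is.na(economics$monthly_wage))) {
    if (is.null(wage_group_values)) {
      wage_group_values <- group_average_wage(economics)
    }
    economics <- impute_wage(economics, wage_group_values)
  }

  costs <- compute_costs(summaries, economics, factors, scenarios = scenarios,
                         convention = convention, case_threshold = case_threshold)
  region <- region_summary(costs, summaries)
  list(cases = cases, summaries = summaries, economics = economics,
       costs = costs, region = region)
}
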