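# Cost models. Direct cost per person is an income-class-specific fraction of
# GDP per capita (PPP); indirect cost prices informal caregiver hours at the
# national average wage under bracketing scenarios. All arithmetic is double
# precision; rounding happens only in report formatting.

#' Informal-care scenario
#'
#' A scenario fixes the daily caregiver hours and the share of people with
#' dementia living in the community (and hence receiving informal care). The
#' defaults used by [default_scenarios()] bracket the burden: best case 1.6
#' h/day for 90% of cases, worst case 3.7 h/day for 99% of cases, both over
#' 365 days/year.
#'
#' @param label scenario name.
#' @param hours_per_day caregiver hours per day (> 0).
#' @param community_share proportion of cases living in the community,
#'   in (0, 1].
#' @param days_per_year days of care per year (default 365).
#' @return a list of class `coi_scenario`.
#' @export
care_scenario <- function(label, hours_per_day, community_share, days_per_year = 365) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    abort_config("scenario label must be a non-empty string")
  }
  if (!is.finite(hours_per_day) || hours_per_day <= 0) {
    abort_config("hours_per_day must be > 0")
  }
  if (!is.finite(community_share) || community_share <= 0 || community_share > 1) {
    abort_config("community_share must lie in (0, 1]")
  }
  if (!is.finite(days_per_year) || days_per_year <= 0) {
    abort_config("days_per_year must be > 0")
  }
  structure(list(label = label, hours_per_day = hours_per_day,
                 community_share = community_share, days_per_year = days_per_year),
            class = "coi_scenario")
}

#' @rdname care_scenario
#' @export
default_scenarios <- function() {
  list(best  = care_scenario("best", 1.6, 0.90),
       worst = care_scenario("worst", 3.7, 0.99))
}

#' Direct cost per person with dementia
#'
#' factor(income class) x GDP per capita (PPP), in USD per person per year.
#'
#' @param gdp_pc_ppp GDP per capita PPP (USD), post-imputation.
#' @param income_class World Bank income class (vector, recycled with gdp).
#' @param factors factor table (see [as_cost_factors()]).
#' @return USD per person per year.
#' @export
direct_cost_per_person <- function(gdp_pc_ppp, income_class, factors) {
  if (anyNA(gdp_pc_ppp)) {
    abort_validation("gdp_pc_ppp missing: impute before computing direct costs")
  }
  f <- factors$factor[match(income_class, factors$income_class)]
  if (anyNA(f)) {
    absent <- unique(income_class[is.na(f)])
    abort_config(sprintf("no direct-cost factor for income class(es): %s",
                         paste(absent, collapse = ", ")))
  }
  f * gdp_pc_ppp
}

#' Total direct cost
#'
#' @param per_person direct cost per person (USD/yr).
#' @param cases number of persons with dementia (the 50+ count by default
#'   convention).
#' @return USD per year.
#' @export
total_direct <- function(per_person, cases) {
  if (any(!is.na(cases) & cases < 0)) abort_validation("cases must be >= 0")
  per_person * cases
}

#' Indirect (informal care) cost under a scenario
#'
#' hourly wage x hours/day x days/year x community share x cases.
#'
#' @param cases persons with dementia.
#' @param hourly_wage caregiver wage in USD/h (retired caregivers are priced
#'   at the working-age wage; there is no separate wage track).
#' @param scenario a [care_scenario()].
#' @return USD per year.
#' @export
indirect_cost <- function(cases, hourly_wage, scenario) {
  if (!inherits(scenario, "coi_scenario")) {
    abort_config("scenario must be created by care_scenario()")
  }
  if (any(!is.na(cases) & cases < 0) || any(!is.na(hourly_wage) & hourly_wage < 0)) {
    abort_validation("cases and hourly_wage must be >= 0")
  }
  hourly_wage * scenario$hours_per_day * scenario$days_per_year *
    scenario$community_share * cases
}

#' Midpoint of best- and worst-case indirect costs
#'
#' @param best best-case indirect cost (USD/yr).
#' @param worst worst-case indirect cost (USD/yr); must be >= best.
#' @return (best + worst) / 2.
#' @export
mean_indirect <- function(best, worst) {
  if (any(!is.na(best) & !is.na(worst) & best > worst)) {
    abort_scenario("best-case indirect cost exceeds worst-case")
  }
  (best + worst) / 2
}

#' Total cost of illness
#'
#' @param direct direct cost (USD/yr).
#' @param indirect indirect cost (USD/yr).
#' @return direct + indirect.
#' @export
total_cost <- function(direct, indirect) {
  direct + indirect
}

#' Cost as a percentage of GDP
#'
#' @param total total cost (USD/yr).
#' @param gdp_total total GDP (USD/yr); `NA` yields `NA` (the country is then
#'   excluded from pooled region ratios).
#' @return percent (100 x total / gdp_total).
#' @export
pct_of_gdp <- function(total, gdp_total) {
  if (any(!is.na(gdp_total) & gdp_total <= 0)) {
    abort_validation("gdp_total must be > 0 when present")
  }
  100 * total / gdp_total
}

#' Country-level cost table
#'
#' Combines case summaries with (imputed) economics to produce, per country:
#' direct cost per person and total, indirect cost per scenario plus the
#' best/worst midpoint, totals under best/worst/mean, and each total as a
#' percentage of GDP. Direct costs use the case count at `case_threshold`
#' (50+ by default).
#'
#' @param summaries output of [aggregate_cases()].
#' @param econ economics table with no missing `gdp_pc_ppp`/`monthly_wage`
#'   (run [impute_gdp()]/[impute_wage()] first).
#' @param factors direct-cost factor table.
#' @param scenarios named list of [care_scenario()]s; must contain `best` and
#'   `worst` (extra scenarios get their own indirect column).
#' @param convention a [wage_convention()].
#' @param case_threshold age cutoff for the case count priced (default 50).
#' @return data frame, one row per country.
#' @export
compute_costs <- function(summaries, econ, factors,
                          scenarios = default_scenarios(),
                          convention = wage_convention(),
                          case_threshold = 50L) {
  if (!all(c("best", "worst") %in% names(scenarios))) {
    abort_config("scenarios must include 'best' and 'worst'")
  }
  col <- paste0("cases_", case_threshold, "plus")
  if (is.null(summaries[[col]])) {
    abort_config(sprintf("summaries lack column %s", col))
  }
  m <- match(summaries$country, econ$country)
  if (anyNA(m)) {
    abort_validation(sprintf("no economics row for country: %s",
                             paste(summaries$country[is.na(m)], collapse = ", ")))
  }
  ec <- econ[m, , drop = FALSE]
  cases <- summaries[[col]]

  out <- data.frame(country = summaries$country,
                    income_class = ec$income_class,
                    cases = cases,
                    hourly_wage = monthly_to_hourly(ec$monthly_wage, convention))
  out$direct_per_person <- direct_cost_per_person(ec$gdp_pc_ppp, ec$income_class, factors)
  out$direct_total <- total_direct(out$direct_per_person, cases)
  for (nm in names(scenarios)) {
    out[[paste0("indirect_", nm)]] <- indirect_cost(cases, out$hourly_wage, scenarios[[nm]])
  }
  out$indirect_mean <- mean_indirect(out$indirect_best, out$indirect_worst)
  out$total_best  <- total_cost(out$direct_total, out$indirect_best)
  out$total_worst <- total_cost(out$direct_total, out$indirect_worst)
  out$total_mean  <- total_cost(out$direct_total, out$indirect_mean)
  out$gdp_total <- ec$gdp_total
  out$pct_gdp_best  <- pct_of_gdp(out$total_best, ec$gdp_total)
  out$pct_gdp_worst <- pct_of_gdp(out$total_worst, ec$gdp_total)
  out$pct_gdp_mean  <- pct_of_gdp(out$total_mean, ec$gdp_total)
  out <- out[order(out$country), , drop = FALSE]
  rownames(out) <- NULL
  out
}
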