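# Economic inputs: income-class imputation of missing GDP and wage values,
# and monthly-to-hourly wage conversion. Imputation never overwrites observed
# values and flags everything it fills, so provenance survives into reports.

#' Wage conversion convention
#'
#' Converts average monthly earnings to an hourly wage under a full-time
#' assumption: hourly = monthly x 12 / (hours_per_week x weeks_per_year).
#' The default 40 h/week x 52 weeks (divisor ~173.33 per month) is the
#' standard full-time-equivalent convention; both knobs are configurable.
#'
#' @param hours_per_week working hours per week (> 0), default 40.
#' @param weeks_per_year working weeks per year (> 0), default 52.
#' @return a list of class `coi_wage_convention`.
#' @export
wage_convention <- function(hours_per_week = 40, weeks_per_year = 52) {
  if (!is.numeric(hours_per_week) || length(hours_per_week) != 1L ||
      !is.finite(hours_per_week) || hours_per_week <= 0 ||
      !is.numeric(weeks_per_year) || length(weeks_per_year) != 1L ||
      !is.finite(weeks_per_year) || weeks_per_year <= 0) {
    abort_config("wage convention: hours_per_week and weeks_per_year must be > 0")
  }
  structure(list(hours_per_week = hours_per_week, weeks_per_year = weeks_per_year),
            class = "coi_wage_convention")
}

#' Convert monthly to hourly wage
#'
#' @param monthly monthly wage(s) in USD, >= 0.
#' @param convention a [wage_convention()].
#' @return hourly wage(s) in USD/h.
#' @export
monthly_to_hourly <- function(monthly, convention = wage_convention()) {
  if (!inherits(convention, "coi_wage_convention")) {
    abort_config("convention must be created by wage_convention()")
  }
  if (any(!is.na(monthly) & monthly < 0)) {
    abort_validation("monthly wage must be >= 0")
  }
  monthly * 12 / (convention$hours_per_week * convention$weeks_per_year)
}

impute_field <- function(econ, group_values, value_col, flag_col, label) {
  if (is.null(names(group_values)) || anyNA(group_values) || any(group_values <= 0)) {
    abort_imputation(sprintf("%s donor values must be a named, positive vector", label))
  }
  miss <- is.na(econ[[value_col]])
  need <- unique(econ$income_class[miss])
  absent <- setdiff(need, names(group_values))
  if (length(absent)) {
    abort_imputation(sprintf("no %s donor value for income class(es): %s",
                             label, paste(absent, collapse = ", ")))
  }
  econ[[value_col]][miss] <- unname(group_values[econ$income_class[miss]])
  econ[[flag_col]] <- econ[[flag_col]] | miss
  econ
}

#' Impute missing GDP per capita (PPP) from income-group values
#'
#' Replaces missing `gdp_pc_ppp` with the donor value of the country's World
#' Bank income class (e.g. the published income-group aggregate) and sets
#' `imputed_gdp`. Observed values are never touched, so the operation is
#' idempotent.
#'
#' @param econ economics table.
#' @param group_values named numeric vector, income class -> USD (PPP).
#' @return the economics table with gaps filled.
#' @export
impute_gdp <- function(econ, group_values) {
  impute_field(econ, group_values, "gdp_pc_ppp", "imputed_gdp", "GDP")
}

#' Impute missing monthly wages from income-class averages
#'
#' @param econ economics table.
#' @param class_wages named numeric vector, income class -> USD/month, e.g.
#'   from [group_average_wage()] on an ILO-style extract.
#' @return the economics table with gaps filled and `imputed_wage` set.
#' @export
impute_wage <- function(econ, class_wages) {
  impute_field(econ, class_wages, "monthly_wage", "imputed_wage", "wage")
}

#' Average monthly wage per income class
#'
#' Arithmetic mean of observed monthly wages within each income class, used as
#' the donor mapping for [impute_wage()]. Classes with no observed wage are
#' omitted (requesting one downstream raises an imputation error there).
#'
#' @param observed data frame with columns `income_class`, `monthly_wage`
#'   (missing wages are ignored).
#' @return named numeric vector, income class -> mean USD/month.
#' @export
group_average_wage <- function(observed) {
  keep <- !is.na(observed$monthly_wage)
  if (!any(keep)) abort_imputation("no observed wages to average")
  means <- tapply(observed$monthly_wage[keep], observed$income_class[keep], mean)
  out <- as.numeric(means)
  names(out) <- names(means)
  out
}
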