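# Typed error conditions: every validation failure raises a classed condition so
# callers (and tests) can distinguish schema problems from domain violations.

coi_abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "coiburden_error"), call = call))
}

abort_schema     <- function(msg) coi_abort(msg, "coi_schema_error")
abort_validation <- function(msg) coi_abort(msg, "coi_validation_error")
abort_alignment  <- function(msg) coi_abort(msg, "coi_alignment_error")
abort_coverage   <- function(msg) coi_abort(msg, "coi_coverage_error")
abort_boundary   <- function(msg) coi_abort(msg, "coi_boundary_error")
abort_aggregation<- function(msg) coi_abort(msg, "coi_aggregation_error")
abort_imputation <- function(msg) coi_abort(msg, "coi_imputation_error")
abort_config     <- function(msg) coi_abort(msg, "coi_config_error")
abort_scenario   <- function(msg) coi_abort(msg, "coi_scenario_error")
abort_io         <- function(msg) coi_abort(msg, "coi_io_error")

#' Recognised sexes and World Bank income classes
#'
#' Enumerations used throughout the pipeline. Sexes follow the two-category
#' layout of UN population tables; income classes are the four World Bank
#' tiers that key both the direct-cost factors and the imputation donors.
#'
#' @name enumerations
#' @keywords internal
NULL

coi_sexes <- c("male", "female")
coi_income_classes <- c("low", "lower_middle", "upper_middle", "high")
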