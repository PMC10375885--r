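# Prevalence engine: apply an age/sex prevalence schedule to population
# pyramids, then aggregate case counts and prevalence proportions above age
# thresholds. Case counts stay real-valued; rounding to whole persons happens
# only at report formatting.

#' Estimate dementia cases per stratum
#'
#' Multiplies each (country, sex, age band) population count by the matching
#' prevalence proportion: cases = p(band, sex) x pop(country, sex, band).
#' Population bands must already be harmonized to the schedule's bands (see
#' [harmonize_bands()]); strata below the schedule's lowest band carry zero
#' cases but are kept so downstream denominators remain complete.
#'
#' @param pop population table harmonized to the schedule bands.
#' @param schedule prevalence schedule.
#' @return a case table: `country`, `sex`, `age_start`, `age_end`,
#'   `population`, `prevalence`, `cases`.
#' @export
estimate_cases <- function(pop, schedule) {
  lo <- min(schedule$age_start)
  sched_key <- paste(schedule$age_start, band_upper(schedule$age_end), schedule$sex)
  pop_key <- paste(pop$age_start, band_upper(pop$age_end), pop$sex)
  p <- schedule$prevalence[match(pop_key, sched_key)]

  below <- pop$age_start < lo & band_upper(pop$age_end) < lo
  p[below] <- 0
  if (anyNA(p)) {
    bad <- which(is.na(p))[1L]
    abort_coverage(sprintf(
      "population band %s (%s, %s) has no matching schedule band; harmonize first",
      band_label(pop$age_start[bad], pop$age_end[bad]),
      pop$country[bad], pop$sex[bad]))
  }

  out <- data.frame(country = pop$country, sex = pop$sex,
                    age_start = pop$age_start, age_end = pop$age_end,
                    population = pop$population,
                    prevalence = p,
                    cases = p * pop$population)
  out <- out[order(out$country, out$sex, out$age_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate cases and prevalence above age thresholds
#'
#' Sums cases and population over both sexes for all bands starting at or
#' above each threshold (default 50 and 60 years), and reports prevalence as
#' cases divided by population at the same threshold. A threshold that cuts
#' through a band is a boundary error; a zero population above a threshold
#' yields `NA` prevalence, never 0.
#'
#' @param cases case table from [estimate_cases()].
#' @param thresholds integer vector of age cutoffs.
#' @return one row per country with `cases_<t>plus`, `pop_<t>plus`,
#'   `prev_<t>plus` columns for each threshold `t`.
#' @export
aggregate_cases <- function(cases, thresholds = c(50L, 60L)) {
  countries <- sort(unique(cases$country))
  out <- data.frame(country = countries)
  upper <- band_upper(cases$age_end)
  for (t in thresholds) {
    straddle <- cases$age_start < t & upper >= t
    if (any(straddle)) {
      bad <- which(straddle)[1L]
      abort_boundary(sprintf(
        "threshold %d cuts through band %s; choose thresholds on band boundaries",
        t, band_label(cases$age_start[bad], cases$age_end[bad])))
    }
    keep <- cases$age_start >= t
    cs <- tapply(cases$cases[keep], factor(cases$country[keep], levels = countries),
                 sum, default = 0)
    ps <- tapply(cases$population[keep], factor(cases$country[keep], levels = countries),
                 sum, default = 0)
    cs <- as.numeric(cs); ps <- as.numeric(ps)
    out[[paste0("cases_", t, "plus")]] <- cs
    out[[paste0("pop_", t, "plus")]] <- ps
    out[[paste0("prev_", t, "plus")]] <- ifelse(ps > 0, cs / ps, NA_real_)
  }
  out
}

#' Region-wide case total
#'
#' Exact sum of per-country case counts at the chosen threshold.
#'
#' @param summaries output of [aggregate_cases()].
#' @param threshold age cutoff whose case column is summed (default 50).
#' @return total persons with dementia across all countries.
#' @export
region_case_total <- function(summaries, threshold = 50L) {
  if (anyDuplicated(summaries$country)) {
    abort_aggregation("duplicate country in summaries")
  }
  col <- paste0("cases_", threshold, "plus")
  if (is.null(summaries[[col]])) {
    abort_aggregation(sprintf("no column %s in summaries", col))
  }
  sum(summaries[[col]])
}
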