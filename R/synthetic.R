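# Synthetic-data generator and its independent oracle. The generator emits
# internally consistent multi-country inputs (5-year population pyramids with
# exponential old-age tails, a prevalence schedule rising with age and higher
# for women, lognormal GDP with income-class thresholds, wages tied to GDP by
# a power law, deliberate missingness). The oracle recomputes every pipeline
# output with naive per-stratum, per-country loops so the vectorized path can
# be checked against it on arbitrary seeds.

#' Synthetic-input configuration
#'
#' @param seed RNG seed; the generator uses one private stream and leaves the
#'   global RNG state untouched.
#' @param n_countries number of countries (>= 1).
#' @param pop_scale_range range of country population scales (persons in the
#'   youngest stratum).
#' @param age_decay per-year exponential decline of stratum size with the band
#'   midpoint; ~0.045 gives old-age tails like high-fertility pyramids.
#' @param sex_ratio_at_60 proportion female at age 60; drifts slightly upward
#'   with age (female survival advantage).
#' @param prevalence_base prevalence in the youngest schedule band (50-59,
#'   males).
#' @param per_decade_multiplier multiplicative increase of prevalence per
#'   decade of age (>= 1, so schedules are non-decreasing in age).
#' @param female_male_ratio female/male prevalence rate ratio.
#' @param gdp_log_mean,gdp_log_sd lognormal parameters of GDP per capita PPP.
#' @param income_thresholds three increasing USD cutpoints splitting GDP per
#'   capita into the four World Bank classes.
#' @param wage_elasticity exponent linking monthly wage to GDP per capita.
#' @param missing_gdp,missing_wage,missing_gdp_total probabilities a field is
#'   blanked to emulate incomplete World Bank / ILO coverage. Wage coverage is
#'   the sparsest in practice (most countries lack ILO wage rows), hence the
#'   high default.
#' @return a list of class `coi_synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_countries = 22L,
                         pop_scale_range = c(5e5, 5e7),
                         age_decay = 0.045,
                         sex_ratio_at_60 = 0.52,
                         prevalence_base = 0.006,
                         per_decade_multiplier = 2.8,
                         female_male_ratio = 1.25,
                         gdp_log_mean = 9.3,
                         gdp_log_sd = 1.1,
                         income_thresholds = c(4000, 13000, 30000),
                         wage_elasticity = 0.9,
                         missing_gdp = 0.14,
                         missing_wage = 0.85,
                         missing_gdp_total = 0.05) {
  cfg <- as.list(environment())
  if (n_countries < 1L) abort_config("n_countries must be >= 1")
  if (per_decade_multiplier < 1) abort_config("per_decade_multiplier must be >= 1")
  if (any(diff(income_thresholds) <= 0) || length(income_thresholds) != 3L) {
    abort_config("income_thresholds must be three strictly increasing cutpoints")
  }
  probs <- c(missing_gdp, missing_wage, missing_gdp_total, sex_ratio_at_60)
  if (any(probs < 0 | probs > 1)) abort_config("probabilities must lie in [0, 1]")
  if (prevalence_base <= 0 || prevalence_base > 1) {
    abort_config("prevalence_base must lie in (0, 1]")
  }
  structure(cfg, class = "coi_synth_config")
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's global RNG state afterwards.
with_private_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a complete synthetic input set
#'
#' Produces the four tables the pipeline consumes (population pyramid on
#' 5-year bands up to an open 90+ band, a decade prevalence schedule from age
#' 50, country economics with missingness, direct-cost factors) plus the
#' ground-truth values needed to check imputation: the pre-blanking GDP and
#' wages and the income-class donor mappings derived from them.
#'
#' @param cfg a [synth_config()].
#' @return list with elements `population`, `schedule`, `economics`,
#'   `factors`, `truth`.
#' @export
generate_inputs <- function(cfg = synth_config()) {
  if (!inherits(cfg, "coi_synth_config")) abort_config("cfg must come from synth_config()")
  with_private_rng(cfg$seed, {
    countries <- sprintf("C%02d", seq_len(cfg$n_countries))

    # prevalence schedule: decade bands from 50, open 90+
    starts <- c(50L, 60L, 70L, 80L, 90L)
    ends <- c(59L, 69L, 79L, 89L, NA)
    p_male <- pmin(cfg$prevalence_base * cfg$per_decade_multiplier^(seq_along(starts) - 1L), 0.95)
    p_female <- pmin(p_male * cfg$female_male_ratio, 0.95)
    schedule <- as_prevalence_schedule(data.frame(
      age_start = rep(starts, 2L), age_end = rep(ends, 2L),
      sex = rep(coi_sexes, each = length(starts)),
      prevalence = c(p_male, p_female)))

    # population pyramids: 5-year bands 0-4 ... 85-89, open 90+
    a_start <- c(seq(0L, 85L, by = 5L), 90L)
    a_end <- c(seq(4L, 89L, by = 5L), NA)
    mid <- ifelse(is.na(a_end), a_start + 5, (a_start + a_end) / 2)
    pop_rows <- vector("list", cfg$n_countries)
    scale <- exp(stats::runif(cfg$n_countries,
                              log(cfg$pop_scale_range[1]), log(cfg$pop_scale_range[2])))
    for (i in seq_len(cfg$n_countries)) {
      base <- scale[i] * exp(-cfg$age_decay * mid) *
        exp(stats::rnorm(length(mid), 0, 0.05))
      fem <- stats::plogis(stats::qlogis(cfg$sex_ratio_at_60) + 0.004 * (mid - 60))
      pop_rows[[i]] <- data.frame(
        country = countries[i],
        sex = rep(coi_sexes, each = length(mid)),
        age_start = rep(a_start, 2L), age_end = rep(a_end, 2L),
        population = round(c(base * (1 - fem), base * fem)))
    }
    population <- as_population_table(do.call(rbind, pop_rows), year = 2021L)

    # economics: lognormal GDP, class from thresholds, wage ~ GDP^elasticity
    gdp <- stats::rlnorm(cfg$n_countries, cfg$gdp_log_mean, cfg$gdp_log_sd)
    cls <- coi_income_classes[findInterval(gdp, cfg$income_thresholds) + 1L]
    wage <- 0.1 * gdp^cfg$wage_elasticity * exp(stats::rnorm(cfg$n_countries, 0, 0.2))
    pop_total <- tapply(population$population,
                        factor(population$country, levels = countries), sum)
    gdp_total <- gdp * as.numeric(pop_total) * stats::runif(cfg$n_countries, 0.6, 1.1)

    blank_gdp <- stats::runif(cfg$n_countries) < cfg$missing_gdp
    blank_wage <- stats::runif(cfg$n_countries) < cfg$missing_wage
    blank_gt <- stats::runif(cfg$n_countries) < cfg$missing_gdp_total
    economics <- as_country_economics(data.frame(
      country = countries,
      gdp_pc_ppp = ifelse(blank_gdp, NA_real_, gdp),
      income_class = cls,
      monthly_wage = ifelse(blank_wage, NA_real_, wage),
      gdp_total = ifelse(blank_gt, NA_real_, gdp_total)))

    factors <- as_cost_factors(data.frame(
      income_class = coi_income_classes,
      factor = c(0.0958, 0.080, 0.060, 0.044)))

    truth <- list(
      config = cfg,
      gdp = stats::setNames(gdp, countries),
      monthly_wage = stats::setNames(wage, countries),
      gdp_group_values = vapply(split(gdp, cls), mean, numeric(1)),
      wage_group_values = vapply(split(wage, cls), mean, numeric(1)),
      schedule_curve = list(male = p_male, female = p_female, age_start = starts))

    list(population = population, schedule = schedule, economics = economics,
         factors = factors, truth = truth)
  })
}

#' Independent loop-based oracle for the full pipeline
#'
#' Recomputes every country- and region-level output of [estimate_burden()]
#' with explicit scalar loops over strata and countries, sharing no code with
#' the vectorized pipeline. Used to verify the pipeline on synthetic inputs.
#'
#' @param inputs output of [generate_inputs()] (or a list with the same
#'   elements).
#' @param scenarios named list with `best` and `worst` [care_scenario()]s.
#' @param convention a [wage_convention()].
#' @return list with `country` (data frame) and `region` (list) results.
#' @export
ground_truth <- function(inputs, scenarios = default_scenarios(),
                         convention = wage_convention()) {
  pop <- as.data.frame(inputs$population)
  sched <- as.data.frame(inputs$schedule)
  econ <- as.data.frame(inputs$economics)
  fact <- as.data.frame(inputs$factors)
  gdp_donor <- inputs$truth$gdp_group_values
  wage_donor <- inputs$truth$wage_group_values

  countries <- sort(unique(pop$country))
  rows <- list()
  for (cn in countries) {
    cases50 <- 0; cases60 <- 0; pop50 <- 0; pop60 <- 0
    for (i in which(pop$country == cn)) {
      s <- pop$age_start[i]
      e <- if (is.na(pop$age_end[i])) Inf else pop$age_end[i]
      n <- pop$population[i]
      p <- 0
      for (j in seq_len(nrow(sched))) {
        if (sched$sex[j] == pop$sex[i]) {
          js <- sched$age_start[j]
          je <- if (is.na(sched$age_end[j])) Inf else sched$age_end[j]
          if (s >= js && e <= je) p <- sched$prevalence[j]
        }
      }
      if (s >= 50) { pop50 <- pop50 + n; cases50 <- cases50 + p * n }
      if (s >= 60) { pop60 <- pop60 + n; cases60 <- cases60 + p * n }
    }

    k <- which(econ$country == cn)
    gdp <- econ$gdp_pc_ppp[k]
    if (is.na(gdp)) gdp <- gdp_donor[[econ$income_class[k]]]
    wage <- econ$monthly_wage[k]
    if (is.na(wage)) wage <- wage_donor[[econ$income_class[k]]]
    hourly <- wage * 12 / (convention$hours_per_week * convention$weeks_per_year)
    f <- fact$factor[fact$income_class == econ$income_class[k]]

    direct_pp <- f * gdp
    direct <- direct_pp * cases50
    ib <- hourly * scenarios$best$hours_per_day * scenarios$best$days_per_year *
      scenarios$best$community_share * cases50
    iw <- hourly * scenarios$worst$hours_per_day * scenarios$worst$days_per_year *
      scenarios$worst$community_share * cases50
    im <- (ib + iw) / 2
    gt <- econ$gdp_total[k]

    rows[[cn]] <- data.frame(
      country = cn,
      cases_50plus = cases50, cases_60plus = cases60,
      pop_50plus = pop50, pop_60plus = pop60,
      prev_50plus = if (pop50 > 0) cases50 / pop50 else NA_real_,
      prev_60plus = if (pop60 > 0) cases60 / pop60 else NA_real_,
      hourly_wage = hourly,
      direct_per_person = direct_pp, direct_total = direct,
      indirect_best = ib, indirect_worst = iw, indirect_mean = im,
      total_best = direct + ib, total_worst = direct + iw, total_mean = direct + im,
      gdp_total = gt,
      pct_gdp_best = if (is.na(gt)) NA_real_ else 100 * (direct + ib) / gt,
      pct_gdp_worst = if (is.na(gt)) NA_real_ else 100 * (direct + iw) / gt,
      pct_gdp_mean = if (is.na(gt)) NA_real_ else 100 * (direct + im) / gt)
  }
  country <- do.call(rbind, rows)
  rownames(country) <- NULL

  pooled <- function(scol) {
    has <- !is.na(country$gdp_total)
    100 * sum(country[[scol]][has]) / sum(country$gdp_total[has])
  }
  region <- list(
    cases_50plus = sum(country$cases_50plus),
    cases_60plus = sum(country$cases_60plus),
    prev_50plus = sum(country$cases_50plus) / sum(country$pop_50plus),
    prev_60plus = sum(country$cases_60plus) / sum(country$pop_60plus),
    direct_total = sum(country$direct_total),
    indirect_best = sum(country$indirect_best),
    indirect_worst = sum(country$indirect_worst),
    indirect_mean = sum(country$indirect_mean),
    total_best = sum(country$total_best),
    total_worst = sum(country$total_worst),
    total_mean = sum(country$total_mean),
    pct_gdp_best_pooled = pooled("total_best"),
    pct_gdp_worst_pooled = pooled("total_worst"),
    pct_gdp_mean_pooled = pooled("total_mean"))
  list(country = country, region = region)
}
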