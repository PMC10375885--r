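# Typed CSV input/output. All tables travel as plain data frames that have
# passed the as_*() validators; readers are thin wrappers around read.csv with
# schema checks, writers emit deterministic UTF-8 CSV (comma separated, "."
# decimal, empty cell = missing, LF line endings) so re-runs are byte-stable.

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_schema(sprintf("%s: missing column(s): %s",
                         basename(path), paste(missing, collapse = ", ")))
  }
  df
}

write_csv_plain <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    abort_io(sprintf("cannot open %s for writing: %s", path, conditionMessage(e))))
  old <- options(scipen = 15)  # plain decimal notation, stable across runs
  on.exit({ close(con); options(old) })
  utils::write.csv(df, con, row.names = FALSE, na = "", eol = "\n",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

check_sex_values <- function(sex, where) {
  bad <- setdiff(unique(sex), coi_sexes)
  if (length(bad)) {
    abort_validation(sprintf("%s: unknown sex value(s): %s (expected %s)",
                             where, paste(bad, collapse = ", "),
                             paste(coi_sexes, collapse = "/")))
  }
}

#' Validate a population table
#'
#' A population table holds one row per (country, sex, age band) stratum with
#' a non-negative person count. Bands within each (country, sex) must be
#' pairwise non-overlapping with at most one open ("X+") band.
#'
#' @param df data frame with columns `country`, `sex`, `age_start`, `age_end`
#'   (`NA` = open band), `population`. An optional `iso3` column is carried
#'   through untouched.
#' @param year calendar year the counts refer to; stored as an attribute.
#' @return the validated data frame, class `coi_population`.
#' @export
as_population_table <- function(df, year = NULL) {
  required <- c("country", "sex", "age_start", "age_end", "population")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_schema(sprintf("population table: missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  check_sex_values(df$sex, "population table")
  check_band_fields(df$age_start, df$age_end, "population table")
  bad <- which(is.na(df$population) | !is.finite(df$population) | df$population < 0)
  if (length(bad)) {
    abort_validation(sprintf(
      "population table: negative or non-finite count in row %d (%s, %s, %s)",
      bad[1L], df$country[bad[1L]], df$sex[bad[1L]],
      band_label(df$age_start[bad[1L]], df$age_end[bad[1L]])))
  }
  for (grp in split(df, list(df$country, df$sex), drop = TRUE)) {
    if (bands_overlap(grp$age_start, grp$age_end)) {
      abort_validation(sprintf("population table: overlapping age bands for %s/%s",
                               grp$country[1L], grp$sex[1L]))
    }
    if (sum(is.na(grp$age_end)) > 1L) {
      abort_validation(sprintf("population table: more than one open band for %s/%s",
                               grp$country[1L], grp$sex[1L]))
    }
  }
  out <- as.data.frame(df)
  if (!is.null(year)) attr(out, "year") <- year
  class(out) <- c("coi_population", "data.frame")
  out
}

#' Validate a prevalence schedule
#'
#' One prevalence proportion per (age band, sex). Bands must be identical for
#' both sexes, contiguous (each band starts the year after the previous ends)
#' and terminate in an open band, so that every old-age stratum is covered.
#'
#' @param df data frame with columns `age_start`, `age_end`, `sex`,
#'   `prevalence`.
#' @return the validated data frame, class `coi_prevalence`.
#' @export
as_prevalence_schedule <- function(df) {
  required <- c("age_start", "age_end", "sex", "prevalence")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_schema(sprintf("prevalence schedule: missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  check_sex_values(df$sex, "prevalence schedule")
  check_band_fields(df$age_start, df$age_end, "prevalence schedule")
  if (any(is.na(df$prevalence) | df$prevalence < 0 | df$prevalence > 1)) {
    abort_validation("prevalence schedule: prevalence must lie in [0, 1]")
  }
  key <- paste(df$age_start, df$age_end, df$sex)
  if (anyDuplicated(key)) {
    abort_validation("prevalence schedule: duplicate (band, sex) entry")
  }
  for (s in coi_sexes) {
    sub <- df[df$sex == s, , drop = FALSE]
    if (nrow(sub) == 0L) {
      abort_validation(sprintf("prevalence schedule: no rows for sex %s", s))
    }
    sub <- sub[order(sub$age_start), , drop = FALSE]
    if (!is.na(sub$age_end[nrow(sub)])) {
      abort_validation(sprintf(
        "prevalence schedule: terminal band for %s must be open (blank age_end)", s))
    }
    if (nrow(sub) > 1L) {
      ends <- sub$age_end[-nrow(sub)]
      starts <- sub$age_start[-1L]
      if (anyNA(ends) || any(starts != ends + 1L)) {
        abort_validation(sprintf(
          "prevalence schedule: bands for %s are not contiguous", s))
      }
    }
  }
  bm <- df[df$sex == "male", c("age_start", "age_end")]
  bf <- df[df$sex == "female", c("age_start", "age_end")]
  bm <- bm[order(bm$age_start), ]; bf <- bf[order(bf$age_start), ]
  if (!identical(unname(as.matrix(bm)), unname(as.matrix(bf)))) {
    abort_validation("prevalence schedule: male and female bands differ")
  }
  out <- as.data.frame(df)
  class(out) <- c("coi_prevalence", "data.frame")
  out
}

#' Validate country economic indicators
#'
#' Per-country GDP per capita (PPP), World Bank income class, average monthly
#' wage and total GDP. Monetary fields may be missing (`NA`) prior to
#' imputation; `imputed_gdp` / `imputed_wage` flags record which values were
#' filled later and are initialised to `FALSE` if absent.
#'
#' @param df data frame with columns `country`, `gdp_pc_ppp`, `income_class`,
#'   `monthly_wage`, `gdp_total`.
#' @return the validated data frame, class `coi_economics`.
#' @export
as_country_economics <- function(df) {
  required <- c("country", "gdp_pc_ppp", "income_class", "monthly_wage", "gdp_total")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_schema(sprintf("economics table: missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(df$income_class), coi_income_classes)
  if (length(bad)) {
    abort_validation(sprintf("economics table: unknown income class(es): %s (expected %s)",
                             paste(bad, collapse = ", "),
                             paste(coi_income_classes, collapse = "/")))
  }
  if (anyDuplicated(df$country)) {
    abort_validation("economics table: duplicate country")
  }
  for (col in c("gdp_pc_ppp", "monthly_wage", "gdp_total")) {
    v <- df[[col]]
    if (any(!is.na(v) & v <= 0)) {
      abort_validation(sprintf("economics table: %s must be > 0 when present", col))
    }
  }
  if (is.null(df$imputed_gdp))  df$imputed_gdp  <- FALSE
  if (is.null(df$imputed_wage)) df$imputed_wage <- FALSE
  out <- as.data.frame(df)
  class(out) <- c("coi_economics", "data.frame")
  out
}

#' Validate a direct-cost factor table
#'
#' Maps each World Bank income class to the dimensionless multiplier applied
#' to GDP per capita (PPP) to obtain the direct cost per person with dementia.
#'
#' @param df data frame with columns `income_class`, `factor`.
#' @return the validated data frame, class `coi_factors`.
#' @export
as_cost_factors <- function(df) {
  required <- c("income_class", "factor")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_schema(sprintf("factor table: missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (!setequal(df$income_class, coi_income_classes) ||
      anyDuplicated(df$income_class)) {
    abort_validation(sprintf("factor table: must contain each income class exactly once (%s)",
                             paste(coi_income_classes, collapse = ", ")))
  }
  if (any(is.na(df$factor) | df$factor <= 0)) {
    abort_validation("factor table: factors must be > 0")
  }
  out <- as.data.frame(df)
  class(out) <- c("coi_factors", "data.frame")
  out
}

#' Read a population CSV
#'
#' Expects columns `country`, `sex`, `age_start`, `age_end`, `population`;
#' a blank `age_end` denotes an open terminal band such as "100+".
#'
#' @param path CSV file path.
#' @param year calendar year of the counts (stored as an attribute).
#' @return a validated population table.
#' @export
read_population_csv <- function(path, year = NULL) {
  df <- read_csv_checked(path, c("country", "sex", "age_start", "age_end", "population"))
  as_population_table(df, year = year)
}

#' Read a prevalence-schedule CSV
#'
#' Expects columns `age_start`, `age_end`, `sex`, `prevalence`; blank
#' `age_end` marks the open terminal band.
#'
#' @param path CSV file path.
#' @return a validated prevalence schedule.
#' @export
read_prevalence_csv <- function(path) {
  df <- read_csv_checked(path, c("age_start", "age_end", "sex", "prevalence"))
  as_prevalence_schedule(df)
}

#' Read a country-economics CSV
#'
#' Expects columns `country`, `gdp_pc_ppp`, `income_class`, `monthly_wage`,
#' `gdp_total`; empty cells mean missing and are left for imputation, with
#' imputation flags initialised to `FALSE`.
#'
#' @param path CSV file path.
#' @return a validated economics table.
#' @export
read_economics_csv <- function(path) {
  df <- read_csv_checked(path, c("country", "gdp_pc_ppp", "income_class",
                                 "monthly_wage", "gdp_total"))
  as_country_economics(df)
}

#' Read a direct-cost factor CSV
#'
#' @param path CSV file path with columns `income_class`, `factor`.
#' @return a validated factor table.
#' @export
read_factors_csv <- function(path) {
  df <- read_csv_checked(path, c("income_class", "factor"))
  as_cost_factors(df)
}

#' Write pipeline tables as deterministic CSV files
#'
#' Writes one file per table with rows ordered by country (a `TOTAL` row, if
#' present, stays last) and a fixed column order, so identical inputs yield
#' byte-identical files.
#'
#' @param tables named list of data frames (e.g. the output of
#'   [build_report()]).
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_results_csv <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  paths <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    if ("country" %in% names(df) && nrow(df)) {
      is_total <- df$country == "TOTAL"
      df <- rbind(df[!is_total, , drop = FALSE][order(df$country[!is_total]), , drop = FALSE],
                  df[is_total, , drop = FALSE])
    }
    paths <- c(paths, write_csv_plain(df, file.path(out_dir, paste0(nm, ".csv"))))
  }
  invisible(paths)
}

#' Write a population table back to CSV
#'
#' Inverse of [read_population_csv()]; open bands get a blank `age_end`.
#'
#' @param pop population table.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_population_csv <- function(pop, path) {
  cols <- intersect(c("country", "sex", "age_start", "age_end", "population", "iso3"),
                    names(pop))
  write_csv_plain(as.data.frame(pop)[, cols, drop = FALSE], path)
}

#' @rdname write_population_csv
#' @param schedule prevalence schedule.
#' @export
write_prevalence_csv <- function(schedule, path) {
  write_csv_plain(as.data.frame(schedule)[, c("age_start", "age_end", "sex", "prevalence")],
                  path)
}

#' @rdname write_population_csv
#' @param econ economics table.
#' @export
write_economics_csv <- function(econ, path) {
  cols <- intersect(c("country", "gdp_pc_ppp", "income_class", "monthly_wage",
                      "gdp_total", "imputed_gdp", "imputed_wage", "iso3"), names(econ))
  write_csv_plain(as.data.frame(econ)[, cols, drop = FALSE], path)
}

#' @rdname write_population_csv
#' @param factors factor table.
#' @export
write_factors_csv <- function(factors, path) {
  write_csv_plain(as.data.frame(factors)[, c("income_class", "factor")], path)
}
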