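# Reporting: region-level roll-ups, country rankings and the output table set
# (prevalence, direct, indirect, totals, pct-of-GDP) with recomputed TOTAL
# rows. Report generation is pure: identical inputs give identical files.

#' Region-level summary
#'
#' Sums country rows into region aggregates: case totals and pooled prevalence
#' at each threshold, direct/indirect/total costs, and cost as percent of GDP
#' in two variants: pooled (sum of costs over sum of GDPs, countries with
#' missing GDP excluded from both) and the unweighted mean of country
#' percentages.
#'
#' @param costs output of [compute_costs()].
#' @param summaries output of [aggregate_cases()].
#' @return a one-row data frame of region aggregates.
#' @export
region_summary <- function(costs, summaries) {
  out <- data.frame(n_countries = nrow(costs))
  for (t in c(50L, 60L)) {
    cs <- paste0("cases_", t, "plus"); ps <- paste0("pop_", t, "plus")
    if (!is.null(summaries[[cs]])) {
      out[[cs]] <- sum(summaries[[cs]])
      out[[ps]] <- sum(summaries[[ps]])
      out[[paste0("prev_", t, "plus")]] <-
        if (out[[ps]] > 0) out[[cs]] / out[[ps]] else NA_real_
    }
  }
  out$direct_total <- sum(costs$direct_total)
  for (s in c("best", "worst", "mean")) {
    out[[paste0("indirect_", s)]] <- sum(costs[[paste0("indirect_", s)]])
    out[[paste0("total_", s)]] <- sum(costs[[paste0("total_", s)]])
  }
  has_gdp <- !is.na(costs$gdp_total)
  gdp_pool <- sum(costs$gdp_total[has_gdp])
  for (s in c("best", "worst", "mean")) {
    tot <- costs[[paste0("total_", s)]]
    out[[paste0("pct_gdp_", s, "_pooled")]] <-
      if (gdp_pool > 0) 100 * sum(tot[has_gdp]) / gdp_pool else NA_real_
    out[[paste0("pct_gdp_", s, "_country_mean")]] <-
      mean(costs[[paste0("pct_gdp_", s)]], na.rm = TRUE)
  }
  out
}

#' Rank countries by a result column
#'
#' Stable sort on the requested column; ties are broken by country name
#' ascending.
#'
#' @param results data frame with a `country` column.
#' @param key column name to rank by.
#' @param decreasing sort largest first (default `TRUE`).
#' @return `results` reordered, with a `rank` column prepended.
#' @export
rank_countries <- function(results, key, decreasing = TRUE) {
  if (is.null(results[[key]])) {
    abort_validation(sprintf("unknown ranking key: %s", key))
  }
  v <- results[[key]]
  ord <- order(if (decreasing) -xtfrm(v) else xtfrm(v), results$country)
  out <- results[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Share of total cost that is informal care
#'
#' Per-country ratio indirect_mean / total_mean (0 when both are zero).
#'
#' @param costs output of [compute_costs()].
#' @return data frame with `country`, `indirect_to_total`.
#' @export
indirect_to_total_ratio <- function(costs) {
  ratio <- ifelse(costs$total_mean > 0, costs$indirect_mean / costs$total_mean, 0)
  data.frame(country = costs$country, indirect_to_total = ratio)
}

round_cols <- function(df, cols, digits) {
  for (cl in intersect(cols, names(df))) df[[cl]] <- round(df[[cl]], digits)
  df
}

#' Assemble the report table set
#'
#' Builds the five country-level output tables (prevalence, direct costs,
#' indirect costs, totals, percent of GDP), each with a recomputed `TOTAL`
#' row, plus the region summary and the indirect-to-total ratios. USD amounts
#' are rounded to whole dollars and percentages to 2 decimals at this
#' formatting stage only. Optionally writes the tables as CSV files and a
#' sorted pct-of-GDP bar chart.
#'
#' @param costs output of [compute_costs()].
#' @param summaries output of [aggregate_cases()].
#' @param out_dir if non-`NULL`, directory to write one CSV per table.
#' @param chart if `TRUE` (and `out_dir` given), also write
#'   `pct_gdp_barchart.pdf`.
#' @return named list of data frames.
#' @export
build_report <- function(costs, summaries, out_dir = NULL, chart = FALSE) {
  region <- region_summary(costs, summaries)

  prevalence <- summaries[order(summaries$country), , drop = FALSE]
  tot <- data.frame(country = "TOTAL")
  for (t in c(50L, 60L)) {
    for (p in c("cases_", "pop_")) {
      cl <- paste0(p, t, "plus")
      if (!is.null(prevalence[[cl]])) tot[[cl]] <- sum(prevalence[[cl]])
    }
    cl <- paste0("prev_", t, "plus")
    if (!is.null(prevalence[[cl]])) tot[[cl]] <- region[[cl]]
  }
  prevalence <- rbind(prevalence, tot[names(prevalence)])
  prevalence <- round_cols(prevalence, grep("^(cases|pop)_", names(prevalence), value = TRUE), 0)
  prevalence <- round_cols(prevalence, grep("^prev_", names(prevalence), value = TRUE), 4)

  usd_total_row <- function(df, usd_cols) {
    tr <- data.frame(country = "TOTAL")
    for (cl in usd_cols) tr[[cl]] <- sum(df[[cl]], na.rm = TRUE)
    for (cl in setdiff(names(df), c("country", usd_cols))) tr[[cl]] <- NA
    rbind(df, tr[names(df)])
  }

  direct <- costs[, c("country", "income_class", "cases",
                      "direct_per_person", "direct_total")]
  direct <- usd_total_row(direct, "direct_total")
  direct <- round_cols(direct, c("cases", "direct_per_person", "direct_total"), 0)

  ind_cols <- grep("^indirect_", names(costs), value = TRUE)
  indirect <- costs[, c("country", "hourly_wage", "cases", ind_cols)]
  indirect <- usd_total_row(indirect, ind_cols)
  indirect <- round_cols(indirect, c("cases", ind_cols), 0)
  indirect$hourly_wage <- round(indirect$hourly_wage, 2)

  totals <- costs[, c("country", "direct_total", "indirect_mean",
                      "total_best", "total_worst", "total_mean")]
  totals <- usd_total_row(totals, setdiff(names(totals), "country"))
  totals <- round_cols(totals, setdiff(names(totals), "country"), 0)

  pct <- costs[, c("country", "total_mean", "gdp_total",
                   "pct_gdp_best", "pct_gdp_worst", "pct_gdp_mean")]
  ptr <- data.frame(country = "TOTAL",
                    total_mean = sum(pct$total_mean),
                    gdp_total = sum(pct$gdp_total, na.rm = TRUE),
                    pct_gdp_best = region$pct_gdp_best_pooled,
                    pct_gdp_worst = region$pct_gdp_worst_pooled,
                    pct_gdp_mean = region$pct_gdp_mean_pooled)
  pct <- rbind(pct, ptr)
  pct <- round_cols(pct, c("total_mean", "gdp_total"), 0)
  pct <- round_cols(pct, grep("^pct_gdp_", names(pct), value = TRUE), 2)

  tables <- list(prevalence = prevalence, direct = direct, indirect = indirect,
                 totals = totals, pct_gdp = pct,
                 indirect_share = indirect_to_total_ratio(costs),
                 region = region)

  if (!is.null(out_dir)) {
    write_results_csv(tables, out_dir)
    if (chart) {
      ord <- rank_countries(costs[!is.na(costs$pct_gdp_mean), ], "pct_gdp_mean")
      grDevices::pdf(file.path(out_dir, "pct_gdp_barchart.pdf"), width = 9, height = 5)
      graphics::par(mar = c(7, 4, 2, 1))
      graphics::barplot(ord$pct_gdp_mean, names.arg = ord$country, las = 2,
                        ylab = "total dementia cost, % of GDP (mean scenario)")
      grDevices::dev.off()
    }
  }
  tables
}
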