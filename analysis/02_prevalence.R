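#!/usr/bin/env Rscript
# Stage 2: apply the age/sex prevalence schedule to the population pyramids.
# Collapses the 5-year pyramid bands into the schedule's decade bands,
# estimates cases per stratum and aggregates to 50+/60+ country summaries.

suppressPackageStartupMessages(library(coiburden))

pop <- read_population_csv("results/inputs/population.csv", year = 2021)
sched <- read_prevalence_csv("results/inputs/prevalence.csv")

pop_h <- harmonize_bands(pop, default_target_bands(sched))
stopifnot(sum(pop_h$population) == sum(pop$population))  # conservation

cases <- estimate_cases(pop_h, sched)
summaries <- aggregate_cases(cases, thresholds = c(50L, 60L))
write_results_csv(list(case_strata = cases, prevalence_summaries = summaries),
                  "results/prevalence")

total <- region_case_total(summaries, 50L)
cat(sprintf("estimated %.0f persons with dementia (50+) across %d countries\n",
            total, nrow(summaries)))
top <- rank_countries(summaries, "prev_60plus")
cat("highest 60+ prevalence:\n")
print(head(top[, c("rank", "country", "prev_60plus")], 3), row.names = FALSE)
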