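#!/usr/bin/env Rscript
# Stage 1: generate a synthetic 22-country input set (population pyramids,
# prevalence schedule, economics with realistic missingness, direct-cost
# factors) and write it as the CSV files the rest of the workflow consumes.
# Seed 2021 (the study year) makes every downstream stage reproducible.

suppressPackageStartupMessages(library(coiburden))

out <- "results/inputs"
cfg <- synth_config(seed = 2021, n_countries = 22L)
inp <- generate_inputs(cfg)

write_population_csv(inp$population, file.path(out, "population.csv"))
write_prevalence_csv(inp$schedule, file.path(out, "prevalence.csv"))
write_economics_csv(inp$economics, file.path(out, "economics.csv"))
write_factors_csv(inp$factors, file.path(out, "factors.csv"))
# donor mappings for imputation (class-level values, the external-source analogue)
write.csv(data.frame(income_class = names(inp$truth$gdp_group_values),
                     gdp_pc_ppp = unname(inp$truth$gdp_group_values)),
          file.path(out, "gdp_group_values.csv"), row.names = FALSE)
write.csv(data.frame(income_class = names(inp$truth$wage_group_values),
                     monthly_wage = unname(inp$truth$wage_group_values)),
          file.path(out, "wage_group_values.csv"), row.names = FALSE)

n_miss_gdp <- sum(is.na(inp$economics$gdp_pc_ppp))
n_miss_wage <- sum(is.na(inp$economics$monthly_wage))
cat(sprintf("wrote %d-country synthetic inputs to %s\n", cfg$n_countries, out))
cat(sprintf("missing GDP per capita: %d countries; missing monthly wage: %d countries\n",
            n_miss_gdp, n_miss_wage))
cat(sprintf("total population: %.0f persons\n", sum(inp$population$population)))
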