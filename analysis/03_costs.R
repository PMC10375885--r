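#!/usr/bin/env Rscript
# Stage 3: economics imputation and cost models. Fills missing GDP per capita
# and wages from income-class donor values, prices direct care as a class
# factor times GDP per capita, and informal care under the bracketing
# best (1.6 h/day, 90% community) and worst (3.7 h/day, 99%) scenarios.

suppressPackageStartupMessages(library(coiburden))

summaries <- read.csv("results/prevalence/prevalence_summaries.csv")
econ <- read_economics_csv("results/inputs/economics.csv")
factors <- read_factors_csv("results/inputs/factors.csv")
gdp_don <- with(read.csv("results/inputs/gdp_group_values.csv"),
                setNames(gdp_pc_ppp, income_class))
wage_don <- with(read.csv("results/inputs/wage_group_values.csv"),
                 setNames(monthly_wage, income_class))

econ <- impute_gdp(econ, gdp_don)
econ <- impute_wage(econ, wage_don)
cat(sprintf("imputed GDP for %d and wages for %d of %d countries\n",
            sum(econ$imputed_gdp), sum(econ$imputed_wage), nrow(econ)))

costs <- compute_costs(summaries, econ, factors,
                       scenarios = default_scenarios(),
                       convention = wage_convention(),
                       case_threshold = 50L)
write_results_csv(list(costs = costs, economics_imputed = econ), "results/costs")

cat(sprintf("region direct cost: %.1f million USD/yr\n", sum(costs$direct_total) / 1e6))
cat(sprintf("region indirect cost: %.1f (best) to %.1f (worst) million USD/yr\n",
            sum(costs$indirect_best) / 1e6, sum(costs$indirect_worst) / 1e6))
cat(sprintf("worst/best indirect ratio per country: %.5f (identical for all)\n",
            costs$indirect_worst[1] / costs$indirect_best[1]))
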