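#!/usr/bin/env Rscript
# Stage 5: unlimited-treatment-duration scenario.
#
# Removes the one-year biologic treatment cap (adalimumab continues until
# loss of response or death) and recomputes the full comparison, writing
# the scenario results table under results/scenario_unlimited/.

suppressMessages(library(uccea))

params <- read_parameters("results/inputs/parameters_default.yaml")
table <- read_life_table("results/inputs/life_table_synthetic.csv")

capped <- run_basecase(params, table)
unlim <- run_scenario_unlimited(params, table)
dir.create("results/scenario_unlimited", recursive = TRUE, showWarnings = FALSE)
write_results_csv(unlim, "results/scenario_unlimited/scenario_results.csv")

cat("Unlimited biologic treatment vs one-year cap:\n")
cat(sprintf("  delta QALY: %.3f (capped %.3f)\n",
            unlim$cea$delta_qaly, capped$cea$delta_qaly))
cat(sprintf("  ICUR payer: %.0f EUR/QALY (capped %.0f)\n",
            unlim$cea$icur_payer_eur, capped$cea$icur_payer_eur))
cat(sprintf("  ICUR societal: %.0f EUR/QALY (capped %.0f)\n",
            unlim$cea$icur_social_eur, capped$cea$icur_social_eur))
cat("\nLonger treatment buys more health but at a higher price per QALY.\n")
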