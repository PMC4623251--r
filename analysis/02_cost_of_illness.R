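#!/usr/bin/env Rscript
# Step 2 — Cost of illness (direct costs) per strategy.
#
# Ingredients-based direct costing: prevention delivered to the whole
# high-risk cohort plus per-episode treatment costs at each clinical
# endpoint. Expected totals: US$74.5M (sub-optimal), US$71.8M (standard),
# US$96.8M (standard + temperature monitoring); indirect cost per premature
# death US$6,719 under the human-capital approach.

suppressPackageStartupMessages(library(footcea))
dir.create("results", showWarnings = FALSE)

ps <- peru_2012_fixture()

bundles <- load_cost_bundles()
cat("ingredient-bundle unit costs (US$):\n")
for (nm in names(bundles)) {
  cat(sprintf("  %-30s %8.2f\n", nm, unit_cost_from_bundle(bundles[[nm]])))
}

cat(sprintf("\nindirect cost per premature death: US$%s\n\n",
            round_half_up(indirect_cost_per_death(ps$economic))))

for (s in strategies()) {
  print(total_direct_cost(ps, s))
  cat("\n")
}

bundle <- render_reports(ps, "results", formats = c("csv", "json", "markdown"))
cat("wrote:", paste(basename(bundle$files), collapse = ", "), "\n")
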