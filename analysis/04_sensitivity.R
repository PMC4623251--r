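#!/usr/bin/env Rscript
# Step 4 — One-way sensitivity analysis (tornado diagrams).
#
# Each parameter with a published range is varied to its low and high bound
# (others at base) and the direct-cost ICER of the comparison is recomputed;
# entries are ordered by swing. Expected: the intervention's prevention cost
# dominates both tornados; for standard care the next-ranked parameters are
# its effectiveness, baseline ulcer prevalence and hospital utilization; for
# temperature monitoring, baseline prevalence and hospital utilization come
# before its effectiveness.

suppressPackageStartupMessages(library(footcea))
dir.create("results", showWarnings = FALSE)

ps <- peru_2012_fixture()

for (s in c("standard", "standard_plus_temp")) {
  tor <- run_owsa(ps, owsa_spec(s, "sub_optimal", outcome = "icer_direct"))
  cat(sprintf("\n== %s vs sub_optimal (icer_direct) ==\n", s))
  print(as.data.frame(tor)[c("parameter", "low_value", "high_value",
                             "outcome_at_low", "outcome_at_high", "swing")],
        digits = 6)
  csv <- sprintf("results/tornado_%s_vs_sub_optimal.csv", s)
  write.csv(as.data.frame(tor), csv, row.names = FALSE, na = "")
  png_file <- sprintf("results/tornado_%s_vs_sub_optimal.png", s)
  png(png_file, width = 900, height = 500)
  plot(tor, main = sprintf("%s vs sub-optimal care", s),
       xlab = "ICER, US$ per death averted (direct costs)")
  dev.off()
  cat("wrote", csv, "and", png_file, "\n")
}
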