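#!/usr/bin/env Rscript
# Longitudinal change report: per-feature means at each scan point, percent
# changes versus baseline and the previous scan, and scan-point t-tests;
# plus the cross-tissue baseline comparisons of ADC and the PK parameters.
# Requires results/features.csv from 01_simulate_cohort.R.

suppressPackageStartupMessages(library(deltarad))

features <- read.csv("results/features.csv", check.names = FALSE)
report <- longitudinal_report(features)
write.csv(report, "results/longitudinal_report.csv", row.names = FALSE)

show <- function(feat) {
  sub <- report[report$feature == feat, ]
  cat(sprintf("%-18s", feat))
  for (i in seq_len(nrow(sub)))
    cat(sprintf("  %s: %8.2f (%+6.2f%%)", sub$scan_point[i], sub$mean[i],
                sub$pct_change_vs_baseline[i]))
  cat("\n")
}
cat("Cohort means and percent change vs baseline:\n")
for (f in c("GTV_ADC_Mean", "NAT-PZ_ADC_Mean", "NAT-TZ_ADC_Mean",
            "GTV_DCE_kep", "GTV_DCE_ve"))
  show(f)

cat("\nCross-tissue baseline comparisons (pooled two-tailed t):\n")
for (f in c("ADC_Mean", "DCE_Ktrans", "DCE_kep", "DCE_ve")) {
  cmp <- compare_rois_at_scan(features, f, scan = "S1")
  cmp$feature <- f
  print(cmp, digits = 3)
  write.table(cmp, "results/baseline_comparisons.csv",
              append = f != "ADC_Mean", sep = ",", row.names = FALSE,
              col.names = f == "ADC_Mean")
}
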