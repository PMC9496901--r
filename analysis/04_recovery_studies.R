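#!/usr/bin/env Rscript
# Statistical guarantees of the pipeline itself:
#  - Tofts forward/fit round trip across the prostate parameter range,
#    noise-free and at 1% curve noise;
#  - end-to-end label-signal recovery on replicate synthetic cohorts with a
#    permuted-label negative control;
#  - null calibration of the two-sample t-test;
#  - cross-tissue baseline separation power at the anchored distributions.

suppressPackageStartupMessages(library(deltarad))
dir.create("results", showWarnings = FALSE)

st <- tofts_recovery_study(n_rep = 100, seed = 7)
cat(sprintf("Tofts recovery: noise-free max rel err %.3g%%; 1%%-noise median rel err %.2f%%\n",
            100 * max(st$noise_free$err_Ktrans, st$noise_free$err_kep),
            100 * median(c(st$noisy$err_Ktrans, st$noisy$err_kep))))
write.csv(st$noisy, "results/tofts_recovery_noisy.csv", row.names = FALSE)

rec <- signal_recovery_study(seeds = 1:10, verbose = TRUE)
cat(sprintf("signal recovery over %d cohorts: median AUC %.3f, ADC-feature recovery %.0f%%, permuted AUC %.2f\n",
            nrow(rec), median(rec$auc), 100 * mean(rec$adc_recovered),
            mean(rec$auc_perm)))
write.csv(rec, "results/signal_recovery.csv", row.names = FALSE)

cat(sprintf("t-test null rejection rate at alpha=0.05: %.3f\n",
            ttest_null_calibration(n_rep = 2000, seed = 11)))
cat(sprintf("baseline GTV vs NAT-PZ ADC power at p<0.005: %.3f\n",
            baseline_separation_power(n_rep = 200, seed = 2)))
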