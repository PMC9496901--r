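# deltarad

Longitudinal prostate mpMRI radiomics and Δ-radiomics outcome modeling.

## The problem

After definitive prostate radiotherapy, residual cancer can stay clinically
silent for years; biopsies at 2–2.5 years are the strongest early marker of
eventual failure, but they are invasive. Quantitative multiparametric MRI
(mpMRI) offers a noninvasive alternative: the apparent diffusion coefficient
(ADC) tracks tissue cellularity, and dynamic contrast-enhanced (DCE)
pharmacokinetics — the forward transfer constant K^trans (min⁻¹), the reflux
rate k_ep (min⁻¹), and the extravascular-extracellular fraction
v_e = K^trans/k_ep — track vascular permeability. `deltarad` implements, as a
tested R package plus a set of analysis drivers, the full workflow for
studying how those features evolve across serial scans (pre-treatment S1 and
three post-treatment points S2–S4) in five regions — tumor (GTV), 5 mm
peritumoral rings split by prostate zone (PT-PZ, PT-TZ), and
normally-appearing tissue in each zone (NAT-PZ, NAT-TZ) — and for predicting
endpoint-biopsy positivity from scan-point features and their pairwise
differences (Δ radiomics).

The modeling core, per comparison (S1..S4 and the six deltas): univariate
logistic screen (LRT p < 0.05) → Welch-t ranking → greedy decorrelation
(drop |Pearson r| > 0.85) down to ≤ 4 features → multivariate logistic
regression → leave-one-out ROC/AUC, confusion matrix, F1. The DCE side fits
the Extended Tofts model

    C_t(t) = v_p·C_p(t−t0) + K^trans ∫ C_p(u)·exp(−k_ep·(t−t0−u)) du

to ROI-averaged curves with the Parker population arterial input function.

Since patient imaging cannot be shipped, the package includes a synthetic
digital-phantom cohort generator (anchored to published tissue statistics)
whose biopsy labels are coupled to baseline tumor features through a known
logistic rule, so every stage — geometry, features, pharmacokinetics,
statistics, modeling — is validated end to end. See
`vignettes/methods.Rmd` for the models, parameter defaults and design
rationale.

## Worked example

```r
library(deltarad)

spec <- phantom_spec(seed = 8)              # one synthetic patient scan
ph   <- generate_phantom(spec)              # ADC + 4-D DCE + masks
rois <- derive_rois(ph$masks$prostate, ph$masks$pz, ph$masks$gtv,
                    spec$spacing_mm)
print(rois)
#> <roi_set> voxel counts:
#>    gtv  pt_pz  pt_tz nat_pz nat_tz
#>    225    329    315   1328   3171

fv <- extract_scan_features(ph$adc, ph$dce, ph$masks, default_config(),
                            n_baseline = ph$truth$n_baseline)
round(fv[c("GTV_ADC_Mean", "NAT-PZ_ADC_Mean", "GTV_DCE_Ktrans",
           "GTV_DCE_kep", "GTV_DCE_ve")], 3)
#>    GTV_ADC_Mean NAT-PZ_ADC_Mean  GTV_DCE_Ktrans     GTV_DCE_kep      GTV_DCE_ve
#>        1166.264        1621.787           0.120           0.471           0.256

fit_tofts(roi_curve(ph$dce, rois$gtv, n_baseline = ph$truth$n_baseline))
#> <tofts_fit> Ktrans=0.1204 /min, kep=0.4713 /min, ve=0.256, vp=0.019,
#>             t_onset=19.7 s (rss=0.00265, converged=TRUE)
```

The tumor ADC mean (~1166 ×1e-6 mm²/s) sits at the generator's tumor
anchor, far below normal peripheral-zone tissue (~1622); the fitted
pharmacokinetics recover the generating values (K^trans 0.12 min⁻¹,
v_e 0.255) from the noisy ROI curve to well under a percent on K^trans.

## The analysis workflow

Numbered drivers under `analysis/` run the study over a 25-patient,
4-scan synthetic cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # features.csv, labels.csv, truth.json
Rscript analysis/02_longitudinal_changes.R # longitudinal_report.csv + printed table
Rscript analysis/03_outcome_models.R       # model_*.json, roc_*.csv, model_summary.csv
Rscript analysis/04_recovery_studies.R     # parameter- and signal-recovery studies
```

On the default seed, `02` prints per-scan cohort means with percent change
versus baseline — tumor ADC +16.1% at S2 and +25.8% at S3 while NAT-PZ ADC
falls by 11.2%, and tumor k_ep roughly halves post-treatment, the
longitudinal pattern the generator is anchored to. `03` prints one line per
comparison; the baseline (S1) model comes out at

```
S1     n=25 AUC=0.980 F1=0.800 features=[GTV_ADC_90, GTV_DCE_ve, GTV_DCE_kep]
```

i.e. the selection recovers the tumor-ADC and tumor-v_e axes the labels were
generated from (GTV_ADC_90 is an r > 0.85 stand-in for the ADC mean, and
k_ep = K^trans/v_e rides along with v_e).

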