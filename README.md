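# ctradiomics

High-throughput 3D radiomics for lung-nodule CT, for imaging scientists
who want a tested, reproducible path from *image + contour* to *diagnostic
signature*. Given a CT volume and an expert-drawn binary region of
interest (ROI) per nodule, the package extracts a fixed inventory of 750
quantitative features and builds a small benign/malignant signature with
the classical statistical pipeline: quantile normalization, Wilcoxon
rank-sum screening, and sequential forward selection (SFS) wrapped around
a support vector machine (SVM) under leave-one-out cross-validation
(LOOCV). A synthetic nodule-phantom generator makes the whole workflow
testable without patient data.

## The method

**Feature extraction.** Each ROI is summarised by nine feature blocks
(750 features in the default configuration):

* *Intensity & shape* (33): a 16-statistic summary of the raw in-mask
  intensities (min, max, median, peak, mean, SD, CV, RMS, skewness,
  kurtosis, energy, entropy, uniformity, range, plus a 32-level
  co-occurrence contrast/homogeneity pair), 10 intensity–volume-histogram
  features (I10–I90, V10–V90, the imaging analogue of a DVH), and 7 mask
  morphology features (volume, surface area, sphericity, ...).
* *Filter banks*: the same 16 statistics applied to the in-mask response
  of 27 separable **Laws** texture-energy kernels
  (L3 = (1,2,1), E3 = (−1,0,1), S3 = (−1,2,−1); 432 features), 8 one-level
  3D **Haar wavelet** subbands (128), and 6 **Laplacian-of-Gaussian**
  scales at σ = 1–6 mm (96).
* *Matrix features*: 26 Haralick-style descriptors of the gray-level
  co-occurrence matrix P(i,j) (256 levels, 13 directions, distance 1),
  11 run-length, 11 size-zone, 5 neighbourhood gray-tone difference and
  8 box-counting fractal-dimension features.

**Signature building.** With features as columns of a cases × 750 table,

1. quantile normalization makes every case's feature distribution
   identical (rank-preserving, ties averaged);
2. a two-sided Wilcoxon rank-sum test per feature keeps those with
   p < 0.05 (no multiple-testing correction), ranked by significance;
3. greedy SFS adds, at each step, the screened feature maximising the
   LOOCV accuracy of a linear SVM on the current set, stopping at k = 4;
4. the signature is evaluated by LOOCV accuracy, sensitivity and
   specificity (positive class: malignant), against two baselines — all
   screened features at once, and the mean accuracy of random 4-feature
   subsets (1000 draws).

## Worked example

Simulate a 16-nodule phantom cohort whose malignant-like class carries
extra regional texture heterogeneity, extract all 750 features, and run
the statistical pipeline:

```r
library(ctradiomics)

ben <- phantom_spec("benign",    diameter_mm = 10, spacing_mm = c(1.5, 1.5, 1.5),
                    noise_sd = 8)
mal <- phantom_spec("malignant", diameter_mm = 10, spacing_mm = c(1.5, 1.5, 1.5),
                    noise_sd = 8, heterogeneity_amp = 20)

manifest <- run_simulate(8, 8, tempfile("cohort"), ben, mal,
                         master_seed = 42, quiet = TRUE)
tbl    <- run_extract(manifest, quiet = TRUE)   # 16 x 752 tibble
report <- run_analyze(tbl, config = radiomics_config(n_perm = 200),
                      seed = 1, quiet = TRUE)
report
#> <radiomics_report>
#>   screened features : 146
#>   signature         : Laws_EES_sd, Laws_EEE_rms, Laws_LSE_range, Laws_ELE_entropy
#>   signature LOOCV   : 93.8% acc / 87.50% sens / 100.00% spec
#>   all-features acc  : 81.2%
#>   random mean acc   : 82.3% (200 draws)
```

146 of 750 features pass the screen; forward selection picks four Laws
texture features (the heterogeneity the phantoms plant is spot/edge
micro-structure, which is exactly what the Laws bank detects), and the
4-feature signature classifies 15 of 16 nodules correctly under LOOCV,
ahead of both baselines. `tidy(report$signature)` gives the per-step
accuracies, `glance(report$evaluation)` the confusion counts, and
`autoplot(report$heatmap)` the clustered z-score heatmap of the signature.

A thin command-line wrapper around the same functions ships in
`inst/cli/ctradiomics.R` with `simulate`, `extract` and `analyze`
subcommands.

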