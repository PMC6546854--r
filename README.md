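# rsmvpa

Multi-voxel pattern analysis (MVPA) of resting-state BOLD fMRI for paired
two-condition designs — for example classifying a subject's metabolic state
(hunger vs. satiety) from a single resting-state scan.

The package implements the full analysis chain:

1. **Voxel-wise feature maps** from a 4D BOLD run:
   - **ReHo** (regional homogeneity): Kendall's coefficient of concordance of
     a voxel's time series with its 26 neighbours,
     `W = (Σᵢ Rᵢ² − n R̄²) / ((1/12) K² (n³ − n))`, with `K = 27` voxels per
     cluster and `n` time points;
   - **DC** (degree centrality): the number of other voxels whose Pearson
     correlation with the voxel's series is at or above a threshold
     (`r ≥ 0.25`);
   - **fALFF** (fractional amplitude of low-frequency fluctuations): the
     amplitude spectrum summed over 0.01–0.08 Hz divided by the amplitude
     over the full band (0, Nyquist].
   Temporal band-pass (ideal spectral mask, 0.01–0.08 Hz) and spatial
   Gaussian smoothing (6 mm FWHM) are applied in the per-feature order:
   ReHo = band-pass → map → smooth the map; DC = smooth the run → band-pass →
   map; fALFF = smooth the run → map with no band-pass.
2. **Region vectors**: atlas means of each map (90 regions in the study
   preset, the cerebellum-free anatomical atlas ordering in
   `aal_region_table()`), giving a samples × regions feature table.
3. **Wrapper region selection**: sequential forward selection (`sfs()`) and
   sequential forward *floating* selection (`sffs()`, with conditional
   exclusion of previously selected regions), both driven by the
   leave-one-out cross-validated misclassification rate of a linear
   soft-margin SVM (`criterion_loocv_error()`), plus a brute-force
   `exhaustive_selection()` reference.
4. **Evaluation and inference**: LOOCV confusion matrix (`loocv_confusion()`),
   accuracy/sensitivity/specificity/error-rate metrics
   (`classification_metrics()`), and a label-permutation test
   (`permutation_test()`) with within-subject pair swaps and
   `p = (1 + #{null ≤ observed}) / (1 + n_perm)`.
5. **Synthetic cohorts**: `simulate_bold_cohort()` generates paired BOLD runs
   with band-limited latent signals and known, calibrated condition effects
   targeting fALFF, ReHo or DC; `simulate_feature_table()` generates region
   tables directly. Every generator is bit-reproducible from its seed, so the
   whole pipeline is testable without scanner data.

The LOOCV inner loop (an SMO solver for the linear C-SVC, reproducing
libsvm's predictions) is compiled code, because wrapper selection and
permutation testing evaluate it millions of times.

## Worked example

```r
library(rsmvpa)

# a paired cohort on the region-vector scale: 24 subjects x 90 regions,
# 5 informative regions with a strong condition effect
ft <- simulate_feature_table(n_subjects = 24, n_regions = 90,
                             informative_regions = c(5, 17, 35, 50, 73),
                             effect_size = 2.5, seed = 208)
ft$table
#> feature_table: 48 samples x 90 regions (hunger vs satiety, 24 subjects, paired)

sel <- sffs(ft$table, max_k = 10)
sel
#> SFFS selection (max_k = 10, sample folds): 891 criterion evaluations
#> final subset (LOOCV error 0.0208): R[5,21]

cm <- loocv_confusion(ft$table, sel$final_subset)
classification_metrics(cm)
#> CA 98%  Sen 100%  Spe 96%  ER 0.02  (n = 48)

permutation_test(ft$table, subset = sel$final_subset, n_perm = 999, seed = 2)
#> permutation test (post_selection, within_subject swaps, 999 permutations, seed 2)
#> observed ER = 0.0208, null mean = 0.5865, p = 0.001
```

Reading the output: the floating search found a two-region subset whose
leave-one-out error is 1/48; the confusion matrix counts hunger scans
classified as hunger (TP = 24) against the reference labels; CA/Sen/Spe are
display-rounded percentages and ER is the raw error rate. The permutation
p-value compares the observed error against 999 within-subject label swaps —
note that the selected subset mixes a true region (5) with a lucky noise
region (21), the selection optimism that makes permutation inference
necessary. Note also that the null error mean sits above 0.5: under
leave-one-out the training-fold majority always opposes the held-out sample,
so a no-information classifier errs more than half the time.

The full volume-level pipeline runs from one configuration object:

```r
report <- run_pipeline(pipeline_config(n_subjects = 8, n_timepoints = 64,
                                       grid_shape = c(6, 6, 6), n_regions = 8,
                                       informative_regions = 2,
                                       effect_kind = "amplitude", effect_size = 2.5,
                                       features = "falff", strategy = "sffs",
                                       n_perm = 199, seed = 1,
                                       out_dir = "out"))
```

`pipeline_config(preset = "study2019")` encodes the emulated study's
conditions (24 subjects, 170 time points at TR = 2 s, 90 regions, threshold
0.25, 6 mm FWHM, 10,000 permutations). A thin command-line front end with
`simulate` / `extract` / `select` / `evaluate` / `permtest` / `run-all`
subcommands ships in `inst/cli/rsmvpa-pipeline.R`.

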