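---
title: "Resting-state MVPA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state MVPA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rsmvpa)
```

This vignette is the package's own account of the science it implements: the
three resting-state features, the wrapper selection and its cross-validated
criterion, the permutation test, the synthetic cohort generator, and the
design decisions taken where the method leaves room.

## The analysis in one paragraph

A paired two-condition resting-state study yields two BOLD runs per subject.
From each run, three voxel-wise feature maps are computed — regional
homogeneity (ReHo), degree centrality (DC) and the fractional amplitude of
low-frequency fluctuations (fALFF) — and averaged over an atlas parcellation
into a region vector. Stacking region vectors over scans gives a samples ×
regions table on which region subsets are selected by sequential forward
(floating) search wrapped around the leave-one-out cross-validated error of a
linear SVM; the selected subset's error is then referred to an empirical null
distribution built from label permutations.

## Feature definitions and numerical conventions

**ReHo.** For every masked voxel, Kendall's coefficient of concordance of the
3×3×3 cluster centred there:
$$W = \frac{\sum_{i=1}^{n} R_i^2 - n\bar R^2}{\tfrac{1}{12}K^2(n^3-n)},$$
where $r_{ij}$ is the rank of time point $i$ within voxel $j$'s series,
$R_i=\sum_j r_{ij}$, $K \le 27$ is the actual cluster size and $n$ the number
of time points. Conventions: average ranks for ties with no tie-correction
term (inputs where more than 10% of a series is tied are flagged with a
warning); clusters truncated at the mask or volume boundary use their actual
$K$ rather than being dropped, so the map's support equals the mask; masked
voxels with no in-mask neighbour ($K<2$) become NA with a warning; values are
clipped to $[0,1]$ only against floating-point overshoot ($\le 10^{-12}$).
Under the no-signal null, $E[W] \approx 1/K$; the tests verify the map's
interior mean against a Monte-Carlo oracle.

**DC.** Pearson correlations between all pairs of masked voxel series,
thresholded at $r \ge 0.25$; the degree written at a voxel counts connections
to *other* voxels (0..N−1). A literal reading of the defining sum
$D_i=\sum_{j=1}^{N}d_{ij}$ would include the self-connection $r_{ii}=1$ and
shift every degree by +1; we follow graph convention and exclude the
diagonal. Zero-variance voxels admit no correlation and are excluded from the
map's mask with a warning (their original handling in the historical toolbox
chain is undocumented). Under the null the mean degree is
$(N-1)\,P(r \ge 0.25)$ with the exact Pearson null tail, which the tests use
as an oracle.

**fALFF.** The amplitude spectrum (square root of the power spectrum) of the
demeaned series, with bin centres $k/(n\,\mathrm{TR})$ Hz; fALFF is the
amplitude summed over bins in the closed band $[0.01, 0.08]$ Hz divided by
the sum over the half-open band $(0, \text{Nyquist}]$. The zero-frequency bin
is excluded from both sums by default — demeaning makes it numerically ~0
anyway and exclusion keeps the ratio scale-free; a dialect flag
(`include_dc_bin`) restores it because historical toolboxes are not explicit
on this point. With 170 time points at TR = 2 s the numerator spans bins
4–27 and the denominator bins 1–85, so white noise sits near 24/85 ≈ 0.28.
An all-zero series yields 0 with a warning (0/0 guard).

**Band-pass and smoothing.** The temporal filter is an ideal spectral mask
(remove the mean, zero all Fourier bins with centre frequency outside the
band, invert) — it matches the frequency-domain feature definitions exactly
and is analytically checkable on on-bin sinusoids, unlike an IIR design.
Smoothing is a separable Gaussian with $\sigma =
\mathrm{FWHM}/(2\sqrt{2\ln 2})/\text{voxel size}$ per axis (study values:
6 mm at 3 mm voxels), renormalised at boundaries (and within the mask for
maps) so constants are preserved. The per-feature order mirrors the study's
preprocessing: ReHo is computed on band-passed, *unsmoothed* data and the
resulting map is smoothed; DC runs on smoothed, band-passed data; fALFF runs
on smoothed data with **no** band-pass, since the measure is itself a
band-ratio.

## The wrapper criterion and the classifier

The selection criterion is the leave-one-out misclassification rate of a
linear soft-margin SVM on the subset's columns. The study era leaves the
classifier's hyperparameters unstated, so they are explicit configuration
echoed into every report: penalty `C = 1` and per-feature z-scoring using
training-fold statistics (defaults of `svm_config()`). Folds are
leave-one-*sample*-out by default, matching the 48-fold confusion matrices
the design implies; because the held-out scan's paired twin remains in
training, a leave-one-*subject*-out mode (`folds = "subject"`) is provided
for leakage-free estimates.

The solver is an SMO coordinate ascent on the C-SVC dual with
maximal-violating-pair working-set selection and the conventional stopping
tolerance 1e-3, compiled because selection and permutation testing evaluate
the criterion millions of times; the test suite verifies its LOOCV
predictions are identical to libsvm's (via e1071) on random and separable
tables.

Two LOOCV artifacts are worth knowing. On a no-information feature with
balanced classes, the training-fold majority is always the class opposite to
the held-out sample, so the error is 1 (not 0.5); on noise tables the same
mechanism pushes the *null* error above 0.5 (≈0.65 at 48 samples). Neither
invalidates the permutation test, which compares the observed error to a null
built by the same estimator.

## SFS, SFFS and their bookkeeping

`sfs()` adds, at each step, the region minimising the criterion and stops
when no addition strictly improves it (tolerance 1e-12 — error rates are
multiples of 1/samples, so this only guards refactors) or at `max_k`.
`sffs()` is the floating variant: after each addition, conditional exclusion
repeatedly removes the member whose removal beats the best known subset of
the reduced size; the forward march continues to `max_k` and the final subset
is the best over all sizes encountered. Ties are broken by the smallest
region label, then the lexicographically smallest subset; both searches are
fully deterministic given the table. `max_k` defaults to 10 (reported subsets
in this literature have ≤5 regions); an evaluation budget of 10,000 criterion
calls bounds floating oscillation and is flagged in the trace if hit. The
final subset is the argmin over best-per-size with ties resolved towards
smaller subsets. These tie and termination rules are this package's
documented choices — the original MATLAB tooling's rules are not recoverable.

Why floating? Greedy forward selection suffers the *nesting effect*: an early
pick can block the better combination that excludes it.
`nesting_demo_table()` is a frozen 20×8 construction where region 5 is the
best singleton but regions {1, 2} jointly separate perfectly; plain SFS locks
onto 5 and stops at error 0.15 while SFFS discards it and reaches 0 —
verified against exhaustive search in the tests.

**Selection optimism.** With 90 candidate regions and 48 samples the wrapper
criterion is strongly optimistic: greedy steps find noise regions whose
chance complementarity drives the LOOCV error towards 0 (a winner's curse —
on pure-noise tables the selected criterion averages ≈0.27 against a true
error of 0.5). Consequences documented and tested here: selected subsets mix
true and lucky regions; recovery of a planted 5-region effect of d = 1.5 per
region succeeds only partially (~40% of seeds yield ≥3 true regions in the
final subset, and at large d the minimum-size tie rule returns 2 true regions
because two suffice for error 0); and post-selection permutation p-values on
the *same* data are anti-conservative, which a dedicated test asserts
empirically. The package therefore offers `mode = "full_pipeline"` in
`permutation_test()`, rerunning the selection inside every permutation, at
correspondingly higher cost.

## The permutation test

`permutation_test()` permutes condition labels within subject (pair swaps),
the exchangeability unit of the paired design; a free-permutation mode exists
behind a flag. The p-value is $(1 + \#\{\mathrm{ER}_{null} \le
\mathrm{ER}_{obs}\})/(1 + n_{perm})$, which avoids p = 0 and equals 1/10,000
at $n_{perm} = 9999$ when the observed error beats every permutation. With
10,000 permutations the default mode evaluates the fixed subset only
(post-selection); rerunning the full selection per permutation is available
at reduced $n_{perm}$, and the call refuses budgets it cannot honour.
Calibration is asserted on null data with a pre-fixed subset:
$P(p \le 0.05)$ over 200 datasets × 199 permutations falls in [0.01, 0.10]
(measured ≈0.02–0.05; the discreteness of error rates and ties make the test
slightly conservative).

## The synthetic cohort generator

Raw scans are not available, so the generator targets the statistical
structure the features measure rather than scanner realism. Per run, each
region has a latent low-frequency signal — a sum of 3 sinusoids (count
configurable) with frequencies drawn uniformly in 0.01–0.08 Hz and random
phases, standardized to unit variance — shared by the region's voxels with
coupling weight `coupling` plus white voxel noise (`noise_sd`, default 1).
The condition modulates, in informative regions only, the parameter matching
the targeted feature: the latent amplitude (fALFF), the voxel-latent coupling
(ReHo), or the weight of a run-wide shared component (DC; all regions carry a
baseline weight 0.4 so the correlation graph is non-trivial). A log-normal
gain shared by a subject's two runs induces the within-subject correlation
(`subject_rho`, default 0.5, matching the paired design; run-level log-sd
0.1, subject-level log-sd scaled by $\sqrt{\rho/(1-\rho)}$).

**Effect calibration.** The requested `effect_size` is a Cohen's d on the
region-mean feature scale, but the mapping from a physical modulation (say,
an amplitude multiplier) to a feature shift is nonlinear. The generator
therefore calibrates by pilot simulation: it simulates single-region
surrogates (27 voxels; for DC, with a background pool of latent-coupled
voxels) over a multiplier grid, estimates the standardized feature shift at
each point, and interpolates monotonically to the requested d — warning if d
is unreachable (fALFF saturates at 1). The tests verify the amplitude kind
realizes d = 2.0 within ±0.3 at 200 subjects; the coherence and coupling
kinds are verified directionally (the surrogate for DC subsamples the
background, so their realized d is approximate). Unreachable or approximate
calibration is a property of the feature scale, not of the search.

`simulate_feature_table()` bypasses the volume level entirely: unit marginal
variance per region, a subject random effect of variance `subject_rho`, and a
±d/2 condition shift in informative regions, so the realized d is exact by
construction. It is the workhorse for selection and inference tests.

What the generator does *not* emulate: head motion, physiological noise,
scanner drift, spatial autocorrelation of noise, anatomical geometry, or any
of the upstream preprocessing chain (ICA denoising, realignment,
normalization). Passing tests therefore certify the pipeline's statistical
machinery, not robustness to real-scanner artifacts.

The toy parcellation partitions a rectangular grid into equal rectangular
blocks (≥3 voxels per side so every region hosts a full 3×3×3 cluster); the
study preset uses an 18×15×9 grid split into 90 such blocks carrying the
90-region atlas names. Region geometry is deliberately not the object of
study; only the map→region aggregation is.

## Pipeline, formats, reproducibility

`run_pipeline()` executes simulate → extract (per-feature order) → select →
evaluate → permutation test from a single `pipeline_config()`; the
`"study2019"` preset encodes the emulated study's conditions (24 subjects,
170 time points at TR = 2 s, 90 regions, r-threshold 0.25, bands
0.01–0.08 Hz / 0–0.25 Hz, 6 mm FWHM, 10,000 permutations). Volumes are
NIfTI (RNifti, double precision; TR in the fourth pixdim), feature tables are
TSV with full-precision values (exact round trip), traces and reports are
JSON. Every report embeds the package version, the full configuration
(minus the output path) and all seeds, and reruns with identical
configuration are byte-identical; all randomness flows from the single master
seed through isolated RNG scopes, so generators never perturb the caller's
RNG state. Stage logging (one line per stage with elapsed time and an md5
content hash) is available behind `verbose`.

## Problem sizes used by the test suite

The suite exercises the study-sized table dimensions (48 × 90) for selection
and recovery, volume grids of 6×6×6–22×22×22 voxels with 32–170 time points
for the feature maps, 1,000 random instances for the Kendall-W oracle, 50
random tables against exhaustive search, 25 seeds for recovery, and 200
datasets × 199 permutations for calibration — sizes chosen so each
property is measured with meaningful Monte-Carlo resolution while the whole
suite remains a routine single-machine run.

## Known limitations

- Sample-level LOOCV leaks paired-subject information into training; the
  subject-level fold mode avoids this but halves the effective fold count.
- Post-selection permutation on the same data is anti-conservative (tested,
  documented above); unbiased inference needs `full_pipeline` mode or an
  outer validation split.
- The SMO solver covers the linear kernel only — nonlinear kernels,
  probability outputs and multi-class problems are out of scope, as are
  eigenvector centrality, weighted-degree variants, non-fractional ALFF and
  surface-based analysis.
- The generator's calibration targets region-mean features; voxel-level
  effect sizes are not controlled.
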