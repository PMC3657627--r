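---
title: "Selecting resting-state network components from a spatial ICA decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting resting-state network components from a spatial ICA decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnselect)
```

## The problem

Spatial independent component analysis (ICA) of resting-state fMRI
decomposes the space-time data matrix as `X = A S + E`: `A` is the
`N x K` mixing matrix of component time courses, `S` the `K x M` matrix
of spatial maps over the `M` in-brain voxels, and `E` Gaussian noise.
Only a fraction of the `K` components are resting-state networks (RSNs);
the rest reflect scanner instability, head motion, cardiac and
respiratory pulsation, and residual Gaussian noise. Picking the RSN
components by eye is slow and subjective. `rsnselect` implements a
fully automatic four-step selection that uses three complementary
properties of RSN components: their spatial maps are strongly *skewed*
(localised activation on a symmetric background), their activation is in
*gray matter*, and their time courses fluctuate *slowly*, between 0.01
and 0.1 Hz.

## The four steps

**Step 1 — skewness filter (on components).** For each row of `S` the
package computes Pearson's median skewness coefficient,

\[ \mathrm{PC} = 3\,(\mathrm{mean} - \mathrm{median})/\sigma , \]

with \(\sigma\) the sample (n−1) standard deviation. Gaussian-noise maps
are symmetric, so their coefficient is near 0; network maps are strongly
skewed. A component is rejected when its coefficient is *strictly below*
a subject-specific threshold TH, the median of the per-component
coefficients. Exact ties survive, which makes the `K = 1` and
all-identical-rows cases non-destructive. Two points here were genuinely
open and are settled as package conventions:

* *TH is the median over the `K` per-row coefficients.* A "per-element"
  Pearson index is undefined; the row statistic is the only coherent
  reading.
* *Coefficients are compared in absolute value by default*
  (`skewness_mode = "absolute"`). The noise criterion — "coefficient
  close to 0" — is a magnitude statement, and the absolute mode avoids
  discarding strongly left-skewed maps (a network map estimated with the
  opposite sign, which ICA cannot fix). `"signed"` mode is available.

Note that a median threshold always rejects about half the components —
that is the design: it adapts TH to each subject's decomposition rather
than fixing a universal cutoff. Zero-variance rows get coefficient 0
(maximally noise-like).

**Step 2 — k-means voxel filter (on maps).** Each surviving component's
retained voxel values are clustered by one-dimensional k-means on the
activation values (no spatial structure is used). The number of clusters
is chosen by maximising the mean silhouette index

\[ \mathrm{SH}_j = (b_j - a_j)/\max(a_j, b_j) \]

over a candidate range of `k` (default `2:9`; 1-D problems saturate the
silhouette quickly), where \(a_j\) is the point's mean distance to its
own cluster and \(b_j\) the smallest mean distance to another cluster;
singleton clusters score 0 and ties go to the smaller `k`. The voxels of
the single cluster whose centroid is nearest to 0 — the
lowest-activation voxels — are then removed. Numerical choices:

* k-means is `stats::kmeans` with 10 restarts, 300 iterations maximum,
  run under a fixed seed (`kmeans_seed`, default 0) so the whole step is
  bit-reproducible.
* the mean silhouette is computed exactly, in `O(n log n)` per cluster
  via sorted prefix sums, for up to `silhouette_subsample` points
  (default 5000); above that cap a deterministic subsample of points is
  scored (each scored point's \(a\) and \(b\) still use *all* points).
* components whose values are degenerate (fewer distinct values than any
  candidate `k`, or range below 1e-12) cannot be clustered and are
  demoted to `rejected_empty` rather than aborting the run.

**Step 3 — tissue filter (on maps).** Voxels with at least 90%
probability (`tissue_prob_threshold`) of being white matter *or* CSF are
cancelled, restricting components to gray matter and suppressing
pulsation effects. The threshold is applied to each tissue map
separately (`tissue_rule = "either_map"`), the natural reading of
"probability of belonging to the white matter or cerebrospinal fluid";
a `"summed"` rule (WM + CSF ≥ threshold) is provided as an option. The
package consumes tissue probability maps (e.g. from SPM segmentation,
resampled to the functional grid); it does not compute them.

**Step 4 — spectral filter (on components).** For every retained voxel
`m` of component `i`, the voxel time course `A[, i] * S[i, m]` is
baseline-corrected (demeaned) and detrended (polynomial degree
`detrend_degree`, default linear), then the courses are averaged. The
raw, unwindowed periodogram of the mean course is split into three
bands: `P1` below `f1 = 0.01` Hz, `P2` in `[0.01, 0.1)` Hz — where RSN
fluctuations concentrate — and `P3` from `f2 = 0.1` Hz to Nyquist
`1/(2 TR)`. A component is rejected when `P2 < 50%` *or*
`P1 + P2 < 90%`; survivors are the selected RSNs. Conventions:

* bins belong to bands by their centre frequency `k/(N TR)`; the DC bin
  is excluded from all bands and from the total (the series is demeaned,
  so it carries no fluctuation information), making `P1 + P2 + P3 = 1`.
* the integration upper bound is Nyquist — the only physically
  meaningful choice for a sampled series.
* OR-logic for the two criteria is the stricter reading of the rejection
  rule and matches the precedent of removing components with ≥ 50%
  high-frequency power; `reject_logic = "and"` is available.
* averaging signed source values can cancel; the package warns when
  `|mean(s)| < 1e-3 mean(|s|)` and proceeds literally. Detrending is
  applied per voxel before averaging, as specified; for these linear
  operations the order is mathematically immaterial.
* a zero-power mean course has no defined spectrum; such components are
  demoted to `rejected_spectral` with a logged reason.

One upstream question is deliberately left to the caller: whether `S`
has been thresholded (e.g. by posterior probability) before selection.
The package accepts raw maps; upstream thresholding is the caller's
choice.

## Evaluation

Against a reference labelling (expert-identified RSNs), the package
counts true/false positives/negatives over the `K` components and
reports

\[ \mathrm{Accuracy} = \frac{TP + TN}{TP + TN + FP + FN}, \qquad
   \mathrm{Precision} = \frac{TP}{TP + FP}. \]

Percentages are available at full precision and rounded to integer
percent. For cross-session reproducibility the package offers greedy
one-to-one matching of component maps by descending spatial correlation
(`match_sessions`, default threshold r = 0.4). This is an *objective
surrogate* for expert session comparison: it makes no claim to reproduce
expert-judged network-presence percentages, which depend on restricted
data and human labels.

## The synthetic decomposition generator

Real decompositions require scanner data and an ICA run, and ICA output
varies between runs. The generator therefore builds `(A, S)` directly,
with ground-truth classes designed to exercise each filter:

* **tissue phantom**: a spherical head with a smooth WM core, GM shell,
  and two ventricle blobs of CSF probability 0.96; probabilities sum to
  at most 1 per voxel. The brain mask is the sphere (about 3100 voxels
  at the default 20³ grid).
* **network components** (default 3): 2–3 Gaussian-enveloped blobs of
  radius 4 voxels of positive folded-Gaussian activation, centred on the
  GM shell, over a symmetric unit-SD background; time courses are
  synthesised on Fourier bins inside [0.012, 0.095] Hz with a 2%
  broadband admixture, i.e. about 98% of power in the RSN band.
* **Gaussian-noise components** (default 7): symmetric unit-SD maps and
  white time courses.
* **CSF components** (default 2): activation confined to ventricle
  voxels (CSF ≥ 0.9) and time courses on bins in (0.105 Hz, 0.96 ×
  Nyquist], mimicking pulsation.

Defaults mirror a typical single-subject resting-state acquisition
(N = 197 volumes, TR = 2 s). The blob geometry and activation scale 12
were chosen so the classes express the contrast the method assumes at
this coarse grid: every network map's skewness coefficient exceeds 0.5
while noise maps stay near 0 (|PC| < 0.1 for ≈ 99% of draws — the
sampling SD of the coefficient at M ≈ 3100 voxels is ≈ 0.04, so
occasional excursions to ≈ 0.12 are expected and correct). Activated
voxels cover roughly 10–25% of the brain mask, comparable to large RSNs
at this resolution. `mix_to_4d` reconstructs `X = A S + E` when a
voxel-level 4-D volume is needed.

What the generator does *not* emulate: hemodynamic response shape, head
motion, EPI distortion, spatial autocorrelation of noise, between-run
ICA instability, and partial-volume mixtures of signal classes. Passing
tests on these fixtures therefore demonstrate the *selection logic* —
not performance on real scanner data, where class contrasts are weaker
and labels are human judgements.

## Worked example

```{r example}
fix <- make_decomposition(seed = 7)           # 3 networks + 7 noise + 2 CSF
res <- suppressMessages(run_pipeline(fix$decomposition, fix$tissue))
res
sort(fix$truth$network_indices)

cm <- confusion(res$selected_indices, fix$truth$network_indices,
                res$counts[["K"]])
accuracy(cm)
precision(cm)
```

The report retains all `K` components with the stage at which each was
rejected — false positives merely cost reviewer time, while false
negatives lose signal irrecoverably, so the audit trail matters:

```{r report}
res$report$components[, c("index", "pearson_coefficient", "p2",
                          "status", "rejection_stage")]
```

## Problem sizes and runtime

The default fixture (20³ grid, ≈ 3100 brain voxels, K = 12, N = 197)
runs the full pipeline in about a second; the package's Monte-Carlo
checks use 20–50 generator seeds, chosen as the smallest replication
that stabilises the recovery rates they estimate. Exact silhouette
computation is the dominant cost at realistic voxel counts, which is why
the `O(n log n)` formulation and the subsample cap exist.

## Known limitations

* The median-based TH always rejects about half the components; on
  decompositions where most components are genuine networks this is too
  aggressive, and a fixed `skewness_threshold_override` is the remedy.
* Step 2 clusters on activation values only; spatially scattered voxels
  with similar values are kept or removed together.
* Band fractions use a rectangular-window periodogram: a sinusoid within
  ≈ 0.005 Hz of a band edge leaks a percent-level fraction of its power
  into the adjacent band. The thresholds (50% / 90%) are far from this
  regime.
* Components are processed per subject; multi-subject use is a loop with
  independent reports, not a group model.
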