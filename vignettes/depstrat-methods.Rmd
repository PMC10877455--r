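---
title: "Criteria-stratified case-control analysis of brain measures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Criteria-stratified case-control analysis of brain measures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

How much of what a case-control neuroimaging study "finds" about
depression depends on how depression was defined? Large biobank cohorts
offer several coexisting operational criteria for lifetime depression —
help-seeking, self-report, antidepressant use, the broad Smith-style
symptom definition, hospital ICD-10 F32/F33 codes, and a CIDI-SF screen —
and studies mix them freely. `depstrat` implements a two-stage analysis
that makes the definition itself the object of study:

1. **Stage 1 — where.** Cases are stratified by the *exact* number k of
   criteria met (the six strata are disjoint, unlike "at least k"
   definitions). For each stratum, modality (fALFF, LCOR, GCOR, voxel-wise
   GMV) and direction, a covariate-adjusted voxel-wise two-sample test with
   cluster-level family-wise error control yields a binary significance
   mask — up to 12 masks (6 strata × 2 directions) per measure, and
   2 × 6 × 4 = 48 tests per control strategy.
2. **Stage 2 — how much, and which criterion.** Per-subject mean values
   inside each mask give Cohen's d for every criteria constellation (the
   63 non-empty subsets of the 6 criteria) versus one common control pool,
   after excluding constellations with fewer than 10 members. The
   *difference in effect size* for a criterion on a mask is the unweighted
   mean d over retained constellations containing the criterion minus the
   mean over those lacking it; six values per mask, summarised per
   modality as median [IQR] across masks.

Because the motivating cohort data cannot be redistributed, the package
ships a synthetic-cohort generator whose planted, criterion-linked effects
make every stage testable end-to-end.

## Imaging measures

All measures operate on a shared `volume_grid` (shape, voxel size,
analysis mask).

* **fALFF** — per voxel, the fraction of spectral content of the detrended
  BOLD series falling in the 0.008–0.09 Hz band, relative to the full
  positive-frequency spectrum; values in [0, 1]. Band-edge membership is
  inclusive on both edges by bin centre, for determinism. The default uses
  the **power** spectrum: after removing a linear trend the residual ramp
  of a finite series leaks broadly across the *amplitude* spectrum (a pure
  in-band tone retains only ~0.79 of its summed amplitude in band, versus
  ~0.98 of its power), so the power ratio is the convention under which
  "an in-band tone scores ≈ 1" actually holds on unwindowed data. The
  classical amplitude convention is available via `spectrum = "amplitude"`.
* **LCOR** — Gaussian-weighted mean Pearson correlation between a voxel
  and its neighbours (self excluded). The weighting kernel FWHM defaults
  to 25 mm; this is a package default, not a community-fixed value, and is
  exposed as a parameter. Implemented exactly in O(V·T) by convolving the
  unit-normalised series, with the explicit neighbourhood loop retained in
  the tests as the oracle.
* **GCOR** — mean correlation of each voxel with all other in-mask voxels,
  computed by the mean-signal identity gcor(v) = (z_v·Σz_u − 1)/(V − 1) on
  unit-norm series; the O(V²) brute force is the test oracle. Constant
  series correlate 0 by convention (flagged).
* **GMV** — relative GMV is total gray matter (voxel volume × sum) over
  TIV; voxel-wise analysis uses the smoothed gray-matter maps with TIV as
  a covariate, so the scalar is reported but not the test target.
* **Smoothing** — mask-aware Gaussian smoothing (kernel renormalised over
  in-mask voxels; sigma = FWHM/2√(2 ln 2) per axis, truncated at 4 sigma).
  A constant image is reproduced exactly; the global sum is preserved only
  up to boundary renormalisation, which matters on small synthetic grids
  and is why the mask-aware form was chosen over zero-padding.

## Stage-1 inference

Per contrast, measures of stratum cases and controls are residualized
against [1, age, age², sex, TIV] fitted on the combined subsample — the
group indicator is *not* in the nuisance design. Welch t statistics with
Satterthwaite degrees of freedom are computed per voxel (sign: case minus
control), thresholded at one-sided p < .001, and grouped by
26-connectivity (18 and 6 are selectable).

Cluster-level FWE uses the permutation distribution of the **maximum
cluster extent**: group labels are permuted over the residualized data
(Freedman–Lane style — the nuisance fit is held fixed), the same
threshold-and-cluster rule is applied, and an observed cluster of size s
gets corrected p = (1 + #{perm max ≥ s})/(1 + n_perm). This is a
deliberate methodological substitution for random-field-theory cluster
p-values: permutation is exact under exchangeability at any grid size and
needs no smoothness estimation. The two directional tests of a contrast
share one permutation stream, as directional contrasts of one model
should. Because cluster extents are integers, ties make the test slightly
conservative; with 8-mm-smooth maps the realised family-wise
false-positive rate sits a little below the nominal .05 but inside the
binomial band checked by the calibration experiment (below).

## Stage-2 effect sizes and attribution

Cohen's d uses the pooled SD; 95% CIs come from a seeded percentile
bootstrap over subjects (1000 resamples by default), with an analytic
noncentral-t interval behind `ci_method = "noncentral_t"` — the choice is
exposed because reference figures of this kind rarely state their CI
method. Constellation effect sizes are always computed against the single
strategy-1 control pool; matched controls are a stage-1 control analysis
only. Constellations below 10 members are omitted (and logged), never
imputed.

Attribution averages constellation d values **unweighted**: the statistic
is defined over combinations, not subjects. A subject-count-weighted
variant exists behind `weighted = TRUE` for sensitivity analysis, and a
test asserts that the two genuinely differ, so the default cannot silently
drift. When a criterion is present in every retained constellation (or
absent from all), its delta is reported as `NA` — undefined, not
fabricated. The median [IQR] summary uses linear-interpolation quantiles
(R type 7).

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes,
not the biology of any real cohort:

* **Criteria.** A single latent severity z ~ N(0,1) per subject;
  criterion j fires when `loading·z + √(1−loading²)·e_j` exceeds the
  probit threshold of its marginal prevalence. Default prevalences
  (.50, .126, .113, .085, .043, .096) with loading 0.55 reproduce the
  qualitative shape of published criteria tables: a dominant help-seeking
  criterion, rarer clinical criteria, and exact-k group sizes that shrink
  monotonically with k. Cases are draws conditioned on k ≥ 1; controls are
  all-false.
* **Demographics.** Truncated-normal age in 45–80 (cases centred at 63.9,
  controls 65.0), education ~16.6 ± 3.8 y, female share .617 in cases and
  .447 in controls (the direction of imbalance in the motivating cohort),
  TIV conditional on sex.
* **Functional volumes.** White Gaussian voxel noise; inside each planted
  spherical region all voxels share an in-band sinusoid (0.045 Hz by
  default) with amplitude `baseline + Σ amp_c·bit_c`, floored at 0, with a
  subject-random phase. Negative per-criterion amplitudes therefore lower
  in-band power — a criterion-linked fALFF decrease. Structural volumes
  are a smooth gray-matter baseline plus additive criterion offsets.
* **Reproducibility.** Every subject's volumes are seeded by a stable
  polynomial hash of (global seed, subject id), so cohorts are
  bit-reproducible regardless of generation order.

What the generator does **not** emulate: hemodynamics, autocorrelated or
physiological noise, motion, registration error, spatially varying
smoothness, or realistic criteria co-occurrence beyond the single-factor
model. Passing tests therefore demonstrate that the *pipeline* recovers
what it is supposed to recover under its own assumptions — they are not
evidence about any real cohort.

## Calibration and recovery experiments

Two seeded experiments exercise the inferential machinery end-to-end; the
problem sizes are the package's desk-scale choices.

* **Null calibration** (`null_fwe_replicate`): 24³ grid, 60 + 60 subjects,
  8-mm-smooth pure-noise maps, unrelated covariates, 500 permutations.
  Over 200 replicates the share of cohorts with any surviving cluster is
  checked against the binomial 95% band around .05, separately per
  direction. Noise maps stand in for computed measure maps because
  calibration depends only on exchangeability of the per-subject maps.
* **Planted-effect recovery** (`recovery_replicate`, conditions in
  `recovery_config`): 16³ grid, 340 cases / 120 controls, flatter and more
  correlated criteria (loading 0.75) so that enough constellations clear
  the 10-member floor at this scale, and a −0.10 in-band amplitude per
  planted criterion (antidepressant use, ICD-10) in one sphere of radius
  3.5 voxels. The amplitude is deliberately moderate: with a very strong
  effect the significance masks dilate well past the planted sphere
  (smoothing halo) and the Dice overlap against the sphere degrades even
  though detection is perfect. The case count matters for a subtler
  reason: attribution can only separate a planted criterion from a
  correlated bystander if their retained-constellation membership
  patterns differ, and with too few retained constellations they can
  coincide exactly; 340 cases give enough coverage for strict separation
  (checked combinatorially at design stage). Each replicate is judged on
  (i) Dice > 0.5
  between the union of decrease masks and the sphere, (ii) |d| increasing
  with exact-k on every decrease mask, and (iii) the two planted criteria
  ranking most negative in attribution on every decrease mask; 18 of 20
  seeded replicates must pass.

## Numerical and design choices

* Matching (strategy 2) is greedy nearest-neighbour without replacement,
  exact on sex, Euclidean on z-scored age and education, in a seeded
  random case order. The algorithm is a transparency choice; an optimal
  assignment variant was considered and omitted because no assignment
  solver is among the package's dependencies and the matched analysis is
  a control analysis here.
* Constellations are encoded as bit masks with bit i = i-th criterion in
  the fixed order help-seeking, self-report, antidepressant use, Smith,
  ICD-10, CIDI-SF; enumeration is ordered by (popcount, value) so outputs
  are comparable across runs.
* Welch voxels with zero variance in both groups get t = 0 and a flag;
  constant time series get fALFF 0 and correlation 0, with warnings.
* The permutation p floor is 1/(n_perm + 1); configurations where the
  floor exceeds the cluster alpha are rejected at call time.
* All randomness flows from explicit seeds; `run_all()` writes a manifest
  with MD5 checksums, and re-running a config reproduces identical TSVs.

## Limitations

The permutation substitute for random-field-theory correction, the
power-spectrum fALFF default, the 25-mm LCOR kernel and the greedy matcher
are all documented choices where the field's tooling varies; each is
either parameterised or covered by a sensitivity variant. Effect sizes
from masks selected on the same data are circular in the usual way; the
design mitigates this by separating mask definition (strata) from
quantification (constellations), but the circularity is inherited from
the analysis being reproduced, not resolved here.
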