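---
title: "Methods: connectivity-based handedness and laterality analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity-based handedness and laterality analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handlat)
```

# Overview

`handlat` studies how the resting-state functional connectome of the
hand-motor system lateralizes with handedness. The pipeline runs, per
subject: band-pass filtering and motion censoring of a dense
(grayordinates × frames) surface time series; functional connectivity
density (gFCD) hub mapping over the thresholded dense connectome, with
hemisphere-scope (global / ipsilateral / contralateral) and sign
(positive / negative threshold) variants; seed-based connectivity of the
left- and right-hand motor ROIs; a handedness index and a vertex-wise
laterality index; interhemispheric asymmetry over homologous vertex
pairs; then a group layer of covariate residualization, t contrasts with
Benjamini–Hochberg FDR, effect sizes and overlap statistics, with a
stratified discovery/replication split.

This vignette documents the model and its assumptions, the parameters
that matter, the numerical conventions, the synthetic world used for
testing, and the design decisions taken where the analysis convention
was genuinely open. It states no empirical result that the test suite
or the acceptance script does not itself compute.

# The measures

## Functional connectivity density

For vertex $v$ with filtered, censored series $x_v(t)$,

$$\mathrm{count}(v) = \#\{u \neq v : r(x_v, x_u) > \theta\},
\qquad \mathrm{gFCD}(v) = \begin{cases}
\log \mathrm{count}(v) & \mathrm{count}(v) \ge 1\\
0 & \mathrm{count}(v) = 0
\end{cases}$$

with $\theta = 0.6$ by default, the conventional FCD threshold. The
convention only names "the logarithm"; base (natural / log10 / none) and
the zero rule are configuration, and raw counts are always retained so
any transform can be recomputed. A negative-threshold variant
($r < -\theta$) serves as a control: handedness effects should live in
the positive tail. Scope restriction to the same or the opposite
hemisphere partitions the edge set, so
$\mathrm{count}_{global} = \mathrm{count}_{ipsi} + \mathrm{count}_{contra}$
holds *exactly*, and the implementation is required to honor it
bit-for-bit — this is enforced at run time by
`fcd_scope_decomposition_check()` and in the acceptance suite.

Correlations are computed on standardized rows over retained frames
only; the chunked implementation computes each $r_{uv}$ as the same dot
product regardless of chunk size, so results are bit-identical across
chunk sizes and equal to the full correlation matrix. Zero-variance rows
are treated as $r = 0$ (count 0), not NaN, so a flat-lined vertex cannot
poison its neighbors.

## Handedness index

$$I_H = \frac{\mathrm{gFCD}(Ml) - \mathrm{gFCD}(Mr)}
             {\mathrm{gFCD}(Ml) + \mathrm{gFCD}(Mr)}$$

on ROI-mean gFCD, after grand-mean scaling (below). Positive $I_H$
means right-hand-area dominance; the sign convention is fixed so the
index correlates positively with a questionnaire handedness score whose
right pole is +100. The denominator guard is $\varepsilon = 10^{-9}$:
below it the index is NaN (undefined), never 0, and group statistics
drop NaNs with a count. The same $\varepsilon$ and NaN conventions
apply to every ratio in the package.

Grand-mean scaling multiplies each subject's value by
(grand mean / stratum mean) over sex × race strata. Because the factor
is a single per-subject scalar applied to the whole gFCD map, it cancels
in $I_H$ exactly; it is applied anyway because the recorded per-ROI gFCD
values (which do not cancel) are part of the report, and because the
convention calls for it. Vertex-wise maps are instead residualized by
ordinary least squares on the covariate table (FD, age, sex, race,
site/scanner), independently per group — mirroring the two distinct
adjustment conventions for the two uses.

## Laterality index

$$\Delta(v) = \frac{z_{Ml}(v) - z_{Mr}(v)}{|z_{Ml}(v)| + |z_{Mr}(v)|}
\in [-1, 1]$$

where $z$ is Fisher-transformed seed correlation, $z = \mathrm{atanh}(r)$
after clipping $|r| \le 1 - 10^{-7}$ (the convention does not address
$r = \pm 1$; clipping keeps $z$ finite and serializable). Whether the
ratio should use $r$ or $z$ is not decidable from the convention's
wording; it is computed on $z$ here, with $r$ available as a
configuration, and the two differ only by a monotone per-map transform.
ROI-level $\Delta$ is computed on ROI-*mean* $z$ values, not as the mean
of the vertex-wise map, matching the "average connectivity of the seed
in the ROI" phrasing; the two disagree when $z$ changes sign inside an
ROI. Seed vertices are not excluded from the target map (the averaged
ROI-correlation convention it emulates does not exclude them).

## Homologous pairing and asymmetry

Left-hemisphere coordinates are reflected in the left–right axis about
the bounding-box center and matched to the nearest right-hemisphere
vertex, one-to-one, by greedy ascending-residual assignment with ties
broken by lower vertex index. The convention describes coordinate
correspondence but no algorithm; greedy nearest-neighbor is
deterministic, order-independent, and exact on mirror-symmetric
surfaces. The pairing quality statistic is the Pearson correlation of
mirrored-left vs matched-right coordinates pooled over the three axes;
on synthetic spaces with sub-spacing jitter it recovers every true
mirror twin and the correlation exceeds 0.995, the printed bound of the
reference analysis. For real fs_LR-registered data the conventional
reflection center is (180, 218, 180) mm; for synthetic spaces the actual
bounding-box center is computed. Asymmetry maps are
$\mathrm{value}(right) - \mathrm{value}(left)$ per pair, so positive
means rightward.

ROI membership uses Euclidean distance on the supplied
midthickness-style coordinates, not geodesic distance: the convention
names a 10-mm radius without a metric, Euclidean balls are the common
reading of the tool call it emulates, and at 10 mm on a smooth surface
the two differ little. The metric is an explicit argument so a geodesic
implementation can slot in.

## Group statistics

Vertex-wise contrasts use the pooled-variance (Student) two-sample t,
two-sided, with per-vertex NaN dropping and df adjustment — pooled
rather than Welch because the reference design matches groups and
reports a single df convention; Welch is a configuration away
(`roi_group_model` covariates aside, the maps are pre-residualized).
FDR control is Benjamini–Hochberg step-up (the convention says only
"FDR"); a Benjamini–Yekutieli switch exists for arbitrary dependence.
The BH mask at level $\alpha$ can never be more liberal than raw
$\alpha$ at its largest passing p-value. One-sample maps guard the
zero-variance case with a finite sentinel $t = \pm 10^9$ plus a warning
instead of Inf, keeping serialization finite. `dice(∅, ∅) = 1` by
convention (two empty masks are identical), logged when triggered.
Cohen's d uses the unbiased pooled standard deviation — note one worked
example in the build contract implies a different normalization
({0,1} vs {1,2} giving −1); the definition ("unbiased pooled variance")
is followed, which gives $-\sqrt 2$ there.

# Preprocessing conventions

The band-pass filter applies the exact two-pass magnitude response of an
order-$n$ Butterworth band-pass (default $n = 4$, 0.01–0.10 Hz) in the
frequency domain:
$G(f) = 1/(1 + ((f^2 - f_0^2)/(Bf))^{2n})$ with $f_0$ the geometric band
center and $B$ the bandwidth. This is zero-phase by construction,
removes DC exactly (every output row is exactly zero-mean), and matches
the two-pass gain of the named time-domain design without requiring a
filter-design dependency. Order and band are configuration.

Processing order is: filter the full series, then censor frames with
FD > 0.5 mm. Filtering after deletion would smear spectral leakage from
the gaps; censoring after filtering keeps correlations on clean frames
while the filter sees an unbroken series. The order is recorded in the
report provenance. A subject retaining fewer than 50% of frames is
*excluded* — a value, not an error — and carries no maps downstream.
(The eligibility phrasing in the source participant description reads
inverted; it is implemented as "excluded when fewer than half the
frames survive FD ≤ 0.5 mm".)

Residualization returns residuals plus the grand mean, drops constant
covariates (nothing to remove), one-hot encodes categoricals dropping
one level, and hard-errors on rank-deficient designs naming the
collinear columns. It is idempotent and leaves residuals orthogonal to
every covariate column to $10^{-8}$.

# The synthetic world

The generator (`generator_params()`, `generate_space()`,
`generate_cohort()`, `generate_subject_timeseries()`) is first-class,
tested code. It emulates the statistical structure the analysis relies
on — not the appearance of real data:

- **Geometry**: each hemisphere is a jittered spherical shell
  (radius ~50 mm) sampled at ≥50 vertices; the right hemisphere is the
  exact mirror of the left (optionally jittered), so the ground-truth
  homologous pairing is known. Hand-motor patches sit at mirrored dorsal
  locations; the posterior 15% of each hemisphere forms a hub set.
- **Signals**: a latent-factor (low-rank + noise) model at
  O(vertices × frames) cost. Hub vertices share a common factor
  (loading 1.5), mirror twins share a homotopic factor whose loading
  $\sqrt{\rho/(1-\rho)}$ targets a twin correlation of $\rho = 0.3$, and
  each hand-motor patch loads (1.5 baseline) on its hemisphere's motor
  factor, with surrounding vertices at half weight. With unit noise this
  puts within-patch correlations at $w^2/(w^2 + \lambda^2 + 1) \approx
  0.61$ — deliberately at the $r > 0.6$ edge threshold, so a
  handedness-dependent shift of $w$ moves edge counts.
- **Handedness effect**: a subject with handedness score $s$ gets motor
  couplings $w_{Ml} = w_0 + e\,s/100$ and $w_{Mr} = w_0 - e\,s/100$
  where $e$ is `motor_asymmetry_effect`. Right-handers therefore gain
  left-motor edges and lose right-motor edges, the direction of the
  reference findings; with $e = 0$ group labels are exchangeable by
  construction.
- **Cohort**: balanced L/R/M groups; four handedness items on
  {100, 50, 0, −50, −100} drawn consistently with the group (right pole
  positive); age ~120 ± 7.5 months, ~43% girls, five race strata, four
  sites, three scanner vendors, FD baseline |N(0.12, 0.04)| mm, brain
  volume ~1215 ± 108 mL — magnitudes typical of a large developmental
  cohort at ages 9–11.
- **Motion**: per-frame FD adds Bernoulli spikes (rate 0.05) drawn in
  0.6–1.5 mm, i.e. censorable at the 0.5-mm threshold.
- **Determinism**: all randomness flows from one master seed through
  named substreams (space, cohort, subject *i*, split, calibration), so
  any subject regenerates bit-identically in isolation.

What the synthetic world does **not** model: spatial smoothness and
autocorrelation of real BOLD, scanner- and site-specific artifacts
beyond covariate labels, non-Gaussian physiological noise, cortical
folding geometry (and hence geodesic ≠ Euclidean effects), and any
structural/diffusion channel. A green test therefore establishes that
the *pipeline arithmetic and inference layer* behave as specified under
the stated statistical structure — not that the biological effect sizes
of any real cohort are reproduced.

## Calibration instead of reproduction

The reference effect sizes (Cohen's d = 0.75 for the handedness index,
index–score correlations of 0.37/0.26, asymmetry-pattern Dice > 0.71)
derive from access-restricted data and are not reproducible at desk
scale. The acceptance layer treats d = 0.75 as a *calibration*:
`calibrate_motor_effect()` root-finds the `motor_asymmetry_effect`
whose design d (measured through the real pipeline stages on a fixed
calibration cohort with common random numbers) equals 0.75, and the
estimate is then re-measured on fresh seeds at n = 300/group. Per-seed
estimates scatter around the target more widely than pure sampling
error because each seed regenerates its own space (ROI size 2–6
vertices at desk scale modulates the effective effect), so the
acceptance band is assessed on the mean across 10 seeds.

## Numerical and degenerate-input choices

- $\varepsilon = 10^{-9}$ for all ratio guards; NaN encodes undefined.
- Correlation clipping at $1 - 10^{-7}$ before atanh.
- Row standardization treats sum-of-squares below $10^{-12}$ as zero
  variance.
- FCD chunk size defaults to 256 rows; any value is bit-identical.
- Greedy pairing ties break on lower vertex index; the assignment is
  reproducible to the bit.
- On-disk vertex ids are 0-based (the interchange convention);
  in-memory indices are R's 1-based. Conversion happens only at the I/O
  boundary.
- I/O dialects are TSV (17 significant digits; exact double round-trip)
  and a raw little-endian binary with a JSON sidecar (bit-exact,
  compact). CIFTI/HDF5 readers are out of scope for this build and
  error informatively.

## Scaled-down inference checks

Two stochastic acceptance checks are run at reduced size with the
scaling chosen once, in advance: the null-pipeline check (no effect →
empty FDR masks) uses 60 seeds at 40 subjects/group, 120 vertices, 128
frames — at very small groups the t approximation on discrete
log-counts is visibly anticonservative, and the reference design's
n = 600/group is *better* approximated by larger groups, so 40/group is
the faithful desk-scale choice; and the d-calibration check evaluates
10 seeds at n = 300/group at the canonical 400-vertex scale. Short
series deserve a warning generally: after band-passing 0.01–0.10 Hz at
TR = 0.8 s, a T-frame series has roughly 0.072·T effective degrees of
freedom, so chance $|r| > 0.6$ is non-negligible below ~200 frames.

# Known limitations

- The greedy pairing is O(nL·nR) in memory; fine for desk-scale
  synthetic spaces, not for full 32k-vertex hemispheres in one block.
- Geodesic ROI distance is not implemented (argument reserved).
- No permutation-based cluster inference or spatial autocorrelation
  modeling: inference is vertex-wise FDR only, as in the reference
  analysis.
- The CLI covers synth/run/report/validate; it does not orchestrate
  multi-study comparisons.
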