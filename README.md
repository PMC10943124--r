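# handlat

Connectivity-based handedness and hemispheric laterality analysis of
dense resting-state functional connectomes.

## The scientific problem

Handedness is the most visible behavioral lateralization in humans, yet
structural brain asymmetries explain little of it. A more sensitive
readout is *functional connectivity density* (FCD): for every
grayordinate (surface vertex) of a dense resting-state fMRI matrix, the
number of other grayordinates whose time series correlate with it beyond
a threshold — a hub measure on the thresholded dense connectome.
Contrasting the FCD of the left-hemisphere hand-motor area (`Ml`, the
right-hand representation) with its right-hemisphere homologue (`Mr`,
the left-hand representation) yields a compact, neurobiological index of
handedness, and seed-based connectivity of the two motor areas yields a
vertex-wise laterality map. This package implements that full analysis
chain for researchers in developmental and systems neuroimaging, along
with a synthetic-cohort generator so every stage is testable without
access-restricted subject data.

## The statistics at the core

For a band-pass filtered (0.01–0.10 Hz), motion-censored (FD ≤ 0.5 mm)
series x_v(t) at vertex v:

- **gFCD**: `gFCD(v) = log #{u ≠ v : r(x_v, x_u) > 0.6}` (log of 0 kept
  at 0; threshold, sign, and hemisphere scope — global / ipsilateral /
  contralateral — configurable). Global counts partition exactly into
  ipsilateral + contralateral.
- **Handedness index**:
  `I_H = (gFCD(Ml) − gFCD(Mr)) / (gFCD(Ml) + gFCD(Mr))`,
  computed on ROI-mean gFCD after grand-mean scaling across sex × race
  strata; positive values are the right-handed direction.
- **Seed connectivity**: `z(v) = atanh(r(seed mean, x_v))` for the `Ml`
  and `Mr` 10-mm ROIs.
- **Laterality index**:
  `Δ(v) = (z_Ml(v) − z_Mr(v)) / (|z_Ml(v)| + |z_Mr(v)|)` ∈ [−1, 1].
- **Asymmetry**: `value(right) − value(left)` over homologous vertex
  pairs obtained by mirror-reflecting left-hemisphere coordinates about
  the bounding-box center and nearest-neighbor matching.
- **Group layer**: pooled-variance two-sample and one-sample t maps,
  Benjamini–Hochberg FDR at p_FDR < 0.05, Cohen's d, Dice overlap of
  thresholded maps, and ROI-level ANCOVA with covariates.

## Worked example

A small synthetic study, end to end (sizes scaled down for the example;
the acceptance suite runs the canonical 60-per-group, 400-vertex study):

```r
library(handlat)
cfg <- study_config(
  n_per_group = 20,
  gen = generator_params(n_vertices_per_hemi = 120, n_frames = 192, seed = 42),
  covariates = c("mean_fd", "age_months"))
report <- run_study(cfg)
print(report)
#> study_report: 60 subjects (0 excluded), 240 vertices
#> index-score correlations:
#>       sample  n         r            p
#>          all 50 0.6112888 2.412571e-06
#>    discovery 26 0.6201336 7.266181e-04
#>  replication 24 0.6037213 1.786078e-03
#> L-vs-R gFCD contrast: 2 significant vertices at pFDR < 0.05
aggregate(handedness_index ~ group, report$subject_index, mean)
#>   group handedness_index
#> 1     L       -0.7919148
#> 2     M        0.2534386
#> 3     R        0.6171759
```

Reading the output: the handedness index orders the groups left <
mixed < right; it correlates positively with the questionnaire
handedness score in both the discovery and the replication half of the
stratified split (here r ≈ 0.61 in a clean synthetic world; real
cohorts are noisier); and the vertex-wise left- vs right-hander gFCD
contrast survives FDR only where the generator placed a true
handedness-dependent effect, i.e. in the hand-motor patches. Ten
subjects with zero suprathreshold counts in both motor ROIs have an
undefined (NaN) index and are dropped from the correlations with a
count.

A command-line interface wraps the same stages:

```sh
Rscript inst/cli/handlat.R run --config study.json --out out/
Rscript inst/cli/handlat.R synth --config study.json --out fixtures/
Rscript inst/cli/handlat.R validate --config study.json
```

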