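---
title: "Methods: static and dynamic functional network connectivity in dynfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: static and dynamic functional network connectivity in dynfc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models and
procedures, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, the numerical
choices, and the places where the design was genuinely open and a choice had
to be made.

## The analysis chain

The package analyses per-subject component time courses `Y ∈ R^{T×C}`
(T volumes at repetition time TR seconds, C independent components), the
output of a group ICA. Two complementary summaries are computed.

**Static FNC.** After conditioning — discarding the first 10 volumes,
despiking, polynomial detrending, and zero-phase fifth-order Butterworth
low-pass filtering at 0.15 Hz — static functional network connectivity is the
C×C matrix of pairwise Pearson correlations, Fisher z-transformed with
clipping at |r| = 1 − 1e−7 and a zeroed diagonal.

**Dynamic FNC.** A sliding window of 22 TR (44 s), stepping 1 TR (2 s),
under a taper built by convolving a rectangle with a Gaussian of σ = 3 TR
(6 s), yields per-window tapered covariances. Each window's connectivity is
estimated through an L1-penalised precision matrix (graphical lasso, written
here as blockwise coordinate descent): the penalty λ is selected once per
subject by repeated random train/test splits of the windows (10 repetitions),
fitting on the pooled training covariance and scoring held-out Gaussian
log-likelihood over a 10-point grid log-spaced on [1e−3, 1]. By default the
window's reported values are the Fisher-z correlations of the regularised
covariance `Θ̂⁻¹`; `scale = "partial"` reports partial correlations
(−Θ̂ᵢⱼ/√(Θ̂ᵢᵢΘ̂ⱼⱼ)) instead. All windows of all subjects are pooled
(vectorised upper triangles) and clustered by k-means under the Manhattan
distance with coordinate-wise-median centroid updates, 150 iterations and 5
restarts; states are relabelled by descending pooled frequency so State 1 is
always the most frequent. Temporal properties per subject and state are
fraction time, mean dwell time in seconds (mean consecutive-run length ×
step duration, 0 for states never entered), transition number, and the
group-level state-entry percentage.

**Statistics.** Group comparisons of connectivity values regress out age,
mean framewise displacement and site (categorical dummies) before a one-way
omnibus F and Welch post hoc t tests for the four enumerated contrasts
(healthy F vs healthy M, patient F vs healthy F, patient M vs healthy M,
patient F vs patient M), with Benjamini–Hochberg FDR across the outcome
family within each contrast at α = 0.05. Temporal properties are compared by
Mann–Whitney U at α = 0.01. Discrimination uses the rank-formula AUC (equal
to U/(n₁n₂)) with a percentile bootstrap CI; associations use partial
Spearman correlation (rank, residualise on controls, Pearson on residuals).

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| window width | 22 | TR (44 s) | standard sliding-window width; sensitivity grid re-runs at 30 TR |
| step | 1 | TR (2 s) | maximal temporal resolution of window placement |
| taper σ | 3 | TR (6 s) | soft window edges reduce cross-state contamination |
| low-pass cutoff | 0.15 | Hz | retains the resting-state band, removes high-frequency noise |
| λ grid | 1e−3 … 1 | — | spans effectively-unpenalised to fully-sparsified precisions |
| CV repetitions | 10 | — | the repetition count of the per-subject λ selection |
| k-means | 150 iter, 5 restarts | — | the clustering budget of the published configuration |
| FDR α / MWU α | 0.05 / 0.01 | — | connectivity family-wise level / temporal-feature level |
| QC limits | 3 mm, 3° | — | strict exclusion above either limit |

Derived durations (window 44 s, step 2 s, taper 6 s) are always recomputed
from the primitives at validation time and never stored separately.

## The synthetic cohort generator

The generator is first-class, tested code: every downstream stage is
validated by recovering what it plants.

*Cohort table.* Four groups (patient/control × female/male; default sizes
135/73/123/105 over six sites) with covariates drawn per group: Gaussian age,
mean framewise displacement (left-truncated at 0 because the tabulated SD
exceeds the mean), grey- and white-matter volume and brain parenchymal
fraction (resampled into (0, 1] when `bpf_truncate = TRUE`, the explicit
default); log-normal lesion volume and disease duration matched to the
tabulated median/IQR by moment matching on the log scale (only median and
IQR are published for these skewed variables); EDSS as a log-normal draw
rounded to the ordinal 0.5-step scale.

*Latent states.* Each subject follows a sticky Markov chain over three
connectivity states, initialised at its stationary distribution. The
transition matrix is `P = (1 − a) I + a 1πᵀ`, whose stationary vector is
exactly the planted occupancy π and whose expected dwell in state s is
`1/(a(1 − π_s))` steps. The default stickiness a = 0.03 gives dwell times of
roughly 45–80 TR (1.5–2.5 minutes) — long enough that 22-TR windows are
mostly state-pure, short enough that a scan contains several episodes. The
three state profiles are block-structured correlation matrices over three
pseudo-networks: a sparse state (within 0.10, between 0.02), a segregated
middle state (within 0.70, between −0.15; the anticorrelation stands in for
the familiar segregation of task-positive and task-negative systems), and a
high connected state (within 0.80, between 0.55). An earlier middle profile
with stronger anticorrelation was rejected because it made the three states
nearly collinear in feature space: windows spanning middle↔high transitions
averaged to a sparse-looking profile and were systematically mislabelled.

*Group effects.* Occupancy defaults plant the qualitative dissociation the
generator is designed to emulate: female controls prefer the middle state
(0.25/0.53/0.22), female patients shift toward the sparse state
(0.55/0.25/0.20), and the male groups share one occupancy (0.45/0.33/0.22)
so that their planted contrast is purely static — an additive −0.20 offset on
the between-network correlations of the first two pseudo-networks in every
state for male patients, projected back to SPD by eigenvalue clipping. The
published pooled state percentages differ between two places in the source
material (42/36/16 vs 49/36/15); occupancy is therefore a free configuration
entry, and the defaults pool to roughly 0.43/0.36/0.21, reproducing the
ordering rather than either exact triple.

*Nuisance structure.* White observation noise (SD 0.1 of the unit signal
scale), slow drift (order-2 polynomial plus a cosine with a 128 s period,
amplitude 0.15) for the detrend/filter stages to remove, and random-walk
motion traces whose expected mean framewise displacement matches each
subject's tabulated value (rotations scaled through the 50 mm head-radius
arc length).

*What is not emulated:* hemodynamic response functions, scanner artefacts
beyond spikes and drift, lesioned anatomy, site-specific acquisition
differences beyond the site covariate, and spatial structure of real
component maps. Passing recovery tests therefore demonstrates correctness of
the estimation machinery under the generative assumptions, not robustness to
everything real scanners do.

## Validation studies and their design

The exported studies are scaled-down in subjects but not in mechanism.

- `recovery_study()`: 20 cohorts of 4 × 12 subjects, T = 300 (a ten-minute
  scan), full dynamic chain; scores the adjusted Rand index of window labels
  at the true k and whether the elbow picks k = 3.
- `occupancy_study()`: one cohort of 4 × 50 subjects, T = 900 (three
  concatenated ten-minute runs). The long scan is deliberate: the group-mean
  fraction time of a sticky chain has a per-cell standard error of ~0.02
  even at this length, and window-modal labelling adds a small systematic
  amplification of dominant states, so shorter designs cannot resolve a
  0.05-level comparison. This study disables the static group offsets — a
  separate planted feature with its own study — because offset-shifted state
  signatures otherwise bleed into the offset group's assignments.
- `null_rejection_study()`: 1000 null datasets for the covariate-adjusted
  group test's type-I error.
- `ica_recovery_study()`: sparse super-Gaussian spatial maps (the
  identifiable side of a spatial ICA) mixed with Gaussian time courses,
  two-stage group ICA with ICASSO, optimal-assignment matching; fraction of
  maps recovered at |r| > 0.9.
- `planted_sign_study()`: 20 cohorts of 4 × 24 subjects, T = 260; checks
  that the significant findings match the planted signs — the female
  contrast's sparse-state fraction time (Mann–Whitney, P < 0.01, correct
  direction) and the male contrast's FDR-significant static pairs inside the
  planted block (all negative). Study size is a design parameter like scan
  length: at 12–18 subjects per group the planted static effect's q-values
  sit just above 0.05 — a power statement, not a correctness one.

## Numerical choices and open decisions

- **Connectivity scale of windowed estimates.** The sparse precision can be
  reported as partial correlations or as correlations of the regularised
  covariance. The default is the latter, the convention of the group-ICA
  dynamic-connectivity toolbox lineage this analysis follows; partial
  correlations also empirically destroy the block structure that separates
  connectivity states. `scale = "partial"` retains the alternative, and the
  λ→0 limit of that scale is tested against the direct inverse-covariance
  oracle.
- **λ selection.** "Repeated random splits" is read as train/test splits of
  the windows with the graphical lasso fitted to the pooled training
  covariance. Because the pooled covariance is well conditioned the selected
  penalty is light, which preserves between-state contrast; training on
  single-window covariances instead selects penalties an order of magnitude
  larger and measurably blurs state separation.
- **Elbow criterion.** The within/between cluster-validity ratio is computed
  and reported, but selection uses the curvature (discrete second
  difference) of the monotone within-cluster dispersion curve. On realistic
  data the ratio is non-monotone in k — the mean between-centroid distance
  falls faster than the within-cluster distance — so the ratio's curvature
  argmax is unstable while the dispersion knee is not.
- **Despiking** is robust MAD-clipping with a smooth tanh squashing beyond 4
  robust SDs: outliers are compressed to at most ~5 robust SDs, inliers are
  untouched to machine precision, and constant series pass through. The
  published tool name pins a behaviour ("despike"), not an algorithm.
- **Framewise displacement** is the 6-parameter backward-difference sum with
  rotations converted at a 50 mm head radius; the QC rule excludes strictly
  above 3 mm translation or 3° rotation, matching the printed "\>".
- **Motion nuisance regression** of "six parameters on the connectivity
  matrix" is ambiguous between per-subject summaries across subjects and
  per-window regressors within subject; both are implemented behind
  `nuisance_level = c("subject", "window", "none")` with `"subject"` as
  default.
- **Zero-phase filtering** (forward–backward) squares the one-way Butterworth
  magnitude response; tests compare against the bilinear-warped digital
  closed form, not the analog prototype.
- **Degenerate inputs.** Zero-variance components get zeroed connectivity
  rows with a warning; non-SPD tapered covariances are repaired by ridge
  jitter and logged; empty k-means clusters are re-seeded at the farthest
  sample; perfectly correlated series are clipped before `atanh`.
- **Reproducibility.** A single master seed fans out to per-stage child
  seeds by a stable hash, so toggling one stage does not shift another's
  random stream; manifests record the seed, a config hash and per-stage
  checksums of a canonical text serialisation.

## Known limitations

- Windows spanning state transitions are genuinely ambiguous; Fisher-z
  convexity biases such mixture windows slightly toward the
  weaker-connectivity state (of order +0.02 on the sparse state's pooled
  fraction), and window-modal labelling amplifies dominant states by a
  similar amount. Both effects are intrinsic to windowed state labelling,
  not estimation bugs.
- Group-mean fraction time at 50 subjects per group carries a ~0.02 per-cell
  standard error from the state chains themselves; recovery checks at the
  0.05 level operate near this statistical floor and a rare seed can exceed
  it.
- The graphical lasso is tuned for the C ≪ window-width regime (10
  components, 22-sample windows); with C approaching the window width the
  estimates lean heavily on the penalty and a warning is issued.
- Site enters all models as a fixed categorical covariate; no mixed-effects
  site modelling, no permutation inference, and no voxel-space preprocessing
  (realignment, normalisation, smoothing) are in scope.
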