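---
title: "Methods: rest-to-task shifts in seed-based directed connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rest-to-task shifts in seed-based directed connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
model and its assumptions, the parameters that matter, what the synthetic
cohort emulates (and what it does not), the numerical choices, and the known
limitations. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` compute.

## The model

`restshift` treats directed seed–voxel influence with a bivariate,
coefficient-based Granger-causal model at one time lag. For z-scored source
`x` and target `y`,

$$y_t = c + a\,y_{t-1} + b\,x_{t-1} + e_t,$$

fit by OLS; the *path coefficient* (PC) is the signed coefficient $b$. Two
directions are estimated independently — the lagged seed predicting each
voxel (seed→brain) and each lagged voxel predicting the seed (brain→seed);
these are distinct regressions, not transposes of one another. No
instantaneous (lag-0) term is included: with one, $b$ would no longer be a
pure directed term, and only the one-lag form is validated here. The
signed-coefficient variant (rather than a variance-ratio Granger statistic)
is used because the analysis requires negative influences to be
representable: group contrasts and one-sample tests of the *change* of
path coefficient (CPC = PC~task~ − PC~rest~) depend on sign.

Assumptions worth keeping in view: the latent dynamics are approximately
linear and stationary within a state; one TR (2.5 s) is an adequate lag for
the influence of interest; and haemodynamic differences between regions are
mild enough that lag-1 coefficients are comparable across voxels. These are
assumptions of the method, not established facts about BOLD.

### Task-state estimation

Only the highest-load (2-back) condition defines the task state. Each 30-s
condition window contains 12 volumes at TR 2.5 s (a volume belongs to a
window if its acquisition midpoint falls inside). Within each block the
series are linearly detrended, mean-centred and scaled to unit SD; the PC
is estimated per block and averaged (unweighted) over the 14 blocks of the
default layout. Blocks shorter than 6 volumes are dropped with a warning.
Within-block mean-centring is required by the short-window regression;
SD-scaling is an extension adopted for scale invariance (both behaviours
are exposed via `zscore_blocks`; scaling is the default). This blockwise
estimator carries visible small-sample shrinkage (see *Calibration*).

## The pipeline

Per subject: discard the first 5 resting volumes; scrub volumes with
framewise displacement (FD) above 0.5 mm by linear interpolation between
the nearest clean neighbours; smooth with an 8-mm FWHM isotropic Gaussian;
band-pass the resting run to 0.01–0.08 Hz (ideal FFT filter, DC removed);
regress the nuisance set (6 motion parameters, global, white-matter and CSF
means). The task chain replaces the band-pass with HRF-convolved condition
regressors appended to the nuisance set, fit session by session so each
session's own global signal is removed (state-specific global regression).
FD uses the 50-mm-radius scalar convention
$\mathrm{FD}_t = \sum|\Delta \mathrm{trans}| + 50\sum|\Delta \mathrm{rot}|$.
Subject exclusion: any translation above 3.0 mm, rotation above 3.0°
(strict inequalities), or task hit rate below 30%.

Group inference fits, at every in-mask voxel, CPC on
[intercept, group (SZ = +1/HC = −1), age, gender, meanFD~rest~,
meanFD~task~] and maps the group-contrast t with df = n − 6 (54 at the full
sample of 60). Including both motion covariates is what makes the df
arithmetic come out at 54; a single pooled meanFD would give 55. Cluster
correction is Monte-Carlo: residual smoothness is estimated by the
classical first-difference estimator, Gaussian noise is simulated on the
analysis mask at that smoothness, re-standardised within the mask,
thresholded two-sided at voxel p, and the maximum suprathreshold component
(26-connectivity, positive and negative excursions labelled separately)
recorded per iteration; the extent threshold is the smallest size whose
null familywise probability is ≤ α. Surviving clusters get per-group
one-sample t tests of the cluster-mean CPC (plain mode, df = n − 1, the
form matching published cluster statistics; a covariate-adjusted intercept
test is available because the two conventions genuinely differ and the
source description is ambiguous), a two-sample Cohen's
d = t·√(1/n₁ + 1/n₂), and an activation-control re-test with per-subject
2-back activation betas of the seed and the cluster appended as covariates.

Associations at cluster level: hit rate by Spearman within each group (with
a one-tailed Fisher r-to-Z comparison of the two correlations), symptom
dimensions by Spearman and SOFAS/SSPI by Pearson within patients,
antipsychotic dose and lifetime exposure by Spearman. Correlation p values
use the t approximation with df = n − 2 − (number of covariates) — the
convention that reproduces published example p values; partial Spearman is
partial Pearson on average ranks. Hypothesised tests use p < 0.025
two-tailed, exploratory tests p < 0.05.

## The synthetic cohort

The generator emulates the study conditions: 29 patients and 31 controls
(12 + 12 at demonstration scale); a 240-volume resting run at TR 2.5 s; two
task sessions of seven 110-s blocks, each block presenting 0-, 1- and
2-back conditions of 30 s in seeded random order with 10-s gaps whose first
2 s are instruction. Latent dynamics are a K+1-node VAR(1) whose
coefficient matrix switches from `A_rest` to the group's task matrix for
volumes whose midpoints lie in 2-back windows; instruction and gap periods
use `A_rest`, and the switch is instantaneous while the *activation*
confound (HRF-convolved condition boxcars added to configured nodes) is
haemodynamically lagged — the simplest convention that still lets the
activation-control analysis do real work. Node series are embedded as
Gaussian profiles (SD 4 mm) at their mm positions on a 24×28×24 grid at
3 mm (16×18×16 at demo scale) inside an ellipsoidal brain-like mask, with
i.i.d. voxel noise (SD 1.0, of the same order as the latent signal at the
node centre — an optimistic but defensible single-voxel SNR), a global
low-frequency drift, WM/CSF nuisance series, and an FD-locked global
artefact. Motion traces are random walks calibrated so the expected mean FD
matches per-subject targets (~0.14–0.17 mm, patients slightly higher), with
rare spikes to exercise scrubbing. Demographics and behaviour are drawn to
match the published group summaries (age 33±9; hit rate 73.7±7.5 vs
78.5±5.0; gender/handedness proportions; chlorpromazine-equivalent and
lifetime-exposure scales); symptom scores are truncated at zero.

Two groups differ **only** in the task-state coefficients of the planted
edges (seed→target1 by default). Subject-level task-edge weights scatter
around their group mean with SD 0.2 — chosen so realized cluster CPC
spreads resemble published per-group SDs (~0.2–0.3) once estimation noise
is included.

### Calibration of the planted effect

The config's `group_cpc_effect_d` is an *observed-scale* effect: the
standardized SZ−HC difference in measured CPC. Converting it to a raw edge
shift requires knowing how much the end-to-end estimator attenuates and
blurs the truth. A first-order analytic account is badly optimistic: the
band-passed resting run has only ≈ 2·BW·T·TR ≈ 82 effective degrees of
freedom (not 235); the 12-volume blockwise estimator shrinks coefficients
by ≈ 12% (small-sample detrend/z-score bias); smoothing, voxel noise and
seed-sphere averaging attenuate further. The package therefore measures the
two constants directly: `calibrate_cpc_estimator()` regresses the CPC
measured at the planted target voxel on the planted true CPC across pilot
subjects run through the full pipeline, giving a slope (attenuation)
g ≈ 0.73 and a per-subject estimator SD ≈ 0.146 at default geometry (3
cohorts × 24 subjects, fixed seed). The generator then plants
$\Delta = d\,\sqrt{(g\sigma_b)^2 + \sigma_{est}^2}\,/\,g$. These constants
are defaults of `cohort_config()`; changing the temporal layout, smoothing,
noise or seed geometry calls for re-running the calibration.

Behavioural coupling is planted against the **true** per-subject CPC
(hit rate within group at r = 0.5 by default; psychomotor poverty within
patients at r = 0.4), so any analysis of *measured* CPC sees an attenuated
correlation (≈ r × g σ_b / √((gσ_b)² + σ²~est~) ≈ 0.75·r at defaults).
This is deliberate: behaviour depends on the subject's physiology, not on
our estimate of it.

### What passing tests do and do not show

The generator's linear-Gaussian world lacks haemodynamic variability across
regions, non-stationarity within states, physiological noise spectra,
anatomy, and spatial dependence of nuisance signals. Recovery of planted
effects therefore demonstrates the *pipeline's* correctness and
calibration — estimator consistency, null calibration, familywise-error
control, direction specificity — not that the method would recover ground
truth in real BOLD data, where the model assumptions are approximations.

### Statistical ceiling at demonstration scale

At demo scale (12 + 12 subjects, observed d = 1.2, voxel p < 0.01
two-sided, df = 18 after covariates) the per-voxel detection power is
$P(T_{18}(\mathrm{ncp}=1.2\sqrt{144/24}) > 2.878) \approx 0.52$; measured
end-to-end cluster recovery is ≈ 0.6–0.7, and recovery of the behaviour
coupling (attenuated to ≈ 0.37 observed, tested as a pooled partial
Spearman controlling diagnosis at n = 24) ≈ 0.25–0.4. These ceilings are
properties of the configured sample size and effect size, reported as
measured; the corresponding published effects were detected at n = 60,
where the noncentrality is ≈ 1.6× larger.

## Numerical choices

- **Band-pass**: ideal FFT-domain filter retaining bins in [low, high] and
  zeroing the rest including DC. Exactly testable; off-grid sinusoids show
  the expected Gibbs leakage (amplitude overshoot ≈ 10% at half-integer
  bins) while power is preserved.
- **Smoothing**: separable Gaussian with SD = FWHM/2.355 per axis in mm,
  kernel truncated at ±4 SD and renormalised over the in-grid support, so
  constants are preserved at edges. Compiled (one pass per axis).
- **Scrubbing**: linear interpolation between nearest unflagged neighbours,
  nearest-neighbour at run edges — a documented stand-in for repair-style
  deweighting; threshold FD > 0.5 mm by default.
- **Sphere inclusion**: voxel-centre distance ≤ radius, 0-based voxel
  indices, mm defined by the affine; if the radius is below the voxel
  spacing the voxel containing the centre is used.
- **Degenerate voxels** (zero variance) receive PC = 0 with a logged count,
  keeping group maps complete.
- **Connected components**: 26-neighbour default (6/18 available),
  positive and negative excursions never merged.
- **Extent-threshold determinism**: the Monte-Carlo is seeded from the run
  seed; when many runs share one mask, a memoised threshold function keyed
  on smoothness rounded to 0.5 mm avoids re-simulating per run (used by the
  acceptance script; the rounding changes thresholds by at most 1 voxel).
- **Problem sizes** in tests and the acceptance script are desk-scale by
  design: demo grid 16×18×16, 300–1000 Monte-Carlo iterations, 25-cohort
  recovery loops, 100-rep consistency checks — sizes chosen so the whole
  validation runs on a single CPU in tens of minutes while keeping binomial
  noise on the measured rates acceptable.

## Open choices made here

- Whether within-block normalisation scales to unit SD (we default to yes)
  — only mean-centring is externally specified; both are exposed.
- Task-state global-signal regression is per session (state-specific); a
  per-block variant would discard more df for little gain at 12 volumes.
- One-sample cluster tests default to the plain df = n − 1 form; the
  covariate-adjusted intercept test is available (`covariates=`).
- The Fisher r-to-Z tail is configurable; the default tests controls >
  patients.
- The demographic chi-square uses no continuity correction — the version
  that reproduces standard demographic-table statistics.

## Limitations

**Reverse-direction leakage of the blockwise estimator.** Estimating the
task-state PC inside 12-volume blocks requires conditioning on within-block
statistics (the block mean, trend and SD), which are computed from the whole
block — including samples that postdate each lagged regressor. This makes
the lagged regressor weakly dependent on future innovations and biases the
*reverse* regression away from zero whenever a forward coupling exists:
simulations at the latent level (no spatial embedding, 200 cohorts) show a
planted seed→target coefficient of 0.5 producing a mean forward task PC of
≈ 0.41 and a mean *reverse* task PC of ≈ −0.14. Direction specificity of
the CPC is therefore real but bounded: the causal direction carries about
3× the signal of the reverse direction at this block length, not an order
of magnitude. Between-group contrasts are affected symmetrically (both
groups share the bias), but single-direction interpretation of blockwise
maps should keep this leakage in mind. Long-window estimation (as in the
resting state) does not show it.

**Secondary clusters from source mixing.** Spatial smoothing mixes the seed
and target profiles in the tissue between them; at mixed voxels the
seed→voxel coefficient responds to a planted seed→target change with the
opposite sign, so recovery runs can show flanking negative clusters beside
the planted positive one. On real data the analogous effect is partial-
volume mixing of neighbouring sources.

Bivariate lag-1 Granger on BOLD omits conditioning on other regions,
spectral structure, and haemodynamic deconvolution; group *differences* of
its coefficients are meaningful under weaker assumptions than the
coefficients themselves, which is the use made here. The Monte-Carlo
correction assumes Gaussian, stationary, isotropically smooth noise within
the mask. The generator's simplifications are listed above; in particular
its brain is an ellipsoid and its nodes are isolated Gaussian blobs, so
anatomical specificity of cluster locations cannot be tested synthetically.
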