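---
title: "Laminar discrimination of MEG sources: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar discrimination of MEG sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

MEG measures cortical current flow directly, so in principle its anatomical
resolution is limited only by data quality and the generative models used to
explain the sensor data. With sufficiently precise co-registration, the deep
(white-matter boundary) and superficial (pial) cortical surfaces become
distinguishable hypotheses for where a measured signal was generated: the two
surfaces are 2-4 mm apart, and a current dipole on one of them produces a
slightly different field pattern than its linked counterpart on the other.
`laminarmeg` implements, end to end, the machinery needed to test whether
sensor data can be classified as deep or superficial in origin:

1. a synthetic two-layer cortical anatomy and a spherical-conductor forward
   model,
2. a trial-structured patch-source simulator with controlled per-trial SNR,
3. empirical-Bayes source inversion by ReML over covariance components under
   four prior schemes (IID, COH, EBB, MSP),
4. three laminar decision rules - whole-brain free-energy comparison,
   held-out-sensor cross-validation, and a region-of-interest (ROI) paired
   t-statistic - and
5. the statistical evaluation of the resulting classifiers (exact binomial,
   exact McNemar, Spearman, Meng's correlated-correlations test).

## Generative model and inversion

Sensor data `Y` (trials x sensors x samples) are modelled as `Y = L J + E`
with `L` the lead field of a cortical surface (dipoles normal to the surface,
in a homogeneous conducting sphere; fT per nAm), `J` the source currents, and
`E` Gaussian sensor noise. Data are reduced to `m` orthonormal spatial modes
(the lead-field basis retaining 99.99 % of its energy, at most
`n_sensors - 1`) and `K = 4` temporal modes (the leading right singular
vectors of the trial-averaged, band-passed epoch). Reducing 251 samples to 4
modes concentrates the signal and gives an effective amplitude SNR gain of
`sqrt(251/4) = 7.922`.

The inversion fits the covariance of the *evoked* response - the
trial-averaged reduced data - which is what makes very low per-trial SNRs
workable: averaging 515 trials buys a further `sqrt(515)` amplitude gain, so
a -50 dB per-trial dataset still carries a clearly super-noise evoked
signal. The free energy keeps the full per-trial sample count
(trials x temporal modes), the reference convention for evoked inversions;
the +-3 evidence threshold of the whole-brain analysis is calibrated to
that scale. (Accumulating per-trial covariances instead provably buries the
signal at -50 dB: its eigenvalue is an order of magnitude below the Wishart
sampling fluctuation of the noise.)

In the reduced space the model covariance is a weighted sum of components,

    Sigma = exp(l_0) I  +  sum_k exp(l_k) Q_k,

with `I` the sensor-noise component and `Q_k` the projected source
components of the chosen scheme:

* **IID** - a single identity source covariance (minimum norm);
* **COH** - a single locally coherent component `G G'`, where `G` is the
  patch basis (a Gaussian of geodesic distance along the mesh, FWHM
  calibrated so the half-maximum radius is half the patch size);
* **EBB** - a single component `G diag(v) G'` with `v` the unit-gain
  beamformer power `1 / (a_j' C^-1 a_j)` of each patched lead-field column,
  estimated from the reduced data covariance (regularised by `1e-6` times
  its mean diagonal). The patch basis at the reconstruction FWHM enters the
  component, which is what makes EBB sensitive to a mismatch between the
  simulated and reconstructed patch size; a strictly diagonal beamformer
  prior would be blind to it;
* **MSP** - one rank-one component per library patch (outer product of a
  patch-basis column); the library holds the 60 candidate source locations
  plus 30 random vertices, and all components are optimised simultaneously
  (automatic-relevance style, no greedy search).

Hyperparameters `l` live on the natural-log scale with Gaussian hyperpriors
(mean -5, variance 16 per component). They are optimised by Fisher scoring
with step-halving, so the accepted free-energy sequence is non-decreasing;
convergence is declared when the accepted increase falls below 0.01, when
the accepted step is below 1e-3 in the infinity norm, or after 512
iterations (large patch libraries shrink slowly late in the optimisation). The data second-moment matrix and all components are
normalised to mean diagonal 1 before optimisation (the normalisation cancels
in free-energy *differences* between models fitted to the same data, which is
the quantity the analyses use). The reported free energy includes the
hyperparameter complexity term `- e' P e / 2 + log det(P C_post) / 2`, so
differences approximate log Bayes factors: a difference of 3 corresponds to
roughly a twenty-fold likelihood ratio, and `|dF| > 3` is the significance
threshold of the whole-brain analysis.

## The three laminar analyses

**Whole-brain.** The data (Hann-tapered, 10-30 Hz) are inverted separately
on the pial-only and the white-only model with identical settings, and
`dF = F_pial - F_white` decides the label. Both inversions share the same
spatial modes, computed from the column-stacked lead field of both surfaces;
without a shared projector the two likelihoods would live in different data
subspaces and their difference would be biased. The stacking order is made
canonical (content-based), so swapping the two surfaces in the input negates
`dF` exactly.

**Cross-validation.** Sensors are split into 10 seeded folds; each fold's
model is fitted without the held-out sensors and predicts their evoked
(trial-averaged) data through their lead-field rows and the posterior
sources. The error is the RMSE of
the prediction as a percentage of the RMS measured data per held-out sensor,
averaged over sensors and folds; `dCV = cv_white - cv_pial` so that, like
`dF`, positive favours pial. Both prediction and measurement are compared in
the band-passed, temporal-mode-projected representation the inversion
uses - raw unfiltered time courses are dominated by noise that no source
model can express, which would push every error towards 100 % and erase the
contrast. Temporal modes are computed once from all sensors and shared
across folds (the same basis for fit, prediction and measurement; spatial
modes are honestly re-derived per fold), which keeps folds comparable and is
identical for the two competing surface models, so it cannot bias the
laminar contrast.

**ROI.** The data (10-30 Hz, no Hann) are inverted once on the combined
white+pial mesh (2N vertices, white first). Per vertex and trial, band
power is the variance of the posterior time course inside the active
(100-500 ms) and baseline (-500 to -100 ms) windows, computed in the
temporal-mode subspace. A per-vertex paired t-map (active vs baseline)
defines the ROI: vertices at or above the 75th percentile of their own
surface's t-values, together with their linked counterparts - so the ROI
definition is orthogonal to the subsequent laminar contrast and symmetric
between surfaces. Per trial, each surface's ROI value is the mean absolute
power change within the ROI; the decision statistic is the paired t over
trials of pial minus white values, thresholded at the two-sided critical t
(df = trials - 1, alpha = 0.05). Per-vertex t-maps use corrected noise
variance estimates: per-vertex variances are floored at the 10th percentile
of the across-vertex variance distribution, which attenuates the
artifactually large t-values that near-zero posterior variance would
otherwise produce (sparse priors leave exact zeros; those vertices get
t = 0). The final paired t is left uncorrected - it has no across-vertex
distribution to take a floor from.

A `dF` (or t) of exactly zero is labelled `undetermined` and scored as
incorrect, a conservative choice that only occurs for degenerate inputs
(identical surface models).

## The synthetic anatomy and what it does and does not emulate

The generator produces a folded two-layer cortex: an icosahedral sphere
(level 4, 2562 vertices per surface) whose radius is modulated by a
band-limited random field (folds of 8 mm amplitude and 30 mm wavelength on a
70 mm base radius), with the white surface offset inward along the pial
normals by a smoothly varying 2-4 mm thickness. This reproduces the features
the method cares about: one-to-one vertex linkage, millimetre-scale
pial-white separation, gyral and sulcal vertices of both curvature signs,
sulcal depths spanning 0 to tens of millimetres, and lead-field strength
varying with depth and orientation. It does not emulate real cortical
topology (no lobes, no insula, no hemispheric separation), FreeSurfer
segmentation noise, axial-gradiometer sensors (the synthetic array is 160
radial point magnetometers on a half-sphere helmet of 110 mm radius), or a
realistic single-shell conductor (the sphere is used; the forward interface
accepts alternative engines). Passing tests on this anatomy therefore shows
the *method* discriminates surfaces when its assumptions hold, not that any
particular empirical accuracy transfers to a given subject.

Desk-scale problem sizes were fixed once: 2562 vertices per surface (the
icosahedral ladder's nearest point to a few thousand), 160 sensors, 515
trials, 251-sample epochs at 250 Hz. The sensor count is not free: the
spatial-mode space must remain comfortably larger than the MSP patch
library (a whole-head 275-channel array yields 274 modes against the 90
patches). When the
library can *span* the mode space, the wrong-surface model absorbs its
residual through other patches and the laminar evidence collapses - a
32-to-64-channel array is structurally too small for a 90-patch library,
which is why the default array has 160 channels. At this mesh density the mean edge
length (5.3 mm) slightly exceeds the 5 mm patch FWHM, so patches are
under-resolved and `compute_patch_basis()` says so with a warning; the
simulations run under that warning deliberately, since 5 mm is the patch
size the study design prescribes. The default epoch is -500 to +500 ms (251
samples at 250 Hz), the span every analysis window uses; longer epochs are
configurable.

Noise is scaled to a per-trial amplitude SNR target: one scale per dataset,
chosen so that 20 log10(signal RMS / noise RMS), measured per sensor over
the active window and averaged over sensors (excluding sensors with exactly
zero signal), hits the target; per-dataset scaling keeps trials
exchangeable. The SNR grid is -100, -50, -20, -5, 0, 5 dB plus a noise-only
control in which the signal is zeroed; since "minus infinity dB" does not
pin down a noise scale, the control keeps the noise at the level a 0 dB
target would give for that source. A fixed-noise mode (10 to 2e6 fT RMS,
20 nAm sources) is also provided.

Source vertices are drawn once per experiment: 60 linked indices eligible on
both surfaces (lead-field RMS above the 1st percentile on each, excluding
boundary rings on open sheets), used as pial sources and as white sources
(120 datasets) and as the 60 MSP candidate patches. The seed ladder derives
all per-simulation seeds from the single experiment seed, so any simulation
is reproducible in isolation and aggregation is order-independent.

## Numerical choices

* Filtering: zero-phase (forward-backward) order-4 Butterworth band-pass,
  represented as an explicit linear operator on the 251-sample epoch; the
  operator is folded into the temporal projection on the hot path, which is
  algebraically identical to filtering first (and tested to be).
* Curvature: cotangent-Laplacian mean curvature with Meyer mixed-Voronoi
  areas; sign convention convex-outward positive (gyral crowns positive,
  fundi negative). Boundary vertices of open sheets are returned as `NA`.
* Sulcal depth: Euclidean distance to the nearest mesh vertex on the convex
  hull, with the hull built from the pial surface; the hull is an
  incremental (quickhull-style) construction written in the package because
  no installed dependency provides a 3-D hull. Points within 1e-6 of the
  hull boundary count as hull vertices, so convex meshes get exactly zero
  depth. Which surface's vertices are queried is a parameter.
* Surface smoothing (thickness, FWHM 8 mm default): a geodesic-Gaussian
  kernel symmetrised and Sinkhorn-balanced to a doubly stochastic operator,
  so constants are exactly invariant and field totals exactly conserved.
* EBB data covariance regularisation: `1e-6 x mean(diag(C))`, recorded in
  the component's metadata.
* ReML initialisation: all log hyperparameters start at `-log(K)` for `K`
  components, splitting the (normalised) data variance evenly; steps are
  capped at infinity-norm 8 before halving.
* Ties at the ROI percentile are included (at-or-above rule), so equal-t
  vertices are never split.

## Design choices where the design was open

* The curvature sign convention and the hull source surface are not
  standardised in the field's descriptions; both are parameters with the
  defaults above.
* MSP's 30 extra patches are drawn (seeded) from the non-candidate vertices
  and shared by the pial and white models of one comparison; on the
  combined ROI mesh every library centre contributes a patch on both
  surfaces (180 components).
* The per-vertex ROI t-tests use df = trials - 1, the same convention as
  the final paired test.
* The patch-size experiment runs the whole-brain analysis at +5 dB with
  16 sources per surface per cell and EBB (the scheme whose bias the
  mismatch exposes); simulate and reconstruct FWHM each range over
  {5, 10} mm.
* Problem sizes in the test suite (120 simulations at 2562 vertices for
  the SNR sweeps; 40 noise-only datasets; 10-fold cross-validation on a
  30-source subset of the -20 dB datasets; 16 sources per surface per
  patch-size cell) are the package's desk-scale rendering of the study
  design.

## Known limitations

At very low per-trial SNR (-50 dB) the whole-brain MSP comparison on this
synthetic anatomy shows the superficial bias that real-anatomy studies
only exhibit one SNR step lower (around -100 dB): the smooth spherical
cortex makes linked pial/white patch topographies ~0.99 correlated at 160
channels, so roughly a third of deep sources are pulled superficial once
the evoked signal approaches the noise-in-average. Accuracy at -50 dB is
therefore around 70 percent here rather than above 90; the -20 dB and
+5 dB behaviour is unaffected.

* The spherical conductor makes purely radial sources silent; on a folded
  sphere a small fraction of vertices have nearly radial normals and
  correspondingly weak lead fields. The eligibility rule excludes only the
  weakest 1 %, so a few hard sources remain - by design.
* Absolute free energies depend on the hyperprior constants and the
  normalisation; only differences between models of the same data are
  interpretable, and no attempt is made to reproduce any particular
  implementation's absolute values.
* Single-source simulations only; simultaneous deep and superficial sources
  in one patch are outside the decision rules implemented here.
* The realistic-noise pathway is an interface (`load_noise_epochs()`) for
  user-supplied epochs; no correlated-noise generator is included.

## A worked example

```{r example}
library(laminarmeg)

cfg <- laminar_config(n_sources_per_surface = 10, n_trials = 100,
                      snr_grid_db = -20, include_noise_only = FALSE)
sweep <- run_snr_sweep(cfg, seed = 1)
glance(sweep)          # accuracy, pial bias, significance per condition
autoplot(sweep)        # accuracy against SNR
plot_decision_metrics(sweep, snr_db = -20)
```

The `scripts/acceptance.R` script at the repository root re-runs the full
study design (120 sources at -20, -50 and +5 dB) and writes the headline
classification rates to JSON; see the README for how to run it.
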