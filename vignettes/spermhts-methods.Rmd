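---
title: "Models and methods behind the spermhts screening pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the spermhts screening pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermhts)
```

## The assay being modelled

The pipeline analyses a two-stage phenotypic screen of human spermatozoa in
384-well plates. A motility stage records short brightfield time-lapse
series — 24 frames spanning 0.5 s (48 frames/s) at two positions per well,
separated so no cell is counted twice — from which sperm heads are tracked
and standard CASA kinematics computed. A flow-cytometry stage then scores
acrosome reaction (PNA-488 lectin, FL1 channel) and viability (propidium
iodide, FL3 channel) on the same wells. Compound effects are read out as
percent-of-control median curvilinear velocity (motility) and percent live
acrosome-reacted events (AR).

The real screen's raw data are not needed anywhere in this package: a
synthetic-data module generates ground-truthed tracks, image stacks, flow
events and whole plates with the statistical structure the analysis
assumes, so every stage can be validated against known truth.

## Track motion models

Three kinematic classes are simulated per field (`motility_sim_config()`),
chosen so that their *measured* kinematics land in the WHO classification
regimes:

* **PM (progressively motile).** Straight drift at a speed drawn from
  N(100, 20²) µm/s, plus a sinusoidal lateral oscillation emulating the
  flagellar beat: amplitude 2 µm, frequency 14 Hz. At 48 fps this yields
  VCL ≈ 145 µm/s, VAP ≈ 105 µm/s and STR ≈ 98% — VCL > VAP > VSL with
  STR above the 80% progressive threshold, in the range of clinical CASA
  values for prepared donor sperm. The beat parameters are modelling
  choices (no beat model is prescribed by the assay), picked to give the
  correct VCL/VAP separation rather than to mimic flagellar hydrodynamics.
* **NPM (non-progressively motile).** First-order autoregressive positional
  jitter (stationary SD 0.8 µm, lag-1 correlation 0.7) around a centre
  drifting at 5 µm/s. Measured VAP ≈ 10–20 µm/s with low STR: motile but
  not progressive.
* **IM (immotile).** Isotropic i.i.d. Gaussian jitter of SD 0.1 µm,
  emulating Brownian wobble and localisation noise; measured VAP and VSL
  fall well below the immotile cut-offs.

Tracks are seeded uniformly over the field and **reflected at the field
edges** so all points stay in-field. Reflection kinks the paths of
fast swimmers that reach an edge within the 0.5 s window (~4% of PM cells
at the default 666 µm field), and those tracks are legitimately classified
non-progressive by the measured-kinematics rules; class-recovery checks
therefore use 95% (PM) and 90% (IM) floors rather than exactness.

The default field is 1024 × 1024 pixels at 0.65 µm/pixel — a desk-scale
stand-in for 20× optics — and the default cell load is 120/50/30
PM/NPM/IM per position (400 cells per well over two positions), matching
the >200 cells per well the assay is designed to track.

## Image rendering and head detection

Heads are rendered as 2-D Gaussian spots (σ = 1.5 px) of amplitude 8000
intensity units on a background of 1000 with additive Gaussian noise
(SD 50), bright-on-dark by default (the convention the mass-based detector
assumes; an `invert` flag renders dark heads). Pixel (i, j) has its centre
at ((j−0.5)·s, (i−0.5)·s) µm for pixel size s; the origin is the top-left
corner with y increasing downward.

Detection follows the Crocker–Grier scheme: a difference-of-Gaussians
band-pass with scales `feature_diameter/7` and `feature_diameter`
(default diameter 9 px), strict 3×3 local maxima outside an image margin of
half a feature, minimum-separation suppression (9 px, brighter peak wins),
and one pass of intensity-weighted centroid refinement over the feature
window, with candidates below an integrated-mass threshold (default 20000,
matched to the default rendering scale) discarded. Candidate peaks that
cannot reach the mass threshold (window area × peak value below it) are
dropped before suppression; this changes nothing for real spots but keeps
noise maxima from entering the quadratic suppression step. The blur itself
is a separable spatial convolution with edge replication — at these kernel
sizes it is markedly faster than FFT-based filtering and adds no
dependency. On noise-free renders the detector recovers centroids to
well under 0.1 px; 0.5 px is the guaranteed bound.

## Track linking

Between consecutive frames, detections are assigned to active track heads
minimising total squared displacement, subject to a hard per-link ceiling
of 12 µm/frame (≈576 µm/s at 48 fps — above any plausible VCL, yet
conservative against cross-track links). Candidate links are partitioned
into connected subnetworks; subnetworks with ≤7 heads and ≤7 detections are
solved exactly by enumeration with a null-link penalty of
`max_displacement²` per unmatched head or detection (the classic
formulation), larger ones greedily by ascending distance. Unmatched
detections start new tracks; with the default `memory = 0` a track ends the
first frame it is missed — no gap closing, which is the conservative
strategy against identity switches. Tracks shorter than 12 of 24 frames are
discarded from kinematic analysis (but counted in the detection
bookkeeping). The two imaging positions of a well are pooled afterwards
with re-assigned unique track ids.

## Kinematics and classification

For an N-point track with frame interval Δt and duration T = (N−1)Δt:
VCL is the polyline length over T; VSL the first-to-last chord over T; VAP
the length of the path smoothed by a centred 5-frame moving average
(window shrinking symmetrically at the ends) over T; STR = 100·VSL/VAP and
LIN = 100·VSL/VCL, both defined as 0 when their denominator is 0. The
5-frame window (~0.104 s) spans ~1.5 beat cycles at 14 Hz, enough to
average the beat out of the path while following genuine curvature; the
window is configurable since no standard prescribes it. STR is reported
uncapped (it can exceed 100 in pathological geometries) and classification
is applied to the value as-is.

Classification uses strict inequalities, PM evaluated first (so a track
meeting both rules is PM): **PM** iff VAP > 25 µm/s AND STR > 80%; else
**NPM** iff VAP > 5 µm/s OR VSL > 11 µm/s; else **IM**. A VAP of exactly
25 µm/s is therefore NPM. Sticky-compound wells (cells stuck in one spot
while the rest move normally) are excluded by an input flag, not detected
algorithmically — the phenomenon is a visual-QC call, not a rule.

## Plate analytics

The well readout is median VCL over qualifying tracks. Percent of control
divides by the **median of the 16 DMSO-well medians** (robust to one bad
control well), so the DMSO wells' own percent-of-control median is exactly
100 and normalisation is idempotent. Z' is computed per plate on the
percent-of-control values of the DMSO (negative) versus pristimerin
(positive) control wells; plates below Z' = 0.4 are flagged, not rejected.
A compound well is an inhibitor hit strictly below 85% of control — the
15%-reduction rule — and flagged as an upregulator strictly above 115%,
a symmetric convention adopted because upregulating compounds are reported
without a stated cut-off. Heatmap grids with appended row/column means
support the visual edge-effect check.

## Whole-plate simulation and its calibration

The default layout holds 352 compound wells, 16 DMSO wells (column 24),
8 pristimerin and 8 A23187 wells (column 23). A well's `motility_scale`
multiplies *all* kinematic magnitudes of its cells — PM speed and beat
amplitude, NPM/IM jitter and drift — so the well's median VCL, and hence
its percent of control, scales proportionally (a well at scale 0.5 reads
~50% of control). Class composition still shifts at strong effects because
slowed cells drop below the VAP/STR thresholds, reproducing the observed
pattern that strongly inhibited wells fill with NPM/IM classifications.
`ar_induction` moves a fraction of flow events from the live non-reacted to
the live acrosome-reacted population.

Two noise sources are calibrated to the assay's published quality band
(Z' between 0.4 and 0.8) while keeping the 85% hit threshold's
false-positive expectation below two wells per 352-compound plate:

* a multiplicative per-well biological factor, lognormal with σ = 0.025
  (≈2.5% well-to-well CV), which together with median-sampling noise gives
  null compound wells a percent-of-control SD of ≈3.5–4 points
  (15 points / 4 ≈ 3.9 SDs to the hit cut-off);
* per-well pristimerin efficacy drawn from N(0.2, 0.09²) truncated to
  [0.02, 0.8] — positive-control response varies well to well (donor-pool
  and dispensing variability) far more than vehicle wells do. This widens
  the positive-control arm of Z' without touching the false-positive rate,
  centring simulated plates near Z' ≈ 0.6.

A23187 wells induce +10 points of live-reacted events over the ~5% DMSO
background, putting the positive control at ≈15% — the maximum-induction
level that defines the AR hit threshold.

Per-well reproducibility uses a counter-based seed split: each well's
stream is seeded by a fixed affine hash of the root seed and the well's
grid index, so wells are independent and results do not depend on
simulation order.

## Flow model, gating and AR analysis

Events are drawn from a four-component mixture of bivariate Gaussians on
(log10 FL1, log10 FL3): unstained/live at (2, 2), dead at (2, 4), dead
reacted at (4, 4), live reacted at (4, 2), all with SD 0.25 decades —
stained and unstained populations two decades apart, as on a plate
cytometer — and exported on the linear scale (default 4000 events/well).
The generator is spillover-free, so no compensation step exists; real FCS
exports are accommodated through a channel-name mapping.

Gates are derived per plate from the pooled DMSO wells (≥1000 events
required): per channel, a kernel density estimate on log10 intensity
(Silverman's rule-of-thumb bandwidth) is scanned for modes; the threshold
is the deepest valley between the two largest modes. A second mode only
counts if the valley dips below half the smaller peak — shoulder wiggles of
a unimodal cloud are not modes — otherwise the 99.5th percentile is used
and the fallback flagged. Quadrant membership is strict (`>` on both
channels; boundary events are negative). Percent events are normalised to
total well events; wells below 200 events or with a Pi-positive (dead +
dead-reacted) fraction under 2% are excluded — the 2% floor is a
configurable choice, as the assay states the irregularity but no number.
A compound well is an AR hit when live-reacted events exceed 15% — applied
to the raw percentage, not a DMSO-subtracted induction, matching how the
screen's results are plotted.

Triage applies two orthogonal interference checks to primary hits: a
plate-reader signal (488 nm excitation; 520 or 670 nm emission) above the
plate median + 3·MAD marks a hit autofluorescent, and a no-dye replicate
whose pseudo live-reacted percentage still exceeds the 15% threshold marks
it dye-independent; only unflagged hits survive. The median + 3·MAD rule
(MAD with the usual 1.4826 consistency constant) is a robust-outlier
choice; the assay specifies the wavelengths, not the decision rule. Hits
without a triage record are retained but marked untriaged.

## Dose-response fitting

The 4PL model `y = bottom + (top − bottom)/(1 + (x/EC50)^hill)` is fitted
decreasing-in-dose for inhibition (mirrored for AR induction) by ordinary
(unweighted) nonlinear least squares with Levenberg–Marquardt on
log10 EC50, replicates entered as individual points. Initial values are
self-starting — top/bottom from the extreme per-concentration means, EC50
at the concentration nearest the half-way response, hill = 1 — with hill
bounded to (0, 10]. If the optimiser errors, the initial values are
polished derivative-free and the fit is flagged unconverged; the returned
parameters never have a worse residual sum of squares than the
initialization. Efficacy on the percent-of-control scale is `100 − bottom`
clamped to [0, 100] — referenced to the DMSO anchor at 100, not the fitted
top — and the fitted top for induction curves.

In the parameter-recovery checks, curves are generated at 5% CV
multiplicative noise with n = 2 at each of 8 three-fold dilutions from
10 µM. The KF-4939 scenario uses EC50 0.49 µM, full reduction, hill 1; the
Ticlatone scenario (EC50 4.4 µM, 96% maximal reduction) uses a generating
hill of 2, because with hill 1 a curve with that EC50 would only reach
~67% reduction at the 10 µM top dose — inconsistent with the reported
near-complete reduction — and leaves the lower asymptote poorly identified.

## Problem sizes and determinism

Unit tests exercise reduced problem sizes (fields of a few hundred µm,
plates with tens of cells per well) so the suite runs in about a minute;
the acceptance script and the end-to-end acceptance test run one
full-scale 384-well plate (400 cells and 4000 events per well) plus a
full-resolution rendered stack, which is where the throughput claims are
actually checked. Every simulation function takes an explicit seed and is
bit-reproducible; the plate simulator derives per-well streams from one
root seed as described above.

## What the simulator does and does not emulate

It emulates the statistical structure the analysis relies on: class-typed
motion with realistic CASA magnitudes, spot-like heads on noisy
backgrounds, four-population fluorescence clouds, plate layouts with
control wells, per-well effects and well-to-well variability. It does not
emulate flagella, hydrodynamic or 3-D swimming, cell–cell collisions,
capacitation state, spectral spillover, doublets, autofocus failure or
spatial plate gradients (edge effects can be planted explicitly, not
emergent). Passing tests therefore demonstrate correctness of the
*analysis* under the stated assumptions, not robustness to every artefact
of real instruments; the QC flags (autofocus, sticky compounds, low
events) exist precisely because such artefacts must be handled by
exclusion in practice.

## Known limitations

* No gap closing or merge/split handling in linking; a cell missed for one
  frame starts a new track (by design, against cross-track errors).
* ALH, BCF, WOB and hyperactivation metrics are out of scope.
* The FCS support is a minimal float-data reader/writer for list-mode
  files; compensated or integer-mode files should be exported to CSV.
* B-score or other spatial corrections are not applied; normalisation is
  per-plate against the DMSO controls only.
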