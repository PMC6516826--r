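---
title: "Methods: models, estimators and design choices in icneuro"
author: "icneuro authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in icneuro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`icneuro` re-implements, as a tested and reusable pipeline, the quantitative
analysis chain used to characterize a molecularly defined class of principal
neurons (VIP neurons) in the mouse inferior colliculus (IC): extraction of
intrinsic membrane properties and firing-pattern classification from
current-clamp step families, PCA-based dendritic morphometry with
stellate/disc-shaped classification, optical-fractionator stereology of
labeled-cell fractions, plane fits of physiology against position in the
central nucleus (ICc), and kinetic analysis of optogenetically evoked
postsynaptic potentials (PSPs) including feedforward-inhibition
quantification. A seedable synthetic-data generator supplies every input the
analyses consume, with the statistical structure the analyses assume, so the
whole chain can be validated end to end.

# The synthetic membrane model

Current-clamp sweeps are generated from a single-compartment threshold-reset
neuron with two optional currents:

* a **sag current** `I_w` (I_h-like), first order and
  hyperpolarization-activated: `tau_w dI_w/dt = g_sag * min(V - E_L, 0) - I_w`.
  During a hyperpolarizing step it builds up over `tau_w` (default 40 ms) and
  pulls the membrane back toward rest, producing the characteristic sag after
  the peak; above rest it is silent, so it does not distort depolarizing
  responses. The rectification matters: a linear (non-rectified) version
  opposes depolarization as it accumulates, which inflates both rheobase and
  the spike-frequency adaptation ratio with a current real I_h does not
  supply at depolarized potentials.
* an **adaptation current** `I_a`, incremented by a fixed amount at every
  spike and decaying with `tau_a` (default 120 ms). It produces
  spike-frequency adaptation; large, slowly decaying increments stop firing
  mid-step and yield transient firing patterns.

Spikes are threshold-reset events. A stylized action potential (1 ms wide,
peaking at +25 mV) is painted into the voltage trace at each reset so that
slope-based spike detection operates on realistic waveforms. Integration is
fixed-step exponential Euler at the configured sampling rate (default
50 kHz, the acquisition rate the analyses assume); correctness is guarded in
the test suite by an independent forward-Euler integration at a 10x finer
step and, for the subthreshold system, by a closed-form eigen-solution
cross-checked against a general-purpose ODE solver.

Emergent properties map onto the model as: peak input resistance
`R_pk ~ 1/g_L` (exactly `1/g_L` without sag), steady-state resistance
`R_ss = 1/(g_L + g_sag)`, membrane time constant `tau_m = C/g_L`, sag ratio
`R_ss/R_pk` (approximately), rheobase `~ (V_th - V_rest) g_L`.

## The VIP population generator

`vipPopulation()` / `simulateVIPCohort()` encode the study conditions for
the recorded VIP population. Per-neuron parameters are drawn so that the
**measured** features (extracted by this package's own estimators from the
simulated sweeps) reproduce the reported population statistics: R_pk
lognormal with mean 242.1 and SD 139.4 MΩ, tau_m lognormal with mean 15.0
and SD 8.8 ms, sag ratio truncated-normal 0.87 ± 0.16 on [0.45, 1], resting
potential normal -69.5 ± 4.4 mV, and an SFA distribution tightly clustered
near 1.47 with ~90% of neurons below the sustained/adapting boundary of 2.
Three calibration details are deliberate design choices:

* conductances are calibrated per neuron against the closed-form
  subthreshold response so that the emergent measured `R_pk` and sag ratio -
  not the raw `1/g_L` - equal the drawn targets (the sag current makes the
  measured peak smaller than `I/g_L`);
* the adaptation increment is drawn **relative to the neuron's
  suprathreshold drive margin** at the ~10-spike step (threshold current
  times `exp(-10/tau)/(1 - exp(-10/tau))`). Without this normalization the
  population SFA is strongly confounded by input resistance and time
  constant, which spreads the SFA distribution far beyond the reported one;
* 1.3% of neurons receive strong, slowly decaying adaptation
  (`tau_a = 400 ms`) and fire transiently.

The per-neuron protocol mirrors the stated convention of incrementing
hyperpolarizing steps until the peak passes -110 mV: peak-deflection targets
from -3 mV down to beyond -110 mV absolute, plus depolarizing steps at fixed
multiples (0.9-3.3) of the predicted threshold current. Steps are 100 ms.

What the generator does **not** emulate: voltage-dependent I_h kinetics
(activation is linear in voltage below rest), action-potential waveform
diversity, electrode/series-resistance artifacts, and the near-equality of
the reported population means of R_pk and R_ss (242 vs 240 MΩ). The last
point is a structural property of real I_h - it barely activates over the
small (0 to -15 mV) deflections that enter the R_ss fit but strongly at
-91 mV - that a first-order voltage-linear sag cannot reproduce: with mean
sag ratio 0.87 at -91 mV, the model's R_ss is necessarily ~13% below R_pk.
Passing tests therefore validate the estimators and the R_pk/SFA/sag
statistics, not the R_ss population mean.

# Intrinsic-property extraction

* **Spike detection**: action-potential peaks (>= -20 mV) are located
  first; each spike time is the final sustained upward crossing of the
  dV/dt threshold (default 20 mV/ms, configurable) within 2 ms before its
  peak, with a 1 ms refractory floor. Anchoring on peaks rather than on raw
  slope crossings prevents noise-induced slope blips just before the
  upstroke from registering as extra spikes.
* **V_rest**: mean voltage over the 50 ms preceding step onset, averaged
  across sweeps.
* **R_pk / R_ss**: least-squares slopes of peak (most negative value) and
  steady-state (mean of the last 10 ms of the step) deflections versus
  current, over hyperpolarizing sweeps whose peak deflection lies in
  (0, -15] mV relative to rest.
* **tau_m**: single-exponential fit from step onset to the time of peak
  deflection on each small (1-3 mV steady-state deflection) hyperpolarizing
  sweep; the median across sweeps is returned. The repeated-small-step
  protocol uses 50 repeats by convention.
* **Sag ratio**: `(V_ss - V_rest)/(V_pk - V_rest)` on the sweep whose peak
  is closest to the target (-91 or -111 mV), nearest-sweep within ±3 mV, no
  interpolation between sweeps.
* **Rheobase**: smallest amplitude evoking >= 1 spike, at the protocol's
  resolution.
* **Firing class**: the classification sweep is the suprathreshold sweep
  with spike count closest to 10 (ties to the lower amplitude). Classes:
  `single_spike` if every suprathreshold sweep fired exactly once;
  `transient` if the last spike precedes step offset by more than half the
  step duration; otherwise `sustained` (SFA < 2) or `adapting` (SFA >= 2),
  with SFA = last ISI / first ISI.

Open conventions resolved here: the sag targets are met by nearest-sweep
selection (not interpolation); the tau fit is a single exponential over the
onset-to-peak window; "firing stopped before the end of the current step" is
operationalized as the last spike preceding the offset by more than 50% of
the step duration, which excludes ordinary adaptation from the transient
class.

# Morphometry

Coordinates follow a coronal convention: x medial→lateral, y
dorsal→ventral, z rostro-caudal; all angles are reported in the anatomical
view (dorsal up), counter-clockwise from the medial-lateral axis, in
[0, 180). Right-side reconstructions are mirrored about the soma's sagittal
axis before analysis.

PCA uses dendrite node coordinates only (soma excluded), unweighted by
segment length or radius. Axis extents are coordinate ranges after rotation
into the eigenbasis; the length-to-width ratio is the first extent over the
second from 3D PCA, with ratio < 3 classed stellate and >= 3 disc-shaped.
Orientation comes from 2D (coronal) PCA; eigenvector sign is fixed by a
non-negative medial-lateral component, and near-isotropic arbors (first two
eigenvalues equal within a relative 1e-9) are flagged indeterminate rather
than assigned an arbitrary angle. Laminar spread is the range of the
dendritic coordinates projected on the normal of the 45° laminar line, in
the coronal plane (2D; the laminar plane is defined in the coronal view).

The arbor generator draws node positions from an anisotropic Gaussian whose
axis SDs are `axisLengths/2`, rotated in-plane, and chains each stem's nodes
by increasing somatic distance, yielding valid single-rooted SWC trees with
a controlled primary-dendrite count.

# Stereology

Systematic random sampling places a square grid (default spacing 370 µm)
with a uniformly random origin; one site is retained per grid square that
falls over the section mask (the square's lowest-x/lowest-y intersection is
the site anchor; overlap is probed on a 5x5 lattice inside the square, so
structures smaller than ~1/5 of the spacing can be missed — irrelevant at
tissue scale). Counting frames (default 184 µm) apply the unbiased-frame
rule — right and top borders included, left and bottom excluded — and the
optical-disector rule in depth: a cell is counted if its top lies in the
central counting window (default 15 µm) between guard zones (>= 2 µm).
Because inclusion and exclusion borders are complementary, the estimator
has no systematic edge bias; this is verified by Monte-Carlo uniformity and
unbiasedness tests.

Group estimates report the mean ± SEM of per-sample percentages (the
convention of reporting across systematic random samples) **and** the
pooled counts; the two estimators disagree slightly on skewed small-count
data and are both reported, neither reconciled. The rostro-caudal gradient
is tested with a one-way ANOVA across slice planes plus Tukey HSD.

The synthetic field is a homogeneous Poisson process (default
1.5e5 cells/mm³ over a 1110 x 1110 x 1800 µm box, giving ~70-80 cells per
counting frame and, at 370 µm spacing, roughly 4-9 usable samples per
section — the scale of the real sections) with a linear labeled-fraction
gradient along the rostro-caudal axis.

# Topography

Positions are standardized to the left IC by negating the medial-lateral
coordinate of right-side neurons. Planes `value = a + b*ml + c*dv` are fit
with the Levenberg-Marquardt optimizer (the model is linear, so LM
converges to the normal-equations optimum; the test suite asserts agreement
to 1e-9 on noiseless data). Fit quality: multiple correlation
`r = cor(observed, fitted)` and adjusted R² `1 - (1 - r²)(n - 1)/(n - 3)`
(two predictors). Because the original chi-squared p-value recipe is
under-specified, the primary p-value is the overall-regression F test; a
chi-squared tail probability of the residual sum of squares under
unit-variance weights is also emitted (`pLegacyChisq`) for comparison but
is not used anywhere. The tonotopy report projects the fitted slopes on the
dorsolateral→ventromedial diagonal (the tonotopic axis) and reports the
gradient direction.

The location cohort (`simulateLocationCohort()`) imposes a linear
ventromedially-increasing mean on the sag ratio with residual scatter set
so the expected multiple correlation is 0.536 at n = 60 (signal SD
`0.16 * 0.536`, residual SD `0.16 * sqrt(1 - 0.536²)`); each neuron's sag
ratio is then *measured* from simulated sweeps before fitting.

# PSP kinetics

Sweeps are averaged after per-sweep baseline subtraction (50 ms
pre-stimulus window; the original baseline convention is unstated, 50 ms is
this package's choice). Metrics on the averaged trace: signed amplitude
relative to baseline, 10-90% rise time, full width at half amplitude with
linear interpolation between samples (no smoothing by default), and a decay
time constant fit from the peak down to the return-to-20%-of-amplitude
point — the 20% cutoff keeps delayed IPSPs in mixed traces out of the fit
window.

The generator builds each PSP component as a unit-peak difference of
exponentials. Defaults encode the DCN-input EPSP: amplitude 2.85 mV and
time constants (rise 4.4 ms, decay 14.3 ms) solved numerically so the
noise-free waveform measures a 4.2 ms 10-90% rise and a 20.6 ms halfwidth.
The feedforward IPSP follows the EPSP onset by 2.5 ms (the disynaptic
latency, 2-3 ms) with slower kinetics (rise 4, decay 35 ms). Condition
semantics: gabazine removes the IPSP, NBQX the EPSP, TTX everything evoked;
strychnine and AP5 leave the waveform unchanged because no glycinergic or
NMDA component is modeled — passing condition tests therefore validates
bookkeeping, not receptor pharmacology.

Condition comparisons are paired: a paired two-tailed t-test for two
conditions, and for three or more the subject-blocked two-way ANOVA
`aov(value ~ cell + condition)` with Tukey HSD on the condition term (the
classic repeated-measures arithmetic), with a Bonferroni critical p of
0.0125 attached for four-metric workflows. The feedforward-inhibition
effect is `100 (hw_gabazine - hw_control)/hw_gabazine`: the disinhibited
(gabazine) halfwidth is the reference because GABA_A block restores the
full-width EPSP; the control-denominator variant is also returned. The
five-cell experiment (`simulateFFIExperiment()`) fixes five relative IPSP
strengths (0.33-0.83 of the EPSP amplitude) chosen so the resulting
halfwidth reductions span ~22-73% with a median near 36%, the reported
range of the effect.

# Statistics and reporting

Two-group contrasts use the Wilcoxon rank-sum test (exact for small untied
samples, normal approximation with tie correction otherwise — the variant
used by the original software is unstated) or Welch's t-test, with mean ±
SD descriptives. Exactness is verified against full enumeration of rank
assignments for n <= 10. Proportions are rounded to the study's printed
precision (one decimal for physiology tallies, integers for morphology);
underlying tables keep full precision. `buildReport()` merges the
per-neuron tables by id and recomputes every summary from the merged table,
so no report number has hidden state.

# Problem sizes and determinism

All randomness flows through explicit integer seeds; identical
configuration and seed give bitwise-identical output. Sizes used by the
bundled validation runs (chosen to keep full runs at desktop scale while
matching the study's sample sizes where those matter): intrinsic cohort
n = 216 (the recorded-cohort scale), parameter-recovery suite n = 50
neurons with 10 repeats of the small-step protocol, plane-fit cohorts
n = 60 with 20 replicate cohorts averaged, stereology 16 replicate fields
of ~330k cells each, 200-400 null-fit replicates. The repeated-small-step
tau protocol supports the conventional 50 repeats; validation runs use
10-15 repeats, which already bring the median tau error well under the 5%
criterion.

# Known limitations

* The membrane model is phenomenological: no conductance-based spike
  mechanism, no voltage-dependent I_h kinetics; R_ss population means sit
  below the reported value as discussed above.
* The transient class is produced by strong slow adaptation; real transient
  neurons may rely on inactivating channels with different subthreshold
  signatures.
* Morphometry treats reconstruction nodes as the coordinate sample;
  node-density-weighted and length-resampled variants would differ for
  very unevenly digitized arbors.
* The stereology grid probes square/region overlap on a finite lattice;
  pathological masks thinner than ~spacing/5 can be under-sampled.
* Plane fits assume independent residuals; spatial autocorrelation in real
  cohorts would make the F-test anti-conservative.
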