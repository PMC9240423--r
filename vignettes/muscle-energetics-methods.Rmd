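---
title: "Models and methods: dynamic 31P-MRS, T2 mapping and twitch-force analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: dynamic 31P-MRS, T2 mapping and twitch-force analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscleMRS)
```

# Overview

`muscleMRS` analyses a rest–stimulation–recovery protocol in mouse hindlimb
muscle that combines three synchronous data streams: dynamic phosphorus
magnetic resonance spectroscopy (³¹P-MRS) of the energy-phosphate pool,
multi-echo T2-weighted imaging, and isometric twitch-force recordings from a
pedal ergometer. The package covers the full chain from raw (or simulated)
acquisitions to cohort-level group statistics. This vignette explains the
models, the assumptions behind them, the tunable parameters, and the design
choices made where reasonable alternatives existed.

# The acquisition model

The spectroscopy arm acquires a train of 800 saturated free induction
decays (FIDs) at a repetition time of 1.875 s: 140 at rest, 450 during a
stimulated exercise bout, and 210 during metabolic recovery. For
signal-to-noise, FIDs are summed in blocks — all 140 rest FIDs into one
reference bin, exercise FIDs in blocks of 15 (28.125 s resolution) and
recovery FIDs in blocks of 30 (56.25 s). `acquisitionProtocol()` holds
these counts together with the spectral sampling (8 kHz sweep width, 2048
complex points) and the stimulation timing (1 Hz twitches for a nominal
6 min).

One deliberate convention: all bin times are derived from FID counts times
TR, never from nominal phase durations. The counts imply an exercise phase
of about 14 min of spectra while stimulation is nominally 6 min; the two
cannot both be taken literally, and counts × TR is the only timeline that
is internally consistent with the data layout. Force is aligned on the same
clock (see below), and exercise bins after the last stimulus are simply
empty and flagged.

The spectrometer frequency (default 121.5 MHz, the ³¹P frequency at 7 T)
only converts ppm to Hz; it cancels out of every reported quantity.

# Spectral quantification

Each summed block is fitted in the time domain as a sum of exponentially
damped complex sinusoids — Lorentzian lines, the standard lineshape for
in vivo ³¹P work — under prior knowledge in the AMARES tradition:

* five resonances: PCr (the 0-ppm shift reference), Pi, and the γ-, α- and
  β-ATP multiplets;
* fixed multiplet structure: 1:1 doublets for γ/α-ATP, a 1:2:1 triplet for
  β-ATP, J = 16.5 Hz;
* group chemical shifts free within bounds; the Pi shift is bounded by the
  open interval (3.27, 5.69) ppm on which the pH calibration is defined;
* one damping factor per multiplet, bounded; one zero-order phase shared by
  all peaks; first-order phase fixed at zero (the forward model generates
  data accordingly).

The fit minimizes the stacked real and imaginary residuals with
Levenberg–Marquardt (`minpack.lm`), initialised by peak-picking on the DFT
magnitude spectrum within each prior's bounds (falling back to the nominal
shift) followed by a linear least-squares solve for the amplitudes. The
highest-magnitude candidate wins ties. Convergence uses a cost tolerance of
1e-10 with at most 500 iterations (both configurable); a block that fails
to converge is flagged, never silently dropped, and an all-zero block
returns zero amplitudes with a flag. Because rest, exercise and recovery
blocks sum different numbers of FIDs, amplitudes are normalized per
constituent FID before any downstream use.

None of the prior-knowledge values (nominal shifts, J, bounds) is claimed
to be a measured property of the reference data set; they are standard
³¹P muscle conventions and all are configurable through `peakPrior()`.

# From amplitudes to physiology

Three conversions, in order:

* **Absolute concentrations.** A single scale factor — 5 mM divided by the
  resting β-ATP amplitude — converts amplitudes to mM. The result is
  invariant under any global rescaling of the raw signal.
* **Intracellular pH** from the Pi–PCr shift difference δ via
  pH = 6.75 + log₁₀((3.27 − δ)/(δ − 5.69)). The formula is defined on
  (3.27, 5.69) ppm and is strictly increasing in δ there; the package also
  ships the exact algebraic inverse (`shiftFromPh()`), so pH → shift → pH
  round-trips to machine precision. "log" is read as log₁₀, the standard
  for this calibration — the natural log would produce non-physiologic pH.
  A bin whose Pi fit failed or fell outside the domain carries `NA` pH with
  a flag; missing bins are excluded from downstream fits, never
  interpolated.
* **Free cytosolic ADP** from the creatine-kinase equilibrium,
  [ADP] = ([Cr][ATP])/([PCr]·10^(−pH)·K_CK) with K_CK = 1.66×10⁹ M⁻¹. The
  creatine pool is fixed at rest — total Cr = resting PCr / 0.85 — and free
  Cr is that pool minus current PCr. Pool conservation is the physiologic
  assumption the formula requires; computing it per bin would let
  measurement noise masquerade as creatine synthesis. Whether [ATP] in the
  numerator tracks the per-bin fitted β-ATP (default) or stays clamped at
  5 mM is a documented switch (`atp_mode`), since either reading is
  defensible.

# PCr kinetics and energetic indices

PCr depletion during exercise and resynthesis during recovery are each fit
by a mono-exponential — `P_end + ΔPCr·exp(−t/τ)` and
`P₀ + ΔPCr·(1 − exp(−t/τ))` — with uniform weights, times measured from
stimulation onset and exercise end respectively. A constant series is
flagged (τ unidentifiable) rather than fitted, and τ pinned at its search
bounds is treated as non-converged.

Derived indices follow their defining ratios: VPCr = ΔPCr/τ for each phase
(the ΔPCr feeding each rate comes from that phase's own fit — the two can
differ under noise and both are reported); Vmax = VPCr_rec·(1 + Km/[ADP_end])
with Km = 30 µM, the mitochondrial ADP affinity in mouse gastrocnemius;
and the force-normalized costs, VPCr_stim divided by begin-exercise force
and VPCr_rec by end-exercise force. The begin/end force windows are defined
as the twitch-peak sums inside the first and last stimulated MRS exercise
bin — the one definition that keeps energetics and force on a single clock.
The cost ratio is reported in (mM·min⁻¹)/N with an explicit `scale`
argument for the ×1000 reporting convention; no tissue-volume unit
conversion is guessed.

# T2 mapping and volumetry

Every pixel of a multi-echo stack (16 echoes, 7.28–116.59 ms by default) is
fitted with the two-parameter single exponential S(TE) = S0·exp(−TE/T2) —
no offset term, matching the single-exponential convention for these
acquisitions. The default estimator is Levenberg–Marquardt on the signal
scale initialised by log-linear regression; a pure log-linear mode exists
for speed. Non-positive or non-decaying pixels are flagged invalid and
excluded from ROI means, with the count reported. ROI summaries average the
two consecutive slices with the largest summed ROI pixel count.

Muscle volume uses the truncated-cone rule on per-slice ROI areas: slices
contribute A·thickness, gaps contribute frustums
(g/3)·(A_i + A_j + √(A_i·A_j)). Defaults (1 mm slices, 0.25 mm gaps, six
slices) follow the anatomical acquisition geometry. The multi-echo
acquisition's own 1 mm gap is irrelevant here — T2 ROI means are
gap-agnostic — so the volumetric geometry is the anatomical one.

# Force analysis

Twitches are detected per stimulus: the peak is the force maximum in
[stimulus, next stimulus), baseline-corrected by the median of the 50 ms
preceding the pulse (the response onset sample when no pre-stimulus data
exist), making detection invariant to DC offsets. Total force production
(TFP) is the sum of baseline-corrected twitch *peaks* — consistent with
quantifying peak force per twitch — not the force–time integral. Specific
values are exact divisions by muscle volume with explicit unit labels
(peak force per cm³, TFP per mm³); the package reproduces this arithmetic
as defined and does not attempt to reconcile the published magnitude of
specific force with mN-scale twitches, which would require an undocumented
unit convention.

# The synthetic generator

`generateFidSeries()` realizes the forward model with known ground truth:
PCr constant at rest, mono-exponential decline toward
(1 + depletion)·rest during exercise, mono-exponential return during
recovery; Pi mirrors PCr exactly (pool conservation); the Pi shift tracks
pH through the exact inverse calibration; ATP multiplets constant; additive
i.i.d. complex Gaussian noise per point (Rician magnitude noise for
images). Defaults are a control-like animal: 16 mM resting PCr (chosen so
the creatine-kinase arithmetic lands at a plausible ~48 µM end-exercise
ADP), −56.45 % depletion, τ = 1.57/2.19 min, resting pH 7.25 falling by
0.28 units. The pH time course is simplified to the same two-phase
mono-exponential as PCr; the in vivo transient alkalinization at exercise
onset is deliberately not modelled.

The force generator emits one alpha-function twitch per 1 Hz stimulus with
a biphasic peak-force envelope rising from its initial value to a peak at
90 s and declining thereafter. Cohort draws (`generateCohort()`) take
per-animal parameters from group-level normal distributions; the default
specs encode the control and hydroxyurea-treated groups (n = 9/8) of the
reference cohort, and clamping keeps tail draws inside physiologic domains.

What the generator does *not* emulate — and therefore what passing
recovery tests do not establish about real data: saturation factors, B0/B1
inhomogeneity, baseline distortions, eddy currents, motion, multi-compartment
Pi, or non-Lorentzian lineshapes. Closure tests demonstrate that the
inverse path is faithful to this forward model, not that the forward model
is a complete account of the scanner.

# Numerical behaviour and known limitations

* **Problem sizes.** Validation runs use the full 800-FID protocol at 2048
  points for the headline closure checks and a reduced protocol (same block
  structure, fewer/shorter FIDs) for unit tests; Monte-Carlo suites use 200
  replicates at 512 points.
* **Closure accuracy.** On noiseless data the direct kinetic fits and the
  T2 map recover ground truth to better than 1e-6 relative. Through the
  full spectral path, τ_stim, depletion and pH close to ≤1e-3 while τ_rec
  is limited to ~2e-3: the Pi line moves as pH recovers, so a 30-FID
  recovery block contains a smeared line that a single Lorentzian absorbs
  with a small amplitude bias, concentrated in the first recovery bin. The
  same mechanism makes summed-block PCr+Pi totals deviate by a few percent
  in early recovery even though conservation is exact per FID. This is an
  intrinsic property of fitting summed dynamic spectra, not an optimizer
  tolerance.
* **Degenerate inputs.** All-zero blocks, constant kinetic series,
  non-decaying pixels and empty ROIs are flagged or rejected explicitly;
  tie-breaks in spectral initialisation take the highest-magnitude DFT
  candidate.
* **Statistics.** Group comparison mirrors the reference analysis:
  Shapiro–Wilk on each group at α = 0.05 (both groups must pass) gating
  Welch's t-test versus the Wilcoxon rank-sum test, with the choice
  recorded per variable. No multiple-testing correction is applied by
  default, matching the reference analysis; `p.adjust` can be applied to
  the returned column when desired.

# A worked example

```{r example, eval = FALSE}
protocol <- acquisitionProtocol()
truth <- kineticsGroundTruth()           # control-like ground truth
series <- generateFidSeries(protocol, truth)
quant <- quantifySeries(series)
metab <- buildMetaboliteSeries(quant, protocol)
trace <- generateForceTrace(protocol)
vol <- truncatedConeVolume(c(20, 26, 29, 29, 26, 20))
force <- forceSummary(trace, protocol, vol)
summarizeKinetics(metab, force)
```

The README shows this pipeline with the numbers it prints.
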