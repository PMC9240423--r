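# muscleMRS

Analysis of skeletal-muscle energetics and function from a
rest–stimulation–recovery protocol in the mouse hindlimb, combining three
synchronous measurement arms:

* **dynamic ³¹P-MRS** — phosphocreatine (PCr), inorganic phosphate (Pi) and
  ATP quantified over a rest / 1 Hz-stimulation / recovery time course;
* **multi-echo T2-weighted MRI** — pixel-wise T2 maps and muscle volumetry;
* **isometric twitch force** — per-twitch peak forces from an ergometer
  trace, normalized to muscle volume.

The intended users are muscle-physiology and preclinical-MR groups who run
stimulation protocols of this kind (for example to compare a treated and a
control cohort) and want the complete, tested analysis chain rather than
per-lab scripts. A synthetic-data generator reproduces the whole
acquisition with known ground truth, so every stage of the inverse path is
validated by forward–inverse closure.

## The models at the core

**Spectral quantification.** Each summed FID block is modelled in the time
domain as a sum of damped complex sinusoids (Lorentzian lines) under
AMARES-style prior knowledge — fixed ATP multiplet ratios (1:1 doublets,
1:2:1 triplet, J = 16.5 Hz), bounded shifts and dampings, one shared
zero-order phase — and fitted by Levenberg–Marquardt on the stacked
real/imaginary residuals.

**Physiology.** With δ the Pi–PCr shift difference (ppm):

    pH    = 6.75 + log10((3.27 − δ)/(δ − 5.69))
    [ADP] = ([Cr][ATP]) / ([PCr]·10^(−pH)·K_CK),   K_CK = 1.66e9 M⁻¹

Concentrations are anchored to 5 mM basal β-ATP; the creatine pool is fixed
at rest via PCr/Cr = 0.85.

**Kinetics.** PCr depletion and recovery are mono-exponential fits
(`P_end + ΔPCr·e^(−t/τ)` and `P₀ + ΔPCr·(1 − e^(−t/τ))`), giving

    VPCr_stim = ΔPCr/τ_stim        VPCr_rec = ΔPCr/τ_rec
    Vmax      = VPCr_rec · (1 + Km/[ADP_end]),   Km = 30 µM
    PCr_cost  = VPCr_stim / force(begin exercise)

**Imaging.** Per-pixel `S(TE) = S0·e^(−TE/T2)` (two parameters, no offset);
ROI means over the two largest consecutive slices; muscle volume by the
truncated-cone rule over per-slice ROI areas.

**Force.** Peak force per 1 Hz stimulus (baseline-corrected window
maximum), total force production (TFP) as the sum of twitch peaks, specific
values as exact division by muscle volume.

## A worked example

Simulate a control-like animal on the reference protocol (800 FIDs at
TR 1.875 s; 140 rest / 450 exercise in blocks of 15 / 210 recovery in
blocks of 30) and run the full analysis:

```r
library(muscleMRS)

protocol <- acquisitionProtocol()
truth    <- kineticsGroundTruth()       # -56.45 % depletion, tau 1.57/2.19 min
series   <- generateFidSeries(protocol, truth)
quant    <- quantifySeries(series)      # AMARES-style fit of all 38 bins
metab    <- buildMetaboliteSeries(quant, protocol)
metab
#> MetaboliteTimeSeries: 38 bins ( exercise=30, recovery=7, rest=1 )
#>   end-exercise PCr % of rest: 43.56
#>   resting pH: 7.250

trace <- generateForceTrace(protocol)   # 360 twitches, biphasic envelope
vol   <- truncatedConeVolume(c(20, 26, 29, 29, 26, 20))  # mm^3 from slice areas
force <- forceSummary(trace, protocol, vol)
summarizeKinetics(metab, force)
#> KineticsResult
#>   tau_stim 1.570 min, tau_rec 2.188 min
#>   depletion -56.44 % of rest
#>   VPCr_stim 5.774, VPCr_rec 4.163, Vmax 6.775 mM/min
#>   ADP_end 47.82 uM
```

The fitted time constants and depletion reproduce the generator's ground
truth (1.57 min, 2.19 min, −56.45 %) through the complete spectral path;
`Vmax` is the ADP-corrected maximal oxidative capacity; `ADP_end` the
creatine-kinase-equilibrium ADP at the last exercise bin. The same applies
to imaging:

```r
stack <- generateMultiechoStack(c(8, 8), defaultEchoTimes(), 30.79, n_slice = 2)
roiMeanT2(fitT2Map(stack), array(1L, c(8, 8, 2)), 1L)$mean_t2_ms
#> [1] 30.79
```

Cohort-level work uses `generateCohort()` (per-animal draws from
group-level normal specs), `simulateAnimal()` / `runAnimal()` for the
per-animal bundle, and `compareGroups()` for Shapiro–Wilk-gated
Welch/Wilcoxon comparisons with the chosen test recorded per variable.

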