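#' Acquisition protocol for the rest-stimulation-recovery experiment
#'
#' Describes the dynamic 31P-MRS acquisition: a train of saturated free
#' induction decays (FIDs) at fixed repetition time covering a resting
#' baseline, an electrically stimulated exercise bout and a metabolic
#' recovery period, plus the spectral sampling parameters and the 1 Hz
#' stimulation timing used by the force arm of the protocol.
#'
#' @slot tr_s repetition time between FIDs (s)
#' @slot n_rest,n_exercise,n_recovery FID counts per phase
#' @slot block_exercise,block_recovery FIDs summed per exercise / recovery block
#' @slot sweep_hz spectral width (Hz)
#' @slot n_points complex points per FID
#' @slot stim_freq_hz twitch stimulation rate (Hz)
#' @slot exercise_duration_s nominal stimulation duration (s)
#' @slot f0_mhz 31P spectrometer frequency (MHz); converts ppm to Hz
#'
#' @details The rest phase is summed into a single high-SNR block; exercise
#' and recovery FIDs are summed in blocks of \code{block_exercise} and
#' \code{block_recovery} respectively, setting the temporal resolution of the
#' metabolite time series. Note the FID counts, not the nominal durations,
#' define the timeline: bin times are always \code{counts * tr_s}.
#'
#' @export
setClass("AcquisitionProtocol",
  representation(
    tr_s = "numeric",
    n_rest = "integer", n_exercise = "integer", n_recovery = "integer",
    block_exercise = "integer", block_recovery = "integer",
    sweep_hz = "numeric", n_points = "integer",
    stim_freq_hz = "numeric", exercise_duration_s = "numeric",
    f0_mhz = "numeric"
  )
)

setValidity("AcquisitionProtocol", function(object) {
  msg <- character()
  counts <- c(object@n_rest, object@n_exercise, object@n_recovery,
              object@block_exercise, object@block_recovery, object@n_points)
  if (any(counts <= 0L)) msg <- c(msg, "all counts must be positive")
  if (object@tr_s <= 0) msg <- c(msg, "tr_s must be > 0")
  if (object@sweep_hz <= 0) msg <- c(msg, "sweep_hz must be > 0")
  if (object@n_exercise %% object@block_exercise != 0L)
    msg <- c(msg, "n_exercise must be divisible by block_exercise")
  if (object@n_recovery %% object@block_recovery != 0L)
    msg <- c(msg, "n_recovery must be divisible by block_recovery")
  if (object@stim_freq_hz <= 0) msg <- c(msg, "stim_freq_hz must be > 0")
  if (object@exercise_duration_s <= 0) msg <- c(msg, "exercise_duration_s must be > 0")
  if (object@f0_mhz <= 0) msg <- c(msg, "f0_mhz must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an acquisition protocol
#'
#' Defaults reproduce the reference protocol: 800 FIDs at TR 1.875 s
#' (140 rest summed together, 450 exercise summed as blocks of 15, 210
#' recovery summed as blocks of 30), 8 kHz sweep width, 2048 points,
#' 1 Hz stimulation for 6 min.
#'
#' @param tr_s repetition time (s)
#' @param n_rest,n_exercise,n_recovery FID counts per phase
#' @param block_exercise,block_recovery FIDs per summed block
#' @param sweep_hz spectral width (Hz)
#' @param n_points complex points per FID
#' @param stim_freq_hz stimulation rate (Hz)
#' @param exercise_duration_s nominal stimulation duration (s)
#' @param f0_mhz spectrometer frequency (MHz)
#' @return an \linkS4class{AcquisitionProtocol}
#' @examples
#' p <- acquisitionProtocol()
#' nBins(p)  # 1 rest + 30 exercise + 7 recovery
#' @export
acquisitionProtocol <- function(tr_s = 1.875,
                                n_rest = 140L, n_exercise = 450L, n_recovery = 210L,
                                block_exercise = 15L, block_recovery = 30L,
                                sweep_hz = 8000, n_points = 2048L,
                                stim_freq_hz = 1, exercise_duration_s = 360,
                                f0_mhz = 121.5) {
  new("AcquisitionProtocol",
      tr_s = tr_s,
      n_rest = as.integer(n_rest), n_exercise = as.integer(n_exercise),
      n_recovery = as.integer(n_recovery),
      block_exercise = as.integer(block_exercise),
      block_recovery = as.integer(block_recovery),
      sweep_hz = sweep_hz, n_points = as.integer(n_points),
      stim_freq_hz = stim_freq_hz, exercise_duration_s = exercise_duration_s,
      f0_mhz = f0_mhz)
}

#' Number of summed spectral bins implied by a protocol
#'
#' @param protocol an \linkS4class{AcquisitionProtocol}
#' @return named integer vector (rest, exercise, recovery)
#' @export
nBins <- function(protocol) {
  stopifnot(is(protocol, "AcquisitionProtocol"))
  c(rest = 1L,
    exercise = protocol@n_exercise %/% protocol@block_exercise,
    recovery = protocol@n_recovery %/% protocol@block_recovery)
}

#' Ground-truth physiology driving the synthetic forward model
#'
#' Holds the per-animal parameters the generator turns into FIDs: basal PCr,
#' the end-exercise depletion (as a negative fraction of rest), the two
#' mono-exponential time constants, the pH excursion realized through the Pi
#' chemical shift, and the per-point complex noise level.
#'
#' @slot pcr_rest_mM basal PCr concentration (mM)
#' @slot pi_rest_mM basal Pi concentration (mM)
#' @slot atp_mM basal beta-ATP concentration (mM); also the quantification anchor
#' @slot depletion_frac end-exercise PCr change as a fraction of rest (in (-1, 0))
#' @slot tau_stim_min,tau_rec_min depletion / recovery time constants (min)
#' @slot ph_rest,ph_end_exercise intracellular pH at rest and end of exercise
#' @slot noise_sd additive complex Gaussian noise SD per FID point
#' @slot seed RNG seed
#' @export
setClass("KineticsGroundTruth",
  representation(
    pcr_rest_mM = "numeric", pi_rest_mM = "numeric", atp_mM = "numeric",
    depletion_frac = "numeric", tau_stim_min = "numeric", tau_rec_min = "numeric",
    ph_rest = "numeric", ph_end_exercise = "numeric",
    noise_sd = "numeric", seed = "integer"
  )
)

setValidity("KineticsGroundTruth", function(object) {
  msg <- character()
  if (!(object@depletion_frac > -1 && object@depletion_frac <= 0))
    msg <- c(msg, "depletion_frac must be in (-1, 0]")
  if (object@tau_stim_min <= 0 || object@tau_rec_min <= 0)
    msg <- c(msg, "tau values must be > 0")
  for (p in c(object@ph_rest, object@ph_end_exercise))
    if (!(p > 6.0 && p < 7.8)) msg <- c(msg, "pH must lie in (6.0, 7.8)")
  if (object@pcr_rest_mM <= 0 || object@pi_rest_mM <= 0 || object@atp_mM <= 0)
    msg <- c(msg, "basal concentrations must be > 0")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct synthetic ground truth
#'
#' Defaults give a control-like animal: 16 mM basal PCr, -56.45 % depletion,
#' tau_stim 1.57 min, tau_rec 2.19 min, resting pH 7.25 falling by 0.28 units
#' at end of exercise.
#'
#' @param pcr_rest_mM,pi_rest_mM,atp_mM basal concentrations (mM)
#' @param depletion_frac end-exercise PCr change, fraction of rest (negative)
#' @param tau_stim_min,tau_rec_min time constants (min)
#' @param ph_rest,ph_end_exercise intracellular pH values
#' @param noise_sd complex noise SD per FID point (0 = noiseless)
#' @param seed RNG seed
#' @return a \linkS4class{KineticsGroundTruth}
#' @export
kineticsGroundTruth <- function(pcr_rest_mM = 16, pi_rest_mM = 1.8, atp_mM = 5,
                                depletion_frac = -0.5645,
                                tau_stim_min = 1.57, tau_rec_min = 2.19,
                                ph_rest = 7.25, ph_end_exercise = 6.97,
                                noise_sd = 0, seed = 1L) {
  new("KineticsGroundTruth",
      pcr_rest_mM = pcr_rest_mM, pi_rest_mM = pi_rest_mM, atp_mM = atp_mM,
      depletion_frac = depletion_frac,
      tau_stim_min = tau_stim_min, tau_rec_min = tau_rec_min,
      ph_rest = ph_rest, ph_end_exercise = ph_end_exercise,
      noise_sd = noise_sd, seed = as.integer(seed))
}

#' Series of complex free induction decays
#'
#' One row per acquisition, ordered in time; the protocol fixes the dwell
#' time and the phase labels partition the rows into rest / exercise /
#' recovery. When produced by \code{\link{generateFidSeries}} the generating
#' ground truth travels along in \code{truth}.
#'
#' @slot fids complex matrix [n_acq x n_points]
#' @slot protocol the \linkS4class{AcquisitionProtocol}
#' @slot phase character vector, one of rest / exercise / recovery per row
#' @slot truth the generating \linkS4class{KineticsGroundTruth}, or NULL
#' @export
setClass("FIDSeries",
  representation(fids = "matrix", protocol = "AcquisitionProtocol",
                 phase = "character", truth = "ANY")
)

setValidity("FIDSeries", function(object) {
  msg <- character()
  if (!is.complex(object@fids)) msg <- c(msg, "fids must be a complex matrix")
  if (ncol(object@fids) != object@protocol@n_points)
    msg <- c(msg, "n_points mismatch between fids and protocol")
  if (nrow(object@fids) != length(object@phase))
    msg <- c(msg, "one phase label per acquisition required")
  if (!all(object@phase %in% c("rest", "exercise", "recovery")))
    msg <- c(msg, "phase labels must be rest/exercise/recovery")
  # acquisitions must be ordered rest -> exercise -> recovery
  r <- rle(object@phase)$values
  if (!identical(r, r[order(match(r, c("rest", "exercise", "recovery")))]) ||
      anyDuplicated(r))
    msg <- c(msg, "acquisitions must be time-ordered rest, exercise, recovery")
  if (length(msg)) msg else TRUE
})

#' @describeIn nAcquisitions rows of the FID matrix
#' @export
setMethod("nAcquisitions", "FIDSeries", function(object) nrow(object@fids))

#' @describeIn fidMatrix complex matrix accessor
#' @export
setMethod("fidMatrix", "FIDSeries", function(object) object@fids)

#' @describeIn protocol protocol of an FID series
#' @export
setMethod("protocol", "FIDSeries", function(object) object@protocol)

#' @describeIn phaseLabels per-acquisition labels
#' @export
setMethod("phaseLabels", "FIDSeries", function(object) object@phase)

setMethod("show", "FIDSeries", function(object) {
  p <- object@protocol
  cat("FIDSeries:", nrow(object@fids), "acquisitions x",
      ncol(object@fids), "points\n")
  cat("  phases:", paste(sprintf("%s=%d", names(table(object@phase)),
                                 table(object@phase)), collapse = ", "), "\n")
  cat(sprintf("  TR %.3f s, sweep %.0f Hz, f0 %.1f MHz\n",
              p@tr_s, p@sweep_hz, p@f0_mhz))
  if (!is.null(object@truth)) cat("  ground truth attached\n")
})

#' Metabolite time series derived from fitted spectra
#'
#' Per-bin physiological quantities: PCr as a percentage of the resting
#' value, absolute concentrations anchored to basal beta-ATP, the Pi
#' chemical shift, intracellular pH and free cytosolic ADP.
#'
#' @slot data data.frame, one row per bin (time_min, phase, pcr_pct, pcr_mM,
#'   pi_mM, atp_mM, shift_pi_ppm, ph, adp_uM, converged, ph_valid)
#' @slot constants the \code{\link{physioConstants}} list used
#' @slot exercise_start_min,recovery_start_min phase boundaries (min)
#' @export
setClass("MetaboliteTimeSeries",
  representation(data = "data.frame", constants = "list",
                 exercise_start_min = "numeric", recovery_start_min = "numeric")
)

setValidity("MetaboliteTimeSeries", function(object) {
  need <- c("time_min", "phase", "pcr_pct", "pcr_mM", "pi_mM", "atp_mM",
            "shift_pi_ppm", "ph", "adp_uM", "converged", "ph_valid")
  if (!all(need %in% names(object@data)))
    return(paste("data must contain columns:", paste(need, collapse = ", ")))
  if (is.unsorted(object@data$time_min)) return("bins must be time-ordered")
  TRUE
})

#' @describeIn asTable per-bin metabolite table
#' @export
setMethod("asTable", "MetaboliteTimeSeries", function(object, ...) object@data)

#' @describeIn phaseLabels per-bin labels
#' @export
setMethod("phaseLabels", "MetaboliteTimeSeries", function(object) object@data$phase)

setMethod("show", "MetaboliteTimeSeries", function(object) {
  d <- object@data
  cat("MetaboliteTimeSeries:", nrow(d), "bins (",
      paste(sprintf("%s=%d", names(table(d$phase)), table(d$phase)),
            collapse = ", "), ")\n")
  i <- which(d$phase == "exercise")
  if (length(i))
    cat(sprintf("  end-exercise PCr %% of rest: %.2f\n", d$pcr_pct[max(i)]))
  cat(sprintf("  resting pH: %.3f\n", d$ph[1L]))
})

#' PCr kinetics and derived energetic indices
#'
#' Scalar results of the mono-exponential depletion / recovery fits and the
#' indices built from them. \code{v_max_mM_per_min} is the ADP-corrected
#' maximal oxidative capacity VPCr_rec * (1 + Km/[ADP_end]).
#'
#' @slot tau_stim_min,tau_rec_min fitted time constants (min)
#' @slot delta_pcr_mM_stim,delta_pcr_mM_rec fitted depletion amplitudes (mM)
#' @slot delta_pcr_pct end-exercise depletion vs rest (%, negative)
#' @slot v_pcr_stim_mM_per_min,v_pcr_rec_mM_per_min initial rates (mM/min)
#' @slot pcr_cost,pcr_rec_cost force-normalized indices (see \code{\link{pcrCost}})
#' @slot v_max_mM_per_min ADP-corrected maximal rate (mM/min)
#' @slot adp_end_uM end-exercise ADP (uM)
#' @slot diagnostics list: per-fit RSS, n points, convergence flags
#' @export
setClass("KineticsResult",
  representation(
    tau_stim_min = "numeric", tau_rec_min = "numeric",
    delta_pcr_mM_stim = "numeric", delta_pcr_mM_rec = "numeric",
    delta_pcr_pct = "numeric",
    v_pcr_stim_mM_per_min = "numeric", v_pcr_rec_mM_per_min = "numeric",
    pcr_cost = "numeric", pcr_rec_cost = "numeric",
    v_max_mM_per_min = "numeric", adp_end_uM = "numeric",
    diagnostics = "list"
  )
)

#' @describeIn asTable one-row summary of kinetics scalars
#' @export
setMethod("asTable", "KineticsResult", function(object, ...) {
  data.frame(
    tau_stim_min = object@tau_stim_min, tau_rec_min = object@tau_rec_min,
    delta_pcr_mM_stim = object@delta_pcr_mM_stim,
    delta_pcr_mM_rec = object@delta_pcr_mM_rec,
    delta_pcr_pct = object@delta_pcr_pct,
    v_pcr_stim_mM_per_min = object@v_pcr_stim_mM_per_min,
    v_pcr_rec_mM_per_min = object@v_pcr_rec_mM_per_min,
    pcr_cost = object@pcr_cost, pcr_rec_cost = object@pcr_rec_cost,
    v_max_mM_per_min = object@v_max_mM_per_min,
    adp_end_uM = object@adp_end_uM
  )
})

setMethod("show", "KineticsResult", function(object) {
  cat("KineticsResult\n")
  cat(sprintf("  tau_stim %.3f min, tau_rec %.3f min\n",
              object@tau_stim_min, object@tau_rec_min))
  cat(sprintf("  depletion %.2f %% of rest\n", object@delta_pcr_pct))
  cat(sprintf("  VPCr_stim %.3f, VPCr_rec %.3f, Vmax %.3f mM/min\n",
              object@v_pcr_stim_mM_per_min, object@v_pcr_rec_mM_per_min,
              object@v_max_mM_per_min))
  cat(sprintf("  ADP_end %.2f uM\n", object@adp_end_uM))
})

#' Multi-echo magnitude image stack
#'
#' Magnitude images over echoes and slices; pixel signal follows
#' S(TE) = S0 exp(-TE/T2).
#'
#' @slot data numeric array [H x W x n_echo x n_slice]
#' @slot te_ms echo times (ms), strictly increasing
#' @slot thickness_mm slice thickness (mm)
#' @slot gap_mm inter-slice gap (mm)
#' @export
setClass("EchoImageStack",
  representation(data = "array", te_ms = "numeric",
                 thickness_mm = "numeric", gap_mm = "numeric")
)

setValidity("EchoImageStack", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4-D array [H, W, echo, slice]")
  else if (dim(object@data)[3L] != length(object@te_ms))
    msg <- c(msg, "third dimension must match length(te_ms)")
  if (length(object@te_ms) && (is.unsorted(object@te_ms, strictly = TRUE) ||
      any(object@te_ms <= 0)))
    msg <- c(msg, "te_ms must be strictly increasing and positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn echoTimes echo times of a stack
#' @export
setMethod("echoTimes", "EchoImageStack", function(object) object@te_ms)

setMethod("show", "EchoImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("EchoImageStack: %d x %d pixels, %d echoes, %d slices\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  TE %.2f..%.2f ms; thickness %.2f mm, gap %.2f mm\n",
              min(object@te_ms), max(object@te_ms),
              object@thickness_mm, object@gap_mm))
})

#' Pixel-wise T2 map
#'
#' @slot t2_ms,s0 numeric arrays [H x W x n_slice]; NA where invalid
#' @slot valid logical array of fit validity
#' @export
setClass("T2Map",
  representation(t2_ms = "array", s0 = "array", valid = "array")
)

setValidity("T2Map", function(object) {
  if (!identical(dim(object@t2_ms), dim(object@s0)) ||
      !identical(dim(object@t2_ms), dim(object@valid)))
    return("t2_ms, s0 and valid must share dimensions")
  if (any(object@t2_ms[object@valid] <= 0, na.rm = TRUE))
    return("valid pixels must have T2 > 0")
  TRUE
})

#' @describeIn t2Values per-pixel T2 accessor
#' @export
setMethod("t2Values", "T2Map", function(object) object@t2_ms)

setMethod("show", "T2Map", function(object) {
  cat(sprintf("T2Map: %s pixels, %d invalid\n",
              paste(dim(object@t2_ms), collapse = " x "),
              sum(!object@valid)))
  v <- object@t2_ms[object@valid]
  if (length(v))
    cat(sprintf("  T2 range %.2f..%.2f ms (median %.2f)\n",
                min(v), max(v), median(v)))
})

#' Sampled force-transducer trace with stimulation timestamps
#'
#' @slot time_s uniformly sampled time axis (s)
#' @slot force_mN force samples (mN)
#' @slot sampling_hz sampling rate
#' @slot stim_times_s stimulation pulse times (s), within the trace span
#' @slot truth_peaks_mN generator ground-truth per-twitch peaks, or NULL
#' @export
setClass("ForceTrace",
  representation(time_s = "numeric", force_mN = "numeric",
                 sampling_hz = "numeric", stim_times_s = "numeric",
                 truth_peaks_mN = "ANY")
)

setValidity("ForceTrace", function(object) {
  msg <- character()
  if (length(object@time_s) != length(object@force_mN))
    msg <- c(msg, "time and force must have equal length")
  if (length(object@time_s) > 1L) {
    dt <- diff(object@time_s)
    if (max(abs(dt - 1 / object@sampling_hz)) > 1e-9)
      msg <- c(msg, "sampling must be uniform at sampling_hz")
  }
  if (length(object@stim_times_s) &&
      (min(object@stim_times_s) < min(object@time_s) - 1e-9 ||
       max(object@stim_times_s) > max(object@time_s) + 1e-9))
    msg <- c(msg, "stimulation times must lie within the trace span")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ForceTrace", function(object) {
  cat(sprintf("ForceTrace: %.1f s at %g Hz, %d stimulation pulses\n",
              diff(range(object@time_s)), object@sampling_hz,
              length(object@stim_times_s)))
})

#' Per-twitch peak-force table
#'
#' One row per stimulation pulse: baseline-corrected peak force within the
#' inter-stimulus window, with the pre-stimulus baseline used.
#'
#' @slot data data.frame (twitch_index, stim_time_s, peak_mN, baseline_mN,
#'   truncated)
#' @export
setClass("TwitchTable", representation(data = "data.frame"))

setValidity("TwitchTable", function(object) {
  need <- c("twitch_index", "stim_time_s", "peak_mN", "baseline_mN", "truncated")
  if (!all(need %in% names(object@data)))
    return(paste("data must contain columns:", paste(need, collapse = ", ")))
  TRUE
})

#' @describeIn asTable per-twitch table
#' @export
setMethod("asTable", "TwitchTable", function(object, ...) object@data)

setMethod("show", "TwitchTable", function(object) {
  d <- object@data
  cat(sprintf("TwitchTable: %d twitches, peak %.1f..%.1f mN\n",
              nrow(d), min(d$peak_mN), max(d$peak_mN)))
})
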