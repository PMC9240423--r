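# Forward simulation of the whole acquisition: dynamic 31P FID series,
# multi-echo image stacks and twitch-force traces with known ground truth.

# Piecewise PCr(t) in mM on the acquisition clock (t in seconds from the
# start of the rest phase): constant at rest, mono-exponential decline with
# tau_stim towards (1 + depletion_frac) * rest during exercise, then
# mono-exponential return with tau_rec from the value actually reached at
# the end of exercise.
.pcrTrajectory <- function(t_s, truth, protocol) {
  te0 <- protocol@n_rest * protocol@tr_s
  te1 <- te0 + protocol@n_exercise * protocol@tr_s
  rest <- truth@pcr_rest_mM
  plateau <- rest * (1 + truth@depletion_frac)
  tau_s <- truth@tau_stim_min * 60
  tau_r <- truth@tau_rec_min * 60
  end_ex <- plateau + (rest - plateau) * exp(-(te1 - te0) / tau_s)
  out <- rep(rest, length(t_s))
  ex <- t_s >= te0 & t_s < te1
  out[ex] <- plateau + (rest - plateau) * exp(-(t_s[ex] - te0) / tau_s)
  rc <- t_s >= te1
  out[rc] <- rest + (end_ex - rest) * exp(-(t_s[rc] - te1) / tau_r)
  out
}

# pH follows the same two-phase mono-exponential timeline between ph_rest
# and ph_end_exercise; a deliberate simplification of the in vivo biphasic
# pH transient (see the methods vignette).
.phTrajectory <- function(t_s, truth, protocol) {
  te0 <- protocol@n_rest * protocol@tr_s
  te1 <- te0 + protocol@n_exercise * protocol@tr_s
  tau_s <- truth@tau_stim_min * 60
  tau_r <- truth@tau_rec_min * 60
  end_ex <- truth@ph_end_exercise +
    (truth@ph_rest - truth@ph_end_exercise) * exp(-(te1 - te0) / tau_s)
  out <- rep(truth@ph_rest, length(t_s))
  ex <- t_s >= te0 & t_s < te1
  out[ex] <- truth@ph_end_exercise +
    (truth@ph_rest - truth@ph_end_exercise) * exp(-(t_s[ex] - te0) / tau_s)
  rc <- t_s >= te1
  out[rc] <- truth@ph_rest + (end_ex - truth@ph_rest) * exp(-(t_s[rc] - te1) / tau_r)
  out
}

#' Generate a synthetic dynamic 31P FID series
#'
#' Forward model of the rest-stimulation-recovery experiment: every
#' acquisition is a sum of exponentially damped complex sinusoids
#' (Lorentzian lines) for PCr, Pi and the three ATP multiplets. The PCr
#' amplitude follows the mono-exponential depletion/recovery trajectory in
#' \code{truth}; Pi mirrors PCr so that PCr + Pi is conserved; the Pi
#' chemical shift tracks intracellular pH through the exact inverse of the
#' pH calibration; ATP amplitudes are constant. Amplitudes are in mM
#' equivalents (the spectral amplitude of a peak equals the underlying
#' concentration), making parameter-recovery closure checks direct.
#'
#' @param protocol an \linkS4class{AcquisitionProtocol}
#' @param truth a \linkS4class{KineticsGroundTruth}
#' @param priors prior set defining line positions, multiplet structure and
#'   dampings used for generation (defaults to \code{\link{defaultPriors}})
#' @return a \linkS4class{FIDSeries} with \code{truth} attached
#' @examples
#' p <- acquisitionProtocol(n_rest = 10L, n_exercise = 30L, n_recovery = 30L,
#'                          block_exercise = 15L, block_recovery = 30L,
#'                          n_points = 256L)
#' s <- generateFidSeries(p, kineticsGroundTruth())
#' @export
generateFidSeries <- function(protocol, truth, priors = defaultPriors()) {
  stopifnot(is(protocol, "AcquisitionProtocol"), is(truth, "KineticsGroundTruth"))
  validObject(protocol); validObject(truth)
  n_acq <- protocol@n_rest + protocol@n_exercise + protocol@n_recovery
  if (n_acq == 0L) stop("protocol defines zero acquisitions")
  np <- protocol@n_points
  t_fid <- (seq_len(np) - 1) / protocol@sweep_hz
  # acquisition time stamps: FID i is centred at (i - 1/2) * TR
  t_acq <- (seq_len(n_acq) - 0.5) * protocol@tr_s
  phase <- rep(c("rest", "exercise", "recovery"),
               c(protocol@n_rest, protocol@n_exercise, protocol@n_recovery))

  pcr <- .pcrTrajectory(t_acq, truth, protocol)
  ph <- .phTrajectory(t_acq, truth, protocol)
  pi_amp <- truth@pi_rest_mM + (truth@pcr_rest_mM - pcr)  # PCr + Pi conserved
  d_pi <- shiftFromPh(ph)

  nm <- vapply(priors, `[[`, "", "name")
  ip <- match(c("PCr", "Pi", "gammaATP", "alphaATP", "betaATP"), nm)
  if (anyNA(ip)) stop("priors must include PCr, Pi and the three ATP multiplets")
  shifts0 <- vapply(priors, `[[`, 0, "shift_ppm")
  damps <- vapply(priors, `[[`, 0, "damping_init")

  fids <- matrix(complex(real = 0), n_acq, np)
  # the constant part (ATP multiplets) and the PCr line shape are shared
  atp_part <- complex(length.out = np)
  for (i in ip[3:5])
    atp_part <- atp_part + .multipletSignal(t_fid, truth@atp_mM, shifts0[i],
                                            damps[i], 0, priors[[i]],
                                            protocol@f0_mhz)
  pcr_shape <- .multipletSignal(t_fid, 1, shifts0[ip[1]], damps[ip[1]], 0,
                                priors[[ip[1]]], protocol@f0_mhz)
  for (a in seq_len(n_acq)) {
    fids[a, ] <- atp_part + pcr[a] * pcr_shape +
      .multipletSignal(t_fid, pi_amp[a], d_pi[a], damps[ip[2]], 0,
                       priors[[ip[2]]], protocol@f0_mhz)
  }
  if (truth@noise_sd > 0) {
    fids <- fids + .withSeed(truth@seed, {
      matrix(complex(real = rnorm(n_acq * np, sd = truth@noise_sd),
                     imaginary = rnorm(n_acq * np, sd = truth@noise_sd)),
             n_acq, np)
    })
  }
  new("FIDSeries", fids = fids, protocol = protocol, phase = phase,
      truth = truth)
}

#' Generate a synthetic multi-echo magnitude image stack
#'
#' Pixel signal S(TE) = S0 exp(-TE/T2) with optional Rician noise (the
#' magnitude of a complex Gaussian perturbation, the standard MR magnitude
#' noise model). A T2 of \code{Inf} is accepted as a no-decay flag value.
#'
#' @param shape c(H, W) image size in pixels
#' @param te_list_ms echo times (ms), strictly increasing and positive
#' @param t2_truth_map ground-truth T2 (ms): scalar, H x W matrix, or
#'   H x W x n_slice array
#' @param s0_map equilibrium signal: scalar or array conformable with
#'   \code{t2_truth_map}
#' @param noise_sd Gaussian noise SD per channel (0 = noiseless)
#' @param seed RNG seed
#' @param n_slice number of slices when maps are scalar / matrix
#' @param thickness_mm,gap_mm slice geometry carried on the stack
#' @return an \linkS4class{EchoImageStack}
#' @export
generateMultiechoStack <- function(shape, te_list_ms, t2_truth_map, s0_map = 1000,
                                   noise_sd = 0, seed = 1L, n_slice = 1L,
                                   thickness_mm = 1, gap_mm = 1) {
  if (is.unsorted(te_list_ms, strictly = TRUE) || any(te_list_ms <= 0))
    stop("te_list_ms must be strictly increasing and positive")
  H <- shape[1]; W <- shape[2]; nE <- length(te_list_ms)
  expand <- function(x) {
    if (length(x) == 1L) array(x, c(H, W, n_slice))
    else if (length(dim(x)) == 2L) array(rep(x, n_slice), c(H, W, n_slice))
    else x
  }
  t2 <- expand(t2_truth_map); s0 <- expand(s0_map)
  n_slice <- dim(t2)[3]
  if (any(t2 <= 0)) stop("ground-truth T2 must be positive everywhere")
  dat <- array(0, c(H, W, nE, n_slice))
  for (e in seq_len(nE))
    dat[, , e, ] <- s0 * exp(-te_list_ms[e] / t2)
  if (noise_sd > 0) {
    dat <- .withSeed(seed, {
      n <- length(dat)
      sqrt((dat + rnorm(n, sd = noise_sd))^2 + rnorm(n, sd = noise_sd)^2)
    })
  }
  new("EchoImageStack", data = dat, te_ms = as.numeric(te_list_ms),
      thickness_mm = thickness_mm, gap_mm = gap_mm)
}

#' Echo times of the reference multi-echo protocol
#'
#' 16 echo times equally spaced from 7.28 to 116.59 ms.
#'
#' @return numeric vector of 16 echo times (ms)
#' @export
defaultEchoTimes <- function() seq(7.28, 116.59, length.out = 16L)

#' Generate a synthetic twitch-force trace
#'
#' One isometric twitch per stimulation pulse at the protocol's stimulation
#' rate over the nominal exercise duration. Twitches are alpha-function
#' transients f(u) = P (u/tc) exp(1 - u/tc) reaching their peak P at
#' u = tc after the pulse; P follows the requested peak-force envelope. The
#' trace clock starts at 0 = exercise onset.
#'
#' The default envelope is biphasic: a rise from \code{base_mN} to
#' \code{peak_mN} peaking at \code{t_peak_s} (90 s), then a progressive
#' decline, via P(t) = base + (peak - base) (t/t_peak) exp(1 - t/t_peak).
#'
#' @param protocol an \linkS4class{AcquisitionProtocol} (stimulation rate
#'   and exercise duration are taken from it)
#' @param envelope_params list: \code{shape} ("biphasic" or "constant"),
#'   \code{peak_mN}, \code{base_mN}, \code{t_peak_s}, \code{tc_s} (twitch
#'   contraction time)
#' @param sampling_hz sampling rate (>= 100 Hz)
#' @param noise_sd additive Gaussian noise SD on the force samples (mN)
#' @param seed RNG seed
#' @return a \linkS4class{ForceTrace} with ground-truth peaks attached
#' @export
generateForceTrace <- function(protocol,
                               envelope_params = list(),
                               sampling_hz = 1000, noise_sd = 0, seed = 1L) {
  stopifnot(is(protocol, "AcquisitionProtocol"))
  if (sampling_hz < 100) stop("sampling_hz must be >= 100")
  ep <- modifyList(list(shape = "biphasic", peak_mN = 120, base_mN = 80,
                        t_peak_s = 90, tc_s = 0.02), envelope_params)
  n_pulse <- floor(protocol@exercise_duration_s * protocol@stim_freq_hz)
  if (n_pulse < 1L) stop("protocol implies zero stimulation pulses")
  stim <- (seq_len(n_pulse) - 1) / protocol@stim_freq_hz
  envelope <- function(t) {
    if (ep$shape == "constant") rep(ep$peak_mN, length(t))
    else ep$base_mN + (ep$peak_mN - ep$base_mN) *
      (t / ep$t_peak_s) * exp(1 - t / ep$t_peak_s)
  }
  peaks <- envelope(stim)
  dur <- protocol@exercise_duration_s + 1  # one spare inter-stimulus interval
  time_s <- seq(0, dur, by = 1 / sampling_hz)
  force <- numeric(length(time_s))
  # each twitch decays to < 1e-18 of its peak within 1 s at tc = 20 ms, so
  # only samples in [stim, stim + 1 s) need evaluating
  for (i in seq_len(n_pulse)) {
    idx <- which(time_s >= stim[i] & time_s < stim[i] + 1)
    u <- time_s[idx] - stim[i]
    force[idx] <- force[idx] + peaks[i] * (u / ep$tc_s) * exp(1 - u / ep$tc_s)
  }
  if (noise_sd > 0)
    force <- force + .withSeed(seed, rnorm(length(force), sd = noise_sd))
  new("ForceTrace", time_s = time_s, force_mN = force,
      sampling_hz = sampling_hz, stim_times_s = stim, truth_peaks_mN = peaks)
}
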