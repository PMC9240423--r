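# Shared forward model: sums of exponentially damped complex sinusoids
# (Lorentzian lines), plus the pH <-> Pi chemical-shift calibration and its
# exact algebraic inverse. Used by both the synthetic generator and the
# time-domain fitter; the fitter's correctness is checked against
# frequency-domain integration oracles in the tests, never against itself.

# Evaluate one multiplet: total amplitude `amp` split over lines with fixed
# ratios, line frequencies centred at shift_ppm * f0_mhz offset by J.
# t in seconds; damping in 1/s; phase in radians.
.multipletSignal <- function(t, amp, shift_ppm, damping, phase, prior, f0_mhz) {
  centre_hz <- shift_ppm * f0_mhz  # 1 ppm at f0 MHz = f0 Hz
  k <- prior$n_lines
  offsets <- (seq_len(k) - (k + 1) / 2) * prior$j_hz
  sig <- complex(length.out = length(t))
  for (l in seq_len(k)) {
    sig <- sig + (amp * prior$ratios[l]) *
      exp(complex(real = -damping * t,
                  imaginary = 2 * pi * (centre_hz + offsets[l]) * t + phase))
  }
  sig
}

# Sum a full parameter set over priors into one FID.
# params: list with vectors amp, shift_ppm, damping (one per prior) and
# scalar phase.
.modelFid <- function(t, params, priors, f0_mhz) {
  sig <- complex(length.out = length(t))
  for (i in seq_along(priors)) {
    sig <- sig + .multipletSignal(t, params$amp[i], params$shift_ppm[i],
                                  params$damping[i], params$phase,
                                  priors[[i]], f0_mhz)
  }
  sig
}

#' Intracellular pH from the Pi chemical shift
#'
#' Evaluates the classic calibration
#' pH = 6.75 + log10((3.27 - dPi) / (dPi - 5.69)) with dPi the Pi chemical
#' shift in ppm relative to PCr. Defined on the open interval
#' (3.27, 5.69) ppm, where it is strictly increasing in dPi.
#'
#' @param delta_pi_ppm Pi chemical shift relative to PCr (ppm)
#' @param constants list from \code{\link{physioConstants}}
#' @return intracellular pH
#' @examples
#' phFromShift(4.48)  # ratio = 1, so exactly 6.75
#' @export
phFromShift <- function(delta_pi_ppm, constants = physioConstants()) {
  a <- constants$ph_a; b <- constants$ph_b; cc <- constants$ph_c
  if (any(delta_pi_ppm <= b) || any(delta_pi_ppm >= cc))
    stop("delta_pi_ppm outside the (", b, ", ", cc,
         ") ppm domain of the pH calibration; Pi peak likely mis-fitted")
  a + log10((b - delta_pi_ppm) / (delta_pi_ppm - cc))
}

#' Pi chemical shift from pH (exact inverse of the calibration)
#'
#' @param ph intracellular pH
#' @param constants list from \code{\link{physioConstants}}
#' @return Pi chemical shift relative to PCr (ppm)
#' @export
shiftFromPh <- function(ph, constants = physioConstants()) {
  r <- 10^(ph - constants$ph_a)
  (constants$ph_b + constants$ph_c * r) / (1 + r)
}

# Deterministic child seed: mix a base seed with a stream label, staying
# within the positive 32-bit integer range.
.childSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 1103515245 + stream * 12345) %% 2147483647L)
}

# Evaluate a function under a local RNG state (restores the caller's state).
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # initialise RNG state
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
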