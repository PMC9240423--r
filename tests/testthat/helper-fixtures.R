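# Shared fixtures. Expensive objects (full-protocol spectral runs) are
# memoized so the acceptance and pipeline suites share one computation.

.fixtures <- new.env(parent = emptyenv())

# Reduced protocol: same block structure as the reference acquisition but
# fewer FIDs and shorter FIDs, for fast spectral tests.
smallProtocol <- function(n_points = 512L)
  acquisitionProtocol(n_rest = 10L, n_exercise = 60L, n_recovery = 80L,
                      block_exercise = 10L, block_recovery = 20L,
                      n_points = n_points)

# Full-protocol noiseless control animal run end to end (generation,
# binning, spectral fitting, physiology); computed once per session.
defaultNoiselessRun <- function() {
  if (!is.null(.fixtures$run)) return(.fixtures$run)
  protocol <- acquisitionProtocol()
  truth <- kineticsGroundTruth()
  series <- generateFidSeries(protocol, truth)
  quant <- quantifySeries(series)
  metab <- buildMetaboliteSeries(quant, protocol)
  .fixtures$run <- list(protocol = protocol, truth = truth, series = series,
                        quant = quant, metab = metab,
                        kinetics = summarizeKinetics(metab))
  .fixtures$run
}

# Frequency-domain peak integration oracle: integrate the phased real part
# of the DFT spectrum over a window around each expected line position.
# The first FID point is halved before the DFT (removes the discrete
# one-sided-transform baseline so the real part is pure absorption).
# Independent of the time-domain fitter.
integrateSpectrum <- function(fid, sweep_hz, centre_hz, half_width_hz) {
  np <- length(fid)
  fid[1L] <- fid[1L] / 2
  spec <- fft(fid)
  freq <- (seq_len(np) - 1) / np * sweep_hz
  freq[freq >= sweep_hz / 2] <- freq[freq >= sweep_hz / 2] - sweep_hz
  sel <- abs(freq - centre_hz) <= half_width_hz
  sum(Re(spec[sel])) * sweep_hz / np
}

# Full-band variant: every spectral bin is assigned to the nearest line
# centre, so the areas partition the whole bandwidth (total is exact).
integrateSpectrumVoronoi <- function(fid, sweep_hz, centres_hz) {
  np <- length(fid)
  fid[1L] <- fid[1L] / 2
  spec <- Re(fft(fid))
  freq <- (seq_len(np) - 1) / np * sweep_hz
  freq[freq >= sweep_hz / 2] <- freq[freq >= sweep_hz / 2] - sweep_hz
  nearest <- apply(abs(outer(freq, centres_hz, "-")), 1, which.min)
  vapply(seq_along(centres_hz), function(k)
    sum(spec[nearest == k]) / np, 0)
}

# Brute-force grid oracle for the mono-exponential fits: for each candidate
# tau the remaining parameters are linear and solved by lm(); returns the
# tau minimizing the residual sum of squares over the grid.
gridTau <- function(times, values, taus, kind = c("depletion", "recovery")) {
  kind <- match.arg(kind)
  rss <- vapply(taus, function(tau) {
    x <- if (kind == "depletion") exp(-times / tau) else 1 - exp(-times / tau)
    sum(lm(values ~ x)$residuals^2)
  }, 0)
  taus[which.max(-rss)]
}
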