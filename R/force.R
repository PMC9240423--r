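# Twitch-force analysis: per-stimulus peak extraction, total force
# production, volume-normalized (specific) indices and alignment of force
# onto the MRS bin clock.

#' Detect per-stimulus twitches in a force trace
#'
#' For each stimulation pulse the search window is [stimulus, next
#' stimulus); the last window runs to the end of the trace and is flagged
#' truncated if shorter than the nominal inter-stimulus interval. The
#' baseline is the median of the 50 ms preceding the stimulus (the samples
#' available when the trace starts at the first pulse), and the peak force
#' is the window maximum minus that baseline - making detection invariant
#' to any DC offset.
#'
#' @param trace a \linkS4class{ForceTrace} with >= 1 stimulus
#' @return a \linkS4class{TwitchTable}
#' @export
detectTwitches <- function(trace) {
  stopifnot(is(trace, "ForceTrace"))
  validObject(trace)
  stim <- trace@stim_times_s
  if (!length(stim)) stop("trace carries no stimulation pulses")
  n <- length(stim)
  isi <- if (n > 1L) median(diff(stim)) else diff(range(trace@time_s))
  t_end <- max(trace@time_s)
  rows <- lapply(seq_len(n), function(i) {
    w0 <- stim[i]
    w1 <- if (i < n) stim[i + 1L] else t_end
    idx <- which(trace@time_s >= w0 & trace@time_s < w1 + (i == n) * 1e-9)
    pre <- which(trace@time_s >= w0 - 0.05 & trace@time_s < w0)
    # no pre-stimulus samples (first pulse at trace start): the sample at
    # the stimulus itself precedes the mechanical response
    baseline <- if (length(pre)) median(trace@force_mN[pre])
                else trace@force_mN[idx[1L]]
    data.frame(twitch_index = i, stim_time_s = w0,
               peak_mN = max(trace@force_mN[idx]) - baseline,
               baseline_mN = baseline,
               truncated = (i == n) && (w1 - w0 < isi - 1e-9))
  })
  new("TwitchTable", data = do.call(rbind, rows))
}

#' Total force production
#'
#' The sum of baseline-corrected per-twitch peak forces over the whole
#' stimulation bout; order-invariant by construction.
#'
#' @param twitches a \linkS4class{TwitchTable}
#' @return total force production (mN)
#' @export
totalForceProduction <- function(twitches) {
  stopifnot(is(twitches, "TwitchTable"))
  if (!nrow(twitches@data)) stop("empty twitch table")
  sum(twitches@data$peak_mN)
}

#' Volume-normalized (specific) value
#'
#' Exact division of an absolute quantity by the muscle volume, with the
#' unit label carried along (peak force per cm^3, total force production
#' per mm^3 by convention).
#'
#' @param absolute absolute value (e.g. mN)
#' @param volume muscle volume (> 0)
#' @param unit label recorded on the result
#' @return the ratio with a \code{unit} attribute
#' @export
specificValue <- function(absolute, volume, unit = "") {
  if (any(volume <= 0)) stop("volume must be positive")
  structure(absolute / volume, unit = unit)
}

#' Sum twitch peaks within each MRS exercise bin
#'
#' Aligns the force and energetics clocks: twitch peaks are summed within
#' consecutive windows of one exercise-block duration
#' (\code{block_exercise * tr_s}), with twitch times measured from exercise
#' onset (the force-trace clock). \code{force_begin} is the first bin's sum
#' and \code{force_end} the last stimulated bin's sum - when the nominal
#' stimulation is shorter than the MRS exercise phase, trailing bins are
#' empty, flagged, and excluded from the "end" definition.
#'
#' @param twitches a \linkS4class{TwitchTable}
#' @param protocol an \linkS4class{AcquisitionProtocol}
#' @return list: \code{bins} (data.frame bin, t_start_s, sum_mN, n_twitches,
#'   empty), \code{force_begin_mN}, \code{force_end_mN},
#'   \code{force_begin_N}, \code{force_end_N}
#' @export
binForceToMrs <- function(twitches, protocol) {
  stopifnot(is(twitches, "TwitchTable"), is(protocol, "AcquisitionProtocol"))
  d <- twitches@data
  if (!nrow(d)) stop("no twitches in the exercise phase")
  w <- protocol@block_exercise * protocol@tr_s
  n_bins <- protocol@n_exercise %/% protocol@block_exercise
  bin_of <- pmin(floor(d$stim_time_s / w) + 1L, n_bins)
  sums <- vapply(seq_len(n_bins), function(b) sum(d$peak_mN[bin_of == b]), 0)
  counts <- vapply(seq_len(n_bins), function(b) sum(bin_of == b), 0L)
  bins <- data.frame(bin = seq_len(n_bins), t_start_s = (seq_len(n_bins) - 1) * w,
                     sum_mN = sums, n_twitches = counts, empty = counts == 0L)
  occupied <- which(counts > 0L)
  if (!length(occupied)) stop("no twitches fall inside the exercise bins")
  list(bins = bins,
       force_begin_mN = sums[occupied[1L]],
       force_end_mN = sums[occupied[length(occupied)]],
       force_begin_N = sums[occupied[1L]] / 1000,
       force_end_N = sums[occupied[length(occupied)]] / 1000)
}

#' Summarize the force arm of one experiment
#'
#' Bundles twitch detection, binning to the MRS clock, total force
#' production and the volume-normalized indices.
#'
#' @param trace a \linkS4class{ForceTrace}
#' @param protocol an \linkS4class{AcquisitionProtocol}
#' @param volume_mm3 gastrocnemius volume (mm^3)
#' @return list of class \code{ForceSummary}: twitches, bins,
#'   force_begin/end (mN and N), tfp_mN, specific_pf (peak twitch force per
#'   cm^3), specific_tfp (TFP per mm^3), volume_mm3
#' @export
forceSummary <- function(trace, protocol, volume_mm3) {
  tw <- detectTwitches(trace)
  binned <- binForceToMrs(tw, protocol)
  tfp <- totalForceProduction(tw)
  vol_cm3 <- volume_mm3 / 1000
  structure(list(
    twitches = tw, bins = binned$bins,
    force_begin_mN = binned$force_begin_mN,
    force_end_mN = binned$force_end_mN,
    force_begin_N = binned$force_begin_N,
    force_end_N = binned$force_end_N,
    tfp_mN = tfp,
    specific_pf = specificValue(max(tw@data$peak_mN), vol_cm3, "mN/cm3"),
    specific_tfp = specificValue(tfp, volume_mm3, "mN/mm3"),
    volume_mm3 = volume_mm3), class = "ForceSummary")
}
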