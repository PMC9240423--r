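# Plain interchange formats: FID series as a binary complex array plus a
# JSON sidecar, tables as CSV, scalar results as JSON.

#' Write / read an FID series
#'
#' The complex matrix is stored as interleaved double-precision real and
#' imaginary parts in \code{fids.bin}; the protocol, phase labels and (when
#' present) the generating ground truth go to a \code{series.json} sidecar.
#'
#' @param series a \linkS4class{FIDSeries}
#' @param dir directory to create / read
#' @return \code{readFidSeries} returns the \linkS4class{FIDSeries}
#' @export
writeFidSeries <- function(series, dir) {
  stopifnot(is(series, "FIDSeries"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- series@fids
  inter <- as.vector(rbind(as.vector(Re(m)), as.vector(Im(m))))
  con <- file(file.path(dir, "fids.bin"), "wb")
  on.exit(close(con))
  writeBin(inter, con, size = 8)
  p <- series@protocol
  sidecar <- list(
    n_acq = nrow(m), n_points = ncol(m), phase = series@phase,
    protocol = list(tr_s = p@tr_s, n_rest = p@n_rest,
                    n_exercise = p@n_exercise, n_recovery = p@n_recovery,
                    block_exercise = p@block_exercise,
                    block_recovery = p@block_recovery,
                    sweep_hz = p@sweep_hz, n_points = p@n_points,
                    stim_freq_hz = p@stim_freq_hz,
                    exercise_duration_s = p@exercise_duration_s,
                    f0_mhz = p@f0_mhz))
  if (!is.null(series@truth)) {
    tr <- series@truth
    sidecar$truth <- list(pcr_rest_mM = tr@pcr_rest_mM,
                          pi_rest_mM = tr@pi_rest_mM, atp_mM = tr@atp_mM,
                          depletion_frac = tr@depletion_frac,
                          tau_stim_min = tr@tau_stim_min,
                          tau_rec_min = tr@tau_rec_min,
                          ph_rest = tr@ph_rest,
                          ph_end_exercise = tr@ph_end_exercise,
                          noise_sd = tr@noise_sd, seed = tr@seed)
  }
  jsonlite::write_json(sidecar, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeFidSeries
#' @export
readFidSeries <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "series.json"),
                            simplifyVector = TRUE)
  n <- sc$n_acq * sc$n_points
  con <- file(file.path(dir, "fids.bin"), "rb")
  on.exit(close(con))
  inter <- readBin(con, "double", 2L * n, size = 8)
  m <- matrix(complex(real = inter[seq(1L, 2L * n, 2L)],
                      imaginary = inter[seq(2L, 2L * n, 2L)]),
              sc$n_acq, sc$n_points)
  pr <- sc$protocol
  proto <- acquisitionProtocol(pr$tr_s, pr$n_rest, pr$n_exercise,
                               pr$n_recovery, pr$block_exercise,
                               pr$block_recovery, pr$sweep_hz, pr$n_points,
                               pr$stim_freq_hz, pr$exercise_duration_s,
                               pr$f0_mhz)
  truth <- NULL
  if (!is.null(sc$truth)) {
    tr <- sc$truth
    truth <- kineticsGroundTruth(tr$pcr_rest_mM, tr$pi_rest_mM, tr$atp_mM,
                                 tr$depletion_frac, tr$tau_stim_min,
                                 tr$tau_rec_min, tr$ph_rest,
                                 tr$ph_end_exercise, tr$noise_sd, tr$seed)
  }
  new("FIDSeries", fids = m, protocol = proto, phase = sc$phase,
      truth = truth)
}

#' Export a metabolite time series as tidy CSV
#'
#' @param series a \linkS4class{MetaboliteTimeSeries}
#' @param path output file
#' @return the path, invisibly
#' @export
exportMetaboliteSeries <- function(series, path) {
  write.csv(asTable(series), path, row.names = FALSE)
  invisible(path)
}

#' Export a kinetics result as JSON
#'
#' @param result a \linkS4class{KineticsResult}
#' @param path output file
#' @return the path, invisibly
#' @export
exportKinetics <- function(result, path) {
  jsonlite::write_json(as.list(asTable(result)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a force trace
#'
#' Samples as CSV (time_s, force_mN); sampling rate and stimulation times
#' in a JSON sidecar next to it.
#'
#' @param trace a \linkS4class{ForceTrace}
#' @param path CSV path; the sidecar takes the same name with .json
#' @return \code{readForceTrace} returns the \linkS4class{ForceTrace}
#' @export
writeForceTrace <- function(trace, path) {
  write.csv(data.frame(time_s = trace@time_s, force_mN = trace@force_mN),
            path, row.names = FALSE)
  jsonlite::write_json(list(sampling_hz = trace@sampling_hz,
                            stim_times_s = trace@stim_times_s),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeForceTrace
#' @export
readForceTrace <- function(path) {
  d <- read.csv(path)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("ForceTrace", time_s = d$time_s, force_mN = d$force_mN,
      sampling_hz = sc$sampling_hz, stim_times_s = sc$stim_times_s,
      truth_peaks_mN = NULL)
}

#' Export per-twitch and cohort tables as CSV
#'
#' @param x a \linkS4class{TwitchTable} or plain data.frame
#' @param path output file
#' @return the path, invisibly
#' @export
exportTable <- function(x, path) {
  if (is(x, "TwitchTable")) x <- asTable(x)
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
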