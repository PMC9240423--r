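#' Prior knowledge for one 31P resonance
#'
#' AMARES-style prior knowledge: a resonance is a multiplet of Lorentzian
#' lines with fixed amplitude ratios and J-splitting, a group chemical shift
#' free within bounds, a common damping factor within bounds, and a
#' zero-order phase shared across all peaks of a spectrum.
#'
#' @param name peak name (PCr, Pi, gammaATP, alphaATP, betaATP, ...)
#' @param shift_ppm nominal chemical shift, ppm relative to PCr = 0
#' @param shift_bounds length-2 numeric, allowed shift interval (ppm)
#' @param n_lines number of multiplet lines
#' @param j_hz J-coupling splitting between adjacent lines (Hz)
#' @param ratios relative line amplitudes; normalized to sum to 1
#' @param damping_bounds allowed damping interval (1/s)
#' @param damping_init initial damping (1/s)
#' @return a list of class \code{PeakPrior}
#' @export
peakPrior <- function(name, shift_ppm, shift_bounds = shift_ppm + c(-0.5, 0.5),
                      n_lines = 1L, j_hz = 0, ratios = rep(1, n_lines),
                      damping_bounds = c(5, 200), damping_init = 30) {
  stopifnot(length(shift_bounds) == 2L, shift_bounds[1] < shift_bounds[2],
            length(ratios) == n_lines, all(ratios > 0),
            length(damping_bounds) == 2L,
            damping_bounds[1] > 0, damping_bounds[1] < damping_bounds[2],
            damping_init >= damping_bounds[1], damping_init <= damping_bounds[2])
  structure(list(name = name, shift_ppm = shift_ppm,
                 shift_bounds = as.numeric(shift_bounds),
                 n_lines = as.integer(n_lines), j_hz = j_hz,
                 ratios = ratios / sum(ratios),
                 damping_bounds = as.numeric(damping_bounds),
                 damping_init = damping_init),
            class = "PeakPrior")
}

#' Default 31P prior-knowledge set for skeletal muscle
#'
#' Standard in vivo muscle conventions with PCr as the 0-ppm reference: Pi
#' free over the open interval where the pH calibration is defined
#' (3.27, 5.69 ppm); gamma-ATP a 1:1 doublet near -2.5 ppm, alpha-ATP a 1:1
#' doublet near -7.5 ppm, beta-ATP a 1:2:1 triplet near -16.2 ppm, all with
#' J = 16.5 Hz. All values are configurable; none is fitted dogma.
#'
#' @param j_hz ATP J-splitting (Hz)
#' @return list of \code{\link{peakPrior}} objects
#' @export
defaultPriors <- function(j_hz = 16.5) {
  eps <- 1e-3  # keep Pi strictly inside the pH-formula domain
  list(
    peakPrior("PCr", 0, c(-0.5, 0.5), damping_init = 30,
              damping_bounds = c(5, 200)),
    peakPrior("Pi", 4.8, c(3.27 + eps, 5.69 - eps), damping_init = 40,
              damping_bounds = c(5, 300)),
    peakPrior("gammaATP", -2.5, c(-3.2, -1.8), n_lines = 2L, j_hz = j_hz,
              ratios = c(1, 1), damping_init = 50, damping_bounds = c(5, 300)),
    peakPrior("alphaATP", -7.5, c(-8.2, -6.8), n_lines = 2L, j_hz = j_hz,
              ratios = c(1, 1), damping_init = 50, damping_bounds = c(5, 300)),
    peakPrior("betaATP", -16.2, c(-17.0, -15.4), n_lines = 3L, j_hz = j_hz,
              ratios = c(1, 2, 1), damping_init = 50, damping_bounds = c(5, 300))
  )
}

#' Read / write a prior-knowledge file
#'
#' Priors are interchanged as JSON, one record per peak.
#'
#' @param priors list of \code{\link{peakPrior}} objects
#' @param path file path
#' @return \code{readPriors} returns the prior list
#' @export
writePriors <- function(priors, path) {
  jsonlite::write_json(lapply(priors, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePriors
#' @export
readPriors <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    peakPrior(r$name, r$shift_ppm, unlist(r$shift_bounds), r$n_lines,
              r$j_hz, unlist(r$ratios), unlist(r$damping_bounds),
              r$damping_init)
  })
}
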