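# Physiological conversion layer: fitted amplitudes/shifts -> PCr %,
# absolute concentrations, intracellular pH and free cytosolic ADP.

#' Physiological constants for 31P muscle spectroscopy
#'
#' The pH calibration constants (6.75, 3.27, 5.69), the creatine-kinase
#' equilibrium constant K_CK = 1.66e9 1/M, the 5 mM basal beta-ATP anchor
#' used for absolute quantification, the assumption that PCr is ~85 % of
#' total creatine at rest, and the mitochondrial ADP affinity
#' Km = 30 uM for mouse gastrocnemius.
#'
#' @param ph_a,ph_b,ph_c pH calibration constants
#' @param k_ck_per_M creatine-kinase equilibrium constant (1/M)
#' @param atp_basal_mM basal beta-ATP concentration (mM)
#' @param pcr_fraction_of_cr resting PCr / total creatine
#' @param km_adp_uM mitochondrial Km for ADP (uM)
#' @return named list of constants
#' @export
physioConstants <- function(ph_a = 6.75, ph_b = 3.27, ph_c = 5.69,
                            k_ck_per_M = 1.66e9, atp_basal_mM = 5,
                            pcr_fraction_of_cr = 0.85, km_adp_uM = 30) {
  stopifnot(ph_b < ph_c, ph_a > 0, ph_b > 0, k_ck_per_M > 0,
            atp_basal_mM > 0, km_adp_uM >= 0,
            pcr_fraction_of_cr > 0, pcr_fraction_of_cr < 1)
  list(ph_a = ph_a, ph_b = ph_b, ph_c = ph_c, k_ck_per_M = k_ck_per_M,
       atp_basal_mM = atp_basal_mM, pcr_fraction_of_cr = pcr_fraction_of_cr,
       km_adp_uM = km_adp_uM)
}

#' Scale fitted amplitudes to absolute concentrations
#'
#' A single scale factor, basal beta-ATP concentration divided by the
#' resting beta-ATP amplitude, converts all per-FID amplitudes to mM. The
#' result is gauge-invariant: multiplying every amplitude by a constant
#' leaves the concentrations unchanged.
#'
#' @param quant data.frame from \code{\link{quantifySeries}}
#' @param constants list from \code{\link{physioConstants}}
#' @return the table with an added \code{conc_mM} column
#' @export
absoluteConcentrations <- function(quant, constants = physioConstants()) {
  need <- c("phase", "name", "amplitude")
  stopifnot(all(need %in% names(quant)))
  i <- which(quant$phase == "rest" & quant$name == "betaATP")
  if (!length(i)) stop("no resting beta-ATP amplitude in the table")
  a0 <- mean(quant$amplitude[i])
  if (!is.finite(a0) || a0 <= 0) stop("resting beta-ATP amplitude must be > 0")
  quant$conc_mM <- quant$amplitude * constants$atp_basal_mM / a0
  quant
}

#' Free cytosolic ADP from the creatine-kinase equilibrium
#'
#' [ADP] = ([Cr] [ATP]) / ([PCr] 10^-pH K_CK), with free creatine obtained
#' from a creatine pool fixed at rest: total Cr = resting PCr / 0.85, so
#' [Cr] = total Cr - current PCr. All concentrations enter in molar units;
#' the result is returned in uM. At fixed pH, [ADP] rises as PCr falls.
#'
#' @param pcr_mM current PCr (mM), must be > 0
#' @param atp_mM current ATP (mM)
#' @param ph intracellular pH
#' @param pcr_rest_mM resting PCr (mM), sets the creatine pool
#' @param constants list from \code{\link{physioConstants}}
#' @return ADP concentration (uM)
#' @examples
#' adpConcentration(15, 5, 7.0, 15)  # free Cr = 15/0.85 - 15 = 2.647 mM
#' @export
adpConcentration <- function(pcr_mM, atp_mM, ph, pcr_rest_mM,
                             constants = physioConstants()) {
  if (any(pcr_mM <= 0)) stop("PCr must be positive")
  cr_total_mM <- pcr_rest_mM / constants$pcr_fraction_of_cr
  cr_free_mM <- cr_total_mM - pcr_mM
  adp_M <- (cr_free_mM * 1e-3) * (atp_mM * 1e-3) /
    ((pcr_mM * 1e-3) * 10^(-ph) * constants$k_ck_per_M)
  adp_M * 1e6
}

#' Build the physiological metabolite time series
#'
#' Converts a quantified amplitude/shift table into per-bin physiology:
#' PCr as % of the resting bin, absolute concentrations anchored to basal
#' beta-ATP, the Pi-PCr shift difference, pH via the calibration formula and
#' free ADP via the creatine-kinase equilibrium. Bins whose Pi fit failed or
#' whose shift falls outside the calibration domain carry \code{ph = NA}
#' with \code{ph_valid = FALSE} - never silently interpolated.
#'
#' @param quant data.frame from \code{\link{quantifySeries}}
#' @param protocol the \linkS4class{AcquisitionProtocol} (phase boundaries)
#' @param constants list from \code{\link{physioConstants}}
#' @param atp_mode "per_bin" tracks the fitted beta-ATP per bin in the ADP
#'   formula; "constant" holds ATP at the basal value
#' @return a \linkS4class{MetaboliteTimeSeries}
#' @export
buildMetaboliteSeries <- function(quant, protocol,
                                  constants = physioConstants(),
                                  atp_mode = c("per_bin", "constant")) {
  atp_mode <- match.arg(atp_mode)
  stopifnot(is(protocol, "AcquisitionProtocol"))
  if (!any(quant$phase == "rest")) stop("rest bin missing from quantified table")
  quant <- absoluteConcentrations(quant, constants)
  bins <- sort(unique(quant$bin))
  pick <- function(b, nm, col) {
    v <- quant[quant$bin == b & quant$name == nm, col]
    if (length(v)) v[1L] else NA_real_
  }
  rest_bins <- unique(quant$bin[quant$phase == "rest"])
  pcr_rest_amp <- mean(vapply(rest_bins, pick, 0, "PCr", "amplitude"))
  pcr_rest_mM <- mean(vapply(rest_bins, pick, 0, "PCr", "conc_mM"))
  if (!is.finite(pcr_rest_amp) || pcr_rest_amp <= 0)
    stop("resting PCr amplitude must be positive")
  rows <- lapply(bins, function(b) {
    sub <- quant[quant$bin == b, ]
    conv <- all(sub$converged)
    pcr_amp <- pick(b, "PCr", "amplitude")
    d_pi <- pick(b, "Pi", "shift_ppm") - pick(b, "PCr", "shift_ppm")
    pi_ok <- isTRUE(sub$converged[sub$name == "Pi"]) && is.finite(d_pi)
    ph <- if (pi_ok) tryCatch(phFromShift(d_pi, constants),
                              error = function(e) NA_real_) else NA_real_
    pcr_mM <- pick(b, "PCr", "conc_mM")
    atp_mM <- if (atp_mode == "per_bin") pick(b, "betaATP", "conc_mM")
              else constants$atp_basal_mM
    adp <- if (is.finite(ph) && is.finite(pcr_mM) && pcr_mM > 0)
      adpConcentration(pcr_mM, atp_mM, ph, pcr_rest_mM, constants)
    else NA_real_
    data.frame(time_min = sub$bin_time_s[1L] / 60, phase = sub$phase[1L],
               pcr_pct = 100 * pcr_amp / pcr_rest_amp,
               pcr_mM = pcr_mM, pi_mM = pick(b, "Pi", "conc_mM"),
               atp_mM = atp_mM, shift_pi_ppm = d_pi, ph = ph, adp_uM = adp,
               converged = conv, ph_valid = is.finite(ph))
  })
  d <- do.call(rbind, rows)
  new("MetaboliteTimeSeries", data = d, constants = constants,
      exercise_start_min = protocol@n_rest * protocol@tr_s / 60,
      recovery_start_min = (protocol@n_rest + protocol@n_exercise) *
        protocol@tr_s / 60)
}
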