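# PCr kinetics: mono-exponential depletion and recovery fits and the
# derived energetic indices (VPCr, PCr cost, ADP-corrected Vmax).

# Shared mono-exponential fitter. Depletion: y = plateau + amp * exp(-t/tau)
# with amp = y(0) - plateau. Recovery: y = y0 + amp * (1 - exp(-t/tau)).
.fitMonoExp <- function(times_min, values, kind = c("depletion", "recovery")) {
  kind <- match.arg(kind)
  keep <- is.finite(times_min) & is.finite(values)
  t <- times_min[keep]; y <- values[keep]
  n <- length(y)
  if (n < 4L) stop("need at least 4 finite points for a mono-exponential fit")
  flagged <- FALSE
  if (sd(y) < 1e-10 * (abs(mean(y)) + 1e-12) || sd(y) == 0) {
    # constant input: amplitude ~ 0, tau unidentifiable
    return(list(tau_min = NA_real_, plateau = mean(y), amplitude = 0,
                rss = sum((y - mean(y))^2), n = n, converged = FALSE))
  }
  span <- max(t) - min(t)
  tau0 <- span / 3
  if (kind == "depletion") {
    p0 <- c(plateau = min(y), amp = y[1L] - min(y), tau = tau0)
    model <- function(p, t) p[1L] + p[2L] * exp(-t / p[3L])
  } else {
    p0 <- c(plateau = y[1L], amp = max(y) - y[1L], tau = tau0)
    model <- function(p, t) p[1L] + p[2L] * (1 - exp(-t / p[3L]))
  }
  lower <- c(-Inf, -Inf, span * 1e-4)
  upper <- c(Inf, Inf, span * 1e3)
  fit <- minpack.lm::nls.lm(p0, lower, upper,
                            fn = function(p) model(p, t) - y,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-12, ptol = 1e-12, maxiter = 500L))
  p <- fit$par
  rss <- sum(fit$fvec^2)
  # info 4 (gradient orthogonal to residual within gtol) arises at exact
  # zero-residual solutions on noiseless input; it is a converged state
  ok <- fit$info %in% c(1L, 2L, 3L, 4L)
  # tau pinned at its search bounds means the time constant was not
  # identified by the data
  if (p[3L] <= lower[3L] * 1.01 || p[3L] >= upper[3L] * 0.99) ok <- FALSE
  if (abs(p[2L]) < 1e-8 * (abs(p[1L]) + 1e-12)) ok <- FALSE  # no amplitude
  list(tau_min = unname(p[3L]), plateau = unname(p[1L]),
       amplitude = unname(p[2L]), rss = rss, n = n, converged = ok && !flagged)
}

#' Fit mono-exponential PCr depletion
#'
#' Least-squares fit of PCr(t) = plateau + amp * exp(-t/tau) to the exercise
#' time course, with t measured from stimulation onset. \code{amp} is the
#' depletion extent (rest minus end-exercise plateau) when the fit spans the
#' full bout.
#'
#' @param times_min bin times from stimulation onset (min), >= 4 points
#' @param pcr_values PCr values (any consistent unit: mM or % of rest)
#' @return list: tau_min, plateau, amplitude, rss, n, converged. A constant
#'   input returns amplitude ~ 0 with \code{converged = FALSE} (tau
#'   unidentifiable), never an error.
#' @export
fitDepletion <- function(times_min, pcr_values)
  .fitMonoExp(times_min, pcr_values, "depletion")

#' Fit mono-exponential PCr recovery
#'
#' Least-squares fit of PCr(t) = y0 + amp * (1 - exp(-t/tau)) to the
#' post-exercise time course, with t measured from the end of exercise.
#' \code{amp} is the recovered extent (resting level minus end-exercise
#' level when recovery is complete).
#'
#' @param times_min bin times from exercise end (min), >= 4 points
#' @param pcr_values PCr values
#' @return list as in \code{\link{fitDepletion}}
#' @export
fitRecovery <- function(times_min, pcr_values)
  .fitMonoExp(times_min, pcr_values, "recovery")

#' Initial PCr rate from depletion extent and time constant
#'
#' VPCr = deltaPCr / tau, the initial rate of PCr breakdown (during
#' stimulation) or resynthesis (during recovery).
#'
#' @param delta_pcr_mM depletion extent (mM), >= 0
#' @param tau_min time constant (min), > 0
#' @return rate in mM/min
#' @export
vPcr <- function(delta_pcr_mM, tau_min) {
  if (any(tau_min <= 0)) stop("tau must be positive")
  if (any(delta_pcr_mM < 0)) stop("delta PCr must be non-negative")
  delta_pcr_mM / tau_min
}

#' Force-normalized PCr rate (cost index)
#'
#' Ratio of a PCr rate to the force produced in the matching exercise
#' window: VPCr_stim over begin-exercise force gives the non-oxidative cost
#' of contraction, VPCr_rec over end-exercise force the oxidative
#' counterpart. The raw ratio has units (mM/min)/N; \code{scale} (default 1)
#' lets callers report the x1000 convention.
#'
#' @param v_pcr rate (mM/min)
#' @param force_N force in the reference window (N), > 0
#' @param scale multiplier applied to the ratio
#' @return cost index
#' @export
pcrCost <- function(v_pcr, force_N, scale = 1) {
  if (any(force_N <= 0)) stop("force must be positive")
  scale * v_pcr / force_N
}

#' ADP-corrected maximal oxidative capacity
#'
#' Vmax = VPCr_rec * (1 + Km / [ADP_end]): the end-exercise rate of
#' oxidative ATP production corrected for the Michaelis-Menten ADP
#' dependence of mitochondrial respiration. Decreasing in [ADP_end] toward
#' the asymptote VPCr_rec; equal to it when Km = 0.
#'
#' @param v_pcr_rec recovery rate (mM/min)
#' @param adp_end_uM end-exercise ADP (uM), > 0
#' @param constants list from \code{\link{physioConstants}} (supplies Km)
#' @return Vmax in mM/min
#' @examples
#' vMax(3.08, 48.94)  # 4.97 mM/min
#' @export
vMax <- function(v_pcr_rec, adp_end_uM, constants = physioConstants()) {
  if (any(adp_end_uM <= 0)) stop("ADP_end must be positive")
  v_pcr_rec * (1 + constants$km_adp_uM / adp_end_uM)
}

#' Summarize PCr kinetics and energetic indices for one experiment
#'
#' Orchestrates the depletion and recovery fits on a
#' \linkS4class{MetaboliteTimeSeries} and derives every index: the two time
#' constants and amplitudes, end-exercise depletion (last exercise bin vs
#' rest), VPCr_stim and VPCr_rec, the ADP-corrected Vmax, and - when a
#' force summary is supplied - the force-normalized costs.
#'
#' The depletion amplitude feeding VPCr_stim comes from the depletion fit;
#' the recovery amplitude feeding VPCr_rec from the recovery fit. The two
#' can differ under noise and both are reported. Bins flagged unconverged
#' are dropped from the fits.
#'
#' @param series a \linkS4class{MetaboliteTimeSeries} with all three phases
#' @param force_summary optional list with \code{force_begin_N} and
#'   \code{force_end_N} (see \code{\link{binForceToMrs}})
#' @param constants list from \code{\link{physioConstants}}
#' @param cost_scale multiplier for the cost indices (see \code{\link{pcrCost}})
#' @return a \linkS4class{KineticsResult}
#' @export
summarizeKinetics <- function(series, force_summary = NULL,
                              constants = physioConstants(), cost_scale = 1) {
  stopifnot(is(series, "MetaboliteTimeSeries"))
  d <- series@data
  for (ph in c("rest", "exercise", "recovery"))
    if (!any(d$phase == ph)) stop("series lacks phase: ", ph)
  ex <- d[d$phase == "exercise" & d$converged, ]
  rc <- d[d$phase == "recovery" & d$converged, ]
  dep <- fitDepletion(ex$time_min - series@exercise_start_min, ex$pcr_mM)
  rec <- fitRecovery(rc$time_min - series@recovery_start_min, rc$pcr_mM)
  last_ex <- ex[nrow(ex), ]
  delta_pct <- last_ex$pcr_pct - 100
  adp_end <- last_ex$adp_uM
  v_stim <- if (dep$converged) vPcr(max(dep$amplitude, 0), dep$tau_min) else NA_real_
  v_rec <- if (rec$converged) vPcr(max(rec$amplitude, 0), rec$tau_min) else NA_real_
  vm <- if (is.finite(v_rec) && is.finite(adp_end) && adp_end > 0)
    vMax(v_rec, adp_end, constants) else NA_real_
  cost <- rec_cost <- NA_real_
  if (!is.null(force_summary)) {
    if (is.finite(v_stim)) cost <- pcrCost(v_stim, force_summary$force_begin_N,
                                           cost_scale)
    if (is.finite(v_rec)) rec_cost <- pcrCost(v_rec, force_summary$force_end_N,
                                              cost_scale)
  }
  new("KineticsResult",
      tau_stim_min = dep$tau_min, tau_rec_min = rec$tau_min,
      delta_pcr_mM_stim = dep$amplitude, delta_pcr_mM_rec = rec$amplitude,
      delta_pcr_pct = delta_pct,
      v_pcr_stim_mM_per_min = v_stim, v_pcr_rec_mM_per_min = v_rec,
      pcr_cost = cost, pcr_rec_cost = rec_cost,
      v_max_mM_per_min = vm, adp_end_uM = adp_end,
      diagnostics = list(depletion = dep, recovery = rec))
}
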