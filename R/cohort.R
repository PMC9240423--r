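# Cohort-level simulation: per-animal parameter draws from group-level
# normal distributions, optionally materialized into full input bundles.

#' Default group specifications (control vs hydroxyurea-treated)
#'
#' Group means and SDs for the per-animal physiology: muscle volume, T2,
#' basal PCr, depletion, time constants, pH excursion and the force
#' envelope. CON and HU values follow the reference cohort
#' (n = 9 control, n = 8 treated).
#'
#' @return named list of group specs; each spec is a named list of
#'   \code{c(mean, sd)} pairs
#' @export
defaultGroupSpecs <- function() {
  list(
    CON = list(
      muscle_volume_mm3 = c(154.76, 15.82),
      t2_ga_ms = c(30.79, 1.70),
      t2_ta_ms = c(25.74, 0.63),
      pcr_rest_mM = c(16, 1),
      depletion_frac = c(-0.5645, 0.0614),
      tau_stim_min = c(1.57, 0.39),
      tau_rec_min = c(2.19, 0.42),
      ph_rest = c(7.25, 0.08),
      ph_drop = c(0.28, 0.09),
      peak_force_mN = c(170, 20),
      specific_tfp = c(437.43, 57.10)
    ),
    HU = list(
      muscle_volume_mm3 = c(158.93, 15.41),
      t2_ga_ms = c(29.43, 0.84),
      t2_ta_ms = c(25.33, 0.55),
      pcr_rest_mM = c(16, 1),
      depletion_frac = c(-0.5868, 0.0812),
      tau_stim_min = c(2.03, 0.90),
      tau_rec_min = c(2.12, 0.43),
      ph_rest = c(7.27, 0.09),
      ph_drop = c(0.25, 0.10),
      peak_force_mN = c(205, 22),
      specific_tfp = c(501.35, 54.12)
    )
  )
}

#' Draw a synthetic cohort
#'
#' Per-animal parameters are drawn independently from the stated normal
#' distributions of each group spec; a fixed seed reproduces the cohort
#' exactly. Draws of bounded parameters are clamped to their physiologic
#' domain (depletion within (-0.95, -0.05), taus and volumes positive) so
#' extreme tails cannot produce invalid ground truth.
#'
#' @param group_specs named list of group specs (see
#'   \code{\link{defaultGroupSpecs}})
#' @param n_per_group animals per group (single value or one per group),
#'   >= 1; cohort statistics require >= 2
#' @param seed RNG seed
#' @return data.frame, one row per animal: id, group, and one column per
#'   drawn parameter
#' @export
generateCohort <- function(group_specs = defaultGroupSpecs(), n_per_group = 9L,
                           seed = 1L) {
  if (length(n_per_group) == 1L)
    n_per_group <- rep(n_per_group, length(group_specs))
  if (any(n_per_group < 1L)) stop("n_per_group must be >= 1")
  for (g in names(group_specs))
    for (p in names(group_specs[[g]]))
      if (group_specs[[g]][[p]][2L] < 0)
        stop("negative SD for ", p, " in group ", g)
  .withSeed(seed, {
    rows <- list()
    for (gi in seq_along(group_specs)) {
      g <- names(group_specs)[gi]
      spec <- group_specs[[gi]]
      for (a in seq_len(n_per_group[gi])) {
        draw <- vapply(spec, function(ms) rnorm(1, ms[1L], ms[2L]), 0)
        if ("depletion_frac" %in% names(draw))
          draw[["depletion_frac"]] <- min(max(draw[["depletion_frac"]], -0.95), -0.05)
        for (p in c("tau_stim_min", "tau_rec_min", "muscle_volume_mm3",
                    "t2_ga_ms", "t2_ta_ms", "pcr_rest_mM", "peak_force_mN"))
          if (p %in% names(draw)) draw[[p]] <- max(draw[[p]], 1e-3)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(id = sprintf("%s_%02d", g, a), group = g),
                as.data.frame(as.list(draw)))
      }
    }
    do.call(rbind, rows)
  })
}

#' Materialize the full input bundle for one simulated animal
#'
#' Turns one row of a cohort table into the inputs the analysis pipeline
#' consumes: a dynamic FID series, a multi-echo stack with an ROI mask, a
#' force trace and per-slice ROI areas for volumetry.
#'
#' @param params one-row data.frame (or named list) of animal parameters as
#'   drawn by \code{\link{generateCohort}}
#' @param protocol an \linkS4class{AcquisitionProtocol}
#' @param noise_sd FID noise level (0 = noiseless)
#' @param image_size pixels per side of the synthetic image slices
#' @param n_slices slices in the multi-echo stack
#' @param seed RNG seed
#' @return list: fids, stack, masks, trace, roi_areas_mm2, params
#' @export
simulateAnimal <- function(params, protocol = acquisitionProtocol(),
                           noise_sd = 0, image_size = 16L, n_slices = 2L,
                           seed = 1L) {
  p <- as.list(params)
  truth <- kineticsGroundTruth(
    pcr_rest_mM = p$pcr_rest_mM %||% 16,
    depletion_frac = p$depletion_frac %||% -0.5645,
    tau_stim_min = p$tau_stim_min %||% 1.57,
    tau_rec_min = p$tau_rec_min %||% 2.19,
    ph_rest = p$ph_rest %||% 7.25,
    ph_end_exercise = (p$ph_rest %||% 7.25) - (p$ph_drop %||% 0.28),
    noise_sd = noise_sd, seed = .childSeed(seed, 1L))
  fids <- generateFidSeries(protocol, truth)
  H <- image_size
  t2map <- array(p$t2_ga_ms %||% 30.79, c(H, H, n_slices))
  stack <- generateMultiechoStack(c(H, H), defaultEchoTimes(), t2map,
                                  s0_map = 1000, noise_sd = 0,
                                  seed = .childSeed(seed, 2L),
                                  n_slice = n_slices)
  masks <- array(0L, c(H, H, n_slices))
  core <- seq.int(max(1L, H %/% 4), min(H, 3L * H %/% 4))
  masks[core, core, ] <- 1L
  trace <- generateForceTrace(
    protocol, list(peak_mN = p$peak_force_mN %||% 170),
    seed = .childSeed(seed, 3L))
  # six slice areas shaped like a muscle belly, scaled to the drawn volume
  shape <- c(0.7, 0.9, 1, 1, 0.9, 0.7)
  vol1 <- truncatedConeVolume(shape, 1, 0.25)
  areas <- shape * (p$muscle_volume_mm3 %||% 154.76) / vol1
  list(fids = fids, stack = stack, masks = masks, trace = trace,
       roi_areas_mm2 = areas, params = p)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1L])) b else a
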