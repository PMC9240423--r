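# End-to-end orchestration: per-animal analysis, cohort aggregation and the
# group-comparison statistics.

#' Run the full analysis for one animal
#'
#' Executes every stage on one input bundle: spectral quantification of the
#' FID series, metabolite time-series construction, PCr kinetics with the
#' force-normalized indices, pixel-wise T2 mapping with ROI means, and
#' truncated-cone volumetry. Deterministic given its inputs; any stage
#' failure is re-thrown as a structured error naming the stage.
#'
#' @param bundle list with elements \code{fids} (\linkS4class{FIDSeries}),
#'   \code{stack} (\linkS4class{EchoImageStack}), \code{masks} (label
#'   array), \code{trace} (\linkS4class{ForceTrace}),
#'   \code{roi_areas_mm2} (per-slice areas)
#' @param priors spectral prior knowledge (see \code{\link{defaultPriors}})
#' @param constants list from \code{\link{physioConstants}}
#' @param thickness_mm,gap_mm volumetry slice geometry
#' @param id,group labels carried onto the result
#' @return list of class \code{AnimalResult}: id, group, series
#'   (\linkS4class{MetaboliteTimeSeries}), kinetics
#'   (\linkS4class{KineticsResult}), t2 (ROI summary), volume_mm3, force
#'   (ForceSummary), flags (character vector of every non-fatal flag raised)
#' @export
runAnimal <- function(bundle, priors = defaultPriors(),
                      constants = physioConstants(),
                      thickness_mm = 1, gap_mm = 0.25,
                      id = "animal", group = NA_character_) {
  need <- c("fids", "stack", "masks", "trace", "roi_areas_mm2")
  missing <- setdiff(need, names(bundle))
  if (length(missing))
    stop("input bundle incomplete; missing stage input(s): ",
         paste(missing, collapse = ", "))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  flags <- character()
  quant <- stage("spectral_quant", quantifySeries(bundle$fids, priors))
  if (!all(quant$converged))
    flags <- c(flags, sprintf("%d unconverged spectral fits",
                              sum(!quant$converged)))
  series <- stage("metabolite_series",
                  buildMetaboliteSeries(quant, protocol(bundle$fids), constants))
  volume <- stage("t2_volume",
                  truncatedConeVolume(bundle$roi_areas_mm2, thickness_mm, gap_mm))
  force <- stage("force", forceSummary(bundle$trace, protocol(bundle$fids),
                                       volume))
  kin <- stage("kinetics", summarizeKinetics(series, force, constants))
  t2map <- stage("t2_volume", fitT2Map(bundle$stack, mask = bundle$masks))
  t2roi <- stage("t2_volume", roiMeanT2(t2map, bundle$masks, 1L))
  if (t2roi$n_invalid > 0)
    flags <- c(flags, sprintf("%d invalid T2 pixels in ROI", t2roi$n_invalid))
  structure(list(id = id, group = group, series = series, kinetics = kin,
                 t2 = t2roi, volume_mm3 = volume, force = force,
                 flags = flags), class = "AnimalResult")
}

#' Flatten an AnimalResult to a one-row summary
#'
#' @param result an \code{AnimalResult} from \code{\link{runAnimal}}
#' @return one-row data.frame of scalar endpoints
#' @export
animalSummaryRow <- function(result) {
  k <- asTable(result$kinetics)
  cbind(data.frame(id = result$id, group = result$group),
        k,
        data.frame(t2_ga_ms = result$t2$mean_t2_ms,
                   volume_mm3 = result$volume_mm3,
                   tfp_mN = result$force$tfp_mN,
                   specific_tfp = as.numeric(result$force$specific_tfp),
                   specific_pf = as.numeric(result$force$specific_pf)))
}

#' Group comparison with normality-gated test selection
#'
#' Per variable: Shapiro-Wilk on each group; when both groups pass at
#' \code{alpha_normality} a Welch two-sample t-test is used, otherwise a
#' Wilcoxon rank-sum test. Constant-valued groups (normality undefined)
#' fall back to Wilcoxon and are flagged. The test actually used is always
#' recorded.
#'
#' @param results data.frame with a \code{group} column and the variables
#' @param variables character vector of column names to compare
#' @param alpha_normality Shapiro-Wilk gate (default 0.05)
#' @return data.frame, one row per variable: per-group mean/SD/n, normality
#'   p-values, test used, p-value, significance at 0.05, flag
#' @export
compareGroups <- function(results, variables, alpha_normality = 0.05) {
  stopifnot("group" %in% names(results))
  groups <- unique(results$group)
  if (length(groups) != 2L) stop("exactly two groups required")
  g1 <- groups[1L]; g2 <- groups[2L]
  rows <- lapply(variables, function(v) {
    x <- results[results$group == g1, v]
    y <- results[results$group == g2, v]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L)
      stop("need >= 2 animals per group for variable ", v)
    flag <- ""
    sw <- function(z) {
      if (length(unique(z)) == 1L || length(z) < 3L) return(NA_real_)
      shapiro.test(z)$p.value
    }
    p1 <- sw(x); p2 <- sw(y)
    normal <- !is.na(p1) && !is.na(p2) &&
      p1 > alpha_normality && p2 > alpha_normality
    if (is.na(p1) || is.na(p2)) flag <- "normality undefined; Wilcoxon fallback"
    if (normal) {
      test <- "Welch"
      pv <- t.test(x, y, var.equal = FALSE)$p.value
    } else {
      test <- "Wilcoxon"
      pv <- suppressWarnings(wilcox.test(x, y, exact = NULL)$p.value)
    }
    out <- data.frame(variable = v,
                      mean_1 = mean(x), sd_1 = sd(x), n_1 = length(x),
                      mean_2 = mean(y), sd_2 = sd(y), n_2 = length(y),
                      shapiro_p_1 = p1, shapiro_p_2 = p2,
                      test = test, p_value = pv,
                      significant = pv < 0.05, flag = flag)
    names(out) <- sub("_1$", paste0("_", g1), names(out))
    names(out) <- sub("_2$", paste0("_", g2), names(out))
    out
  })
  do.call(rbind, rows)
}

#' Percent difference between two group means
#'
#' 100 * (mean_a - mean_b) / mean_b, the convention used to report a
#' treated-vs-control contrast.
#'
#' @param mean_a,mean_b group means; \code{mean_b} is the reference and
#'   must be nonzero
#' @return percent difference
#' @examples
#' percentDifference(501.35, 437.43)  # +14.6
#' @export
percentDifference <- function(mean_a, mean_b) {
  if (any(mean_b == 0)) stop("reference mean must be nonzero")
  100 * (mean_a - mean_b) / mean_b
}
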