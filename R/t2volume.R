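# Multi-echo T2 relaxometry (pixel-wise single-exponential mapping, ROI
# summaries) and truncated-cone muscle volumetry.

#' Fit a single pixel's echo decay
#'
#' Two-parameter least-squares fit of S(TE) = S0 exp(-TE/T2), no offset.
#' \code{method = "nls"} (default) minimizes squared residuals on the signal
#' scale by Levenberg-Marquardt, initialised from the log-linear solution;
#' \code{method = "loglin"} returns the log-linear regression itself
#' (ordinary least squares of log S on TE). Non-positive or non-decaying
#' signals are flagged invalid rather than fitted.
#'
#' @param signal magnitude signal per echo
#' @param te_ms echo times (ms), >= 3
#' @param method "nls" or "loglin"
#' @return list: t2_ms, s0, valid
#' @export
fitT2Pixel <- function(signal, te_ms, method = c("nls", "loglin")) {
  method <- match.arg(method)
  if (length(te_ms) < 3L) stop("need at least 3 echoes")
  if (length(signal) != length(te_ms)) stop("signal/te length mismatch")
  invalid <- list(t2_ms = NA_real_, s0 = NA_real_, valid = FALSE)
  if (any(!is.finite(signal)) || any(signal <= 0)) return(invalid)
  co <- coef(lm(log(signal) ~ te_ms))
  if (!is.finite(co[2L]) || co[2L] >= 0) return(invalid)  # non-decaying
  t2 <- unname(-1 / co[2L]); s0 <- unname(exp(co[1L]))
  if (method == "nls") {
    fit <- minpack.lm::nls.lm(c(s0 = s0, t2 = t2),
                              lower = c(0, 1e-6), upper = c(Inf, Inf),
                              fn = function(p) p[1L] * exp(-te_ms / p[2L]) - signal,
                              control = minpack.lm::nls.lm.control(
                                ftol = 1e-12, ptol = 1e-12, maxiter = 200L))
    if (fit$info %in% c(1L, 2L, 3L, 4L)) {
      s0 <- unname(fit$par[1L]); t2 <- unname(fit$par[2L])
    }
  }
  if (!is.finite(t2) || t2 <= 0) return(invalid)
  list(t2_ms = t2, s0 = s0, valid = TRUE)
}

#' Pixel-wise T2 mapping of a multi-echo stack
#'
#' Applies \code{\link{fitT2Pixel}} to every pixel of every slice. Pixels
#' whose signal is non-positive or non-decaying are marked invalid and
#' excluded from downstream ROI means.
#'
#' @param stack an \linkS4class{EchoImageStack}
#' @param method fit method, see \code{\link{fitT2Pixel}}
#' @param mask optional logical/integer array [H x W x n_slice]; only pixels
#'   with mask > 0 are fitted (all pixels when NULL)
#' @return a \linkS4class{T2Map}
#' @export
fitT2Map <- function(stack, method = c("nls", "loglin"), mask = NULL) {
  method <- match.arg(method)
  stopifnot(is(stack, "EchoImageStack"))
  d <- dim(stack@data)
  H <- d[1L]; W <- d[2L]; nS <- d[4L]
  t2 <- s0 <- array(NA_real_, c(H, W, nS))
  valid <- array(FALSE, c(H, W, nS))
  for (s in seq_len(nS)) {
    for (i in seq_len(H)) for (j in seq_len(W)) {
      if (!is.null(mask) && !(mask[i, j, s] > 0)) next
      f <- fitT2Pixel(stack@data[i, j, , s], stack@te_ms, method)
      t2[i, j, s] <- f$t2_ms; s0[i, j, s] <- f$s0; valid[i, j, s] <- f$valid
    }
  }
  new("T2Map", t2_ms = t2, s0 = s0, valid = valid)
}

#' ROI-mean T2 over the two largest consecutive slices
#'
#' For a labelled ROI, selects the consecutive slice pair maximizing the
#' summed ROI pixel count (the "2 largest consecutive slices" rule; a
#' single-slice map uses that slice alone) and averages T2 over the valid
#' ROI pixels of those slices.
#'
#' @param map a \linkS4class{T2Map}
#' @param roi_masks integer label array [H x W x n_slice]
#' @param label ROI label to summarize
#' @return list: mean_t2_ms, n_pixels, n_invalid, slices (indices used)
#' @export
roiMeanT2 <- function(map, roi_masks, label = 1L) {
  stopifnot(is(map, "T2Map"))
  if (!identical(dim(roi_masks), dim(map@t2_ms)))
    stop("roi_masks must match the map dimensions")
  nS <- dim(map@t2_ms)[3L]
  counts <- vapply(seq_len(nS), function(s) sum(roi_masks[, , s] == label), 0L)
  if (sum(counts) == 0L) stop("ROI with label ", label, " is empty")
  if (nS == 1L) slices <- 1L
  else {
    pair_sum <- counts[-nS] + counts[-1L]
    k <- which.max(pair_sum)
    slices <- c(k, k + 1L)
    if (pair_sum[k] == 0L) slices <- which.max(counts)  # ROI on one slice only
  }
  sel <- array(FALSE, dim(roi_masks))
  sel[, , slices] <- roi_masks[, , slices, drop = FALSE] == label
  vals <- map@t2_ms[sel & map@valid]
  n_inv <- sum(sel & !map@valid)
  if (!length(vals)) stop("no valid ROI pixels on the selected slices")
  list(mean_t2_ms = mean(vals), n_pixels = length(vals),
       n_invalid = n_inv, slices = slices)
}

#' Muscle volume from slice ROI areas (truncated-cone formula)
#'
#' Each slice contributes a cylinder A_i * thickness; each inter-slice gap
#' contributes a conical frustum (gap/3) (A_i + A_{i+1} + sqrt(A_i A_{i+1})).
#' With equal areas this collapses to the cylinder A (k t + (k-1) g); with a
#' vanishing second area the gap term becomes the cone limit A g / 3.
#'
#' @param areas_mm2 per-slice ROI areas (mm^2), >= 2 slices, >= 0
#' @param thickness_mm slice thickness (mm), default 1
#' @param gap_mm inter-slice gap (mm), default 0.25
#' @return total volume (mm^3)
#' @examples
#' truncatedConeVolume(c(10, 20), 1, 0.25)  # 33.678 mm^3
#' @export
truncatedConeVolume <- function(areas_mm2, thickness_mm = 1, gap_mm = 0.25) {
  if (length(areas_mm2) < 2L) stop("need at least 2 slices")
  if (any(areas_mm2 < 0) || thickness_mm < 0 || gap_mm < 0)
    stop("areas, thickness and gap must be non-negative")
  a <- areas_mm2
  slab <- sum(a) * thickness_mm
  i <- seq_len(length(a) - 1L)
  gaps <- sum(gap_mm / 3 * (a[i] + a[i + 1L] + sqrt(a[i] * a[i + 1L])))
  slab + gaps
}
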