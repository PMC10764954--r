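#' Noise variance in a region of interest
#'
#' Unbiased sample variance of voxel values in the ROI (conventionally the
#' adipose compartment), in (1/cm)^2.
#'
#' @param vol a [ct_volume()].
#' @param roi logical array matching the volume.
#' @return variance, (1/cm)^2.
#' @export
noise_variance <- function(vol, roi) {
  stopifnot(identical(dim(roi), dim(vol$values)))
  v <- vol$values[roi]
  if (length(v) < 2) stop("ROI must contain at least two voxels")
  stats::var(v)
}

#' Signal-difference-to-noise ratio between two tissues
#'
#' `(mean_fibroglandular - mean_adipose) / sd`, with the noise term taken
#' from the adipose ROI by default (`denominator = "adipose"`) or from the
#' pooled standard deviation of both ROIs.
#'
#' @param vol a [ct_volume()].
#' @param roi_fibroglandular,roi_adipose logical arrays.
#' @param denominator `"adipose"` (default) or `"pooled"`.
#' @return unitless SDNR.
#' @export
sdnr <- function(vol, roi_fibroglandular, roi_adipose,
                 denominator = c("adipose", "pooled")) {
  denominator <- match.arg(denominator)
  fg <- vol$values[roi_fibroglandular]
  ad <- vol$values[roi_adipose]
  stopifnot(length(fg) > 1, length(ad) > 1)
  s <- if (denominator == "adipose") stats::sd(ad)
       else sqrt((stats::var(fg) * (length(fg) - 1) +
                  stats::var(ad) * (length(ad) - 1)) /
                 (length(fg) + length(ad) - 2))
  if (s == 0) stop("zero noise denominator")
  (mean(fg) - mean(ad)) / s
}

#' Full width at half maximum of a small object's profile
#'
#' Extracts a 1D profile through `center` along a named anatomical axis
#' (ML = mediolateral = world `x`; SI = superior-inferior = world `z`) by
#' trilinear interpolation, estimates the background as the median of the
#' profile's two end quarters, locates the half-maximum crossings on either
#' side of the peak by linear interpolation between samples, and returns
#' their distance.
#'
#' @param vol a [ct_volume()].
#' @param center world position of the object (e.g. a calcification), mm.
#' @param direction `"ML"` or `"SI"`.
#' @param half_window profile half-length, mm (default 10); must contain the
#'   full peak.
#' @param step profile sampling step, mm (default half the voxel pitch).
#' @return FWHM, mm.
#' @export
fwhm_profile <- function(vol, center, direction = c("ML", "SI"),
                         half_window = 10, step = vol$pitch / 2) {
  direction <- match.arg(direction)
  axis <- if (direction == "ML") c(1, 0, 0) else c(0, 0, 1)
  t <- seq(-half_window, half_window, by = step)
  pts <- cbind(center[1] + t * axis[1], center[2] + t * axis[2],
               center[3] + t * axis[3])
  prof <- interp_volume(vol, pts)
  n <- length(prof)
  q <- max(2L, n %/% 4)
  bg <- stats::median(c(prof[seq_len(q)], prof[seq(n - q + 1, n)]))
  ipk <- which.max(prof)
  peak <- prof[ipk]
  if (peak <= bg) stop("peak not above background in profile window")
  half <- bg + (peak - bg) / 2
  cross <- function(idx) {  # linear interpolation between bracketing samples
    i <- idx[1]; j <- idx[2]
    t[i] + (half - prof[i]) / (prof[j] - prof[i]) * (t[j] - t[i])
  }
  left <- NULL
  if (ipk >= 2) for (i in seq(ipk, 2L, by = -1L))
    if (prof[i - 1] <= half && prof[i] > half) {
      left <- cross(c(i - 1, i)); break
    }
  right <- NULL
  if (ipk <= n - 1) for (i in seq(ipk, n - 1L))
    if (prof[i + 1] <= half && prof[i] > half) {
      right <- cross(c(i + 1, i)); break
    }
  if (is.null(left) || is.null(right))
    stop("half-maximum crossings not bracketed inside the window")
  right - left
}

#' Paired comparison with a normality gate
#'
#' Applies a Shapiro-Wilk test to the paired differences; if normality is not
#' rejected at `alpha`, a paired t-test is used, otherwise a Wilcoxon
#' signed-rank test. Standard test implementations are delegated to
#' `stats`; the gating logic is this function's contract. All-zero
#' differences (degenerate for the signed-rank test) are flagged.
#'
#' @param metric_a,metric_b per-case metric values (equal length >= 5).
#' @param alpha significance level for the normality gate.
#' @return list with `shapiro_p`, `test` (`"t"`, `"wilcoxon"` or
#'   `"degenerate"`), `p_value`, `mean_diff`.
#' @export
paired_compare <- function(metric_a, metric_b, alpha = 0.05) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 5)
  d <- metric_a - metric_b
  if (all(d == 0)) {
    return(list(shapiro_p = NA_real_, test = "degenerate",
                p_value = NA_real_, mean_diff = 0))
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value >= alpha) {
    tt <- stats::t.test(metric_a, metric_b, paired = TRUE)
    list(shapiro_p = sw$p.value, test = "t", p_value = tt$p.value,
         mean_diff = mean(d))
  } else {
    wt <- stats::wilcox.test(metric_a, metric_b, paired = TRUE, exact = FALSE)
    list(shapiro_p = sw$p.value, test = "wilcoxon", p_value = wt$p.value,
         mean_diff = mean(d))
  }
}

#' Image-quality report for a reconstruction against phantom truth
#'
#' Computes the four standard metrics on one volume: adipose noise variance,
#' fibroglandular-vs-adipose SDNR, and the FWHM of the first annotated
#' calcification along the ML and SI axes. ROIs come from the phantom
#' annotation masks, eroded to interior voxels by requiring the same label in
#' a one-voxel neighborhood is not applied here; pass eroded masks for edge-
#' free statistics if needed.
#'
#' FWHM is evaluated per annotated calcification; `fwhm_ml`/`fwhm_si` are the
#' means over calcifications whose profiles yield a valid measurement (a
#' single small object at coarse voxel pitch is quantization-limited - one
#' profile interpolation step of half a voxel on a few-mm object is a
#' double-digit relative error - so the per-case value is the average across
#' calcifications, with the per-object values reported alongside).
#'
#' @param vol a [ct_volume()] on the phantom grid.
#' @param annotation a phantom annotation (see [generate_phantom()]).
#' @param fwhm_half_window profile half-window, mm.
#' @return list with `noise_variance`, `sdnr`, `fwhm_ml`, `fwhm_si` (means;
#'   `NA` if the phantom has no measurable calcification) and per-object
#'   vectors `fwhm_ml_each`, `fwhm_si_each`.
#' @export
metrics_report <- function(vol, annotation, fwhm_half_window = 10) {
  m <- annotation$masks
  out <- list(noise_variance = noise_variance(vol, m$adipose),
              sdnr = sdnr(vol, m$fibroglandular, m$adipose),
              fwhm_ml = NA_real_, fwhm_si = NA_real_,
              fwhm_ml_each = numeric(0), fwhm_si_each = numeric(0))
  cc <- annotation$calcifications
  if (nrow(cc) > 0) {
    one <- function(i, dir) tryCatch(
      fwhm_profile(vol, c(cc$x[i], cc$y[i], cc$z[i]), dir, fwhm_half_window),
      error = function(e) NA_real_)
    out$fwhm_ml_each <- vapply(seq_len(nrow(cc)), one, numeric(1), dir = "ML")
    out$fwhm_si_each <- vapply(seq_len(nrow(cc)), one, numeric(1), dir = "SI")
    out$fwhm_ml <- mean(out$fwhm_ml_each, na.rm = TRUE)
    out$fwhm_si <- mean(out$fwhm_si_each, na.rm = TRUE)
  }
  out
}
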