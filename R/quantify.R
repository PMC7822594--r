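#' Pixels of a disk around a point
#'
#' Row/column indices of the pixels within Euclidean distance `radius` of a
#' (possibly fractional) center, clipped to the image bounds. Used to dilate
#' a detected spindle pole body point into the small region over which the
#' probe maximum is taken.
#'
#' @param center `c(row, col)` center (1-based, may be fractional).
#' @param radius Disk radius in pixels.
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @return Two-column integer matrix of (row, col) indices.
#' @keywords internal
disk_pixels <- function(center, radius, dim) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(dim[1], ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(dim[2], ceiling(center[2] + radius))
  g <- expand.grid(row = r0:r1, col = c0:c1)
  d2 <- (g$row - center[1])^2 + (g$col - center[2])^2
  as.matrix(g[d2 <= radius^2, , drop = FALSE])
}

#' Relative enrichment of a probe at a spindle pole body
#'
#' Maximum probe intensity within a disk of `dilation_radius` pixels around
#' the SPB point (the SPB itself is diffraction-limited, so the dilated
#' maximum captures its signal), normalized to the median probe intensity in
#' the cytosol, minus one:
#' `max(probe in dilated SPB) / median(probe in cytosol) - 1`.
#' Intensities are assumed background-subtracted; the statistic is invariant
#' to a global multiplicative gain.
#'
#' @param probe Background-subtracted probe image (matrix, rows x cols).
#' @param spb_point `c(row, col)` SPB coordinates.
#' @param cytosol_mask Logical matrix selecting cytosolic pixels (cell area
#'   minus marker areas), same dimensions as `probe`.
#' @param dilation_radius Disk radius in pixels (default 2).
#' @return Unitless relative enrichment (>= -1).
#' @export
spb_enrichment <- function(probe, spb_point, cytosol_mask, dilation_radius = 2) {
  stopifnot(is.matrix(probe), identical(dim(probe), dim(cytosol_mask)))
  if (!any(cytosol_mask)) stop("empty cytosol mask")
  cyt <- stats::median(probe[cytosol_mask])
  if (!is.finite(cyt) || cyt <= 0) stop("non-positive cytosol median")
  px <- disk_pixels(spb_point, dilation_radius, dim(probe))
  max(probe[px]) / cyt - 1
}

#' Relative enrichment of a probe in the nucleolus
#'
#' Median probe intensity within the nucleolus mask (segmented from the
#' nucleolar marker) over the median in the cytosol, minus one.
#'
#' @param probe Background-subtracted probe image.
#' @param nucleolus_mask,cytosol_mask Logical masks, dimensions of `probe`.
#' @return Unitless relative enrichment (>= -1).
#' @export
nucleolar_enrichment <- function(probe, nucleolus_mask, cytosol_mask) {
  stopifnot(identical(dim(probe), dim(nucleolus_mask)),
            identical(dim(probe), dim(cytosol_mask)))
  if (!any(nucleolus_mask)) stop("empty nucleolus mask")
  if (!any(cytosol_mask)) stop("empty cytosol mask")
  cyt <- stats::median(probe[cytosol_mask])
  if (!is.finite(cyt) || cyt <= 0) stop("non-positive cytosol median")
  stats::median(probe[nucleolus_mask]) / cyt - 1
}

#' Coefficient of variation of reporter pixels in a dividing cell
#'
#' Translocation statistic for a nuclear-to-cytoplasmic reporter: the
#' coefficient of variation (standard deviation over mean) of the pixel
#' intensities within the dividing cell (mother plus bud). A nuclear-
#' concentrated reporter gives a high CV; uniform redistribution into the
#' cytoplasm drives it toward the noise floor. Invariant to multiplicative
#' gain; an additive offset lowers it, so pixels should be
#' background-subtracted.
#'
#' @param pixels Numeric vector of reporter pixel intensities (>= 2 values).
#' @param population Use the population (n) rather than sample (n - 1)
#'   standard deviation. Default `TRUE`: the pixels are the complete
#'   population of the cell, not a sample from it.
#' @return Unitless CV.
#' @export
reporter_cv <- function(pixels, population = TRUE) {
  pixels <- as.numeric(pixels[!is.na(pixels)])
  if (length(pixels) < 2L) stop("need at least 2 pixels")
  m <- mean(pixels)
  if (m <= 0) stop("non-positive mean intensity")
  s <- stats::sd(pixels)
  if (population) s <- s * sqrt((length(pixels) - 1) / length(pixels))
  s / m
}

#' Per-pixel nucleolar Cdc14/Cfi1 ratio
#'
#' Mean over nucleolus pixels of the per-pixel ratio of Cdc14 to Cfi1/Net1
#' intensity; the readout of Cdc14 sequestration on its nucleolar anchor.
#' Pixels whose denominator falls below `floor_frac` of the median Cfi1
#' intensity in the mask are excluded to avoid ratio blow-up.
#'
#' @param cdc14,cfi1 Background-subtracted channel images (matrices).
#' @param nucleolus_mask Logical mask of the nucleolus.
#' @param floor_frac Denominator floor as a fraction of the in-mask median
#'   Cfi1 intensity (default 0.05).
#' @return Mean per-pixel ratio (unitless).
#' @export
nucleolar_ratio <- function(cdc14, cfi1, nucleolus_mask, floor_frac = 0.05) {
  stopifnot(identical(dim(cdc14), dim(cfi1)),
            identical(dim(cdc14), dim(nucleolus_mask)))
  if (!any(nucleolus_mask)) stop("empty nucleolus mask")
  den <- cfi1[nucleolus_mask]
  num <- cdc14[nucleolus_mask]
  floor_val <- floor_frac * stats::median(den)
  ok <- den > pmax(floor_val, 0)
  if (!any(ok)) stop("no nucleolus pixels above the denominator floor")
  mean(num[ok] / den[ok])
}

#' Relative release of Cdc14 from the nucleolus
#'
#' From a per-frame nucleolar `I_Cdc14 / I_Cfi1` ratio trace, quantifies how
#' completely Cdc14 left the nucleolus:
#' `1 - ratio(t_min) / ratio(t_-20)`, where `t_-20` is the frame 20 min
#' before the daughter SPB entered the bud (the pre-release baseline) and
#' `t_min` is the frame with the minimal ratio searched from `t_-20` to the
#' end of the trace (earliest frame on ties). 0 for a constant trace, 1 for
#' complete release; never exceeds 1 for non-negative ratios.
#'
#' @param ratio_trace Per-frame nucleolar ratio values (> 0 where defined).
#' @param bud_entry_frame Frame (1-based) at which the dSPB entered the bud.
#' @param frame_interval Minutes per frame.
#' @param baseline_min Minutes before bud entry defining the baseline frame
#'   (default 20).
#' @return List with `relative_release`, `t_min`, `t_baseline` and `status`
#'   (`"ok"`, or `"insufficient-history"` when the trace does not reach 20
#'   min before bud entry, in which case the cell is excluded and the value
#'   is `NA`).
#' @export
relative_release <- function(ratio_trace, bud_entry_frame, frame_interval,
                             baseline_min = 20) {
  stopifnot(frame_interval > 0)
  n_back <- round(baseline_min / frame_interval)
  t_base <- as.integer(bud_entry_frame) - n_back
  if (t_base < 1L || is.na(ratio_trace[t_base])) {
    return(list(relative_release = NA_real_, t_min = NA_integer_,
                t_baseline = t_base, status = "insufficient-history"))
  }
  window <- seq.int(t_base, length(ratio_trace))
  vals <- ratio_trace[window]
  if (all(is.na(vals))) stop("ratio trace empty over the search window")
  t_min <- window[which.min(vals)]       # earliest frame attaining the minimum
  rel <- 1 - ratio_trace[t_min] / ratio_trace[t_base]
  list(relative_release = rel, t_min = t_min, t_baseline = t_base,
       status = "ok")
}

#' Detect anaphase onset from spindle length
#'
#' Anaphase onset is the first frame at which the spindle, measured as the
#' distance between the two spindle pole bodies, exceeds 3 um — with the
#' threshold required on `min_consecutive` consecutive frames to resist
#' single-frame detection noise.
#'
#' @param spb1,spb2 Two-column matrices of per-frame (row, col) SPB
#'   coordinates in pixels (`NA` rows where an SPB was not tracked).
#' @param pixel_size_um Pixel size, um/pixel.
#' @param threshold_um Spindle-length threshold (default 3 um).
#' @param min_consecutive Consecutive supra-threshold frames required
#'   (default 2).
#' @return Frame index of onset, or `NA_integer_` when the threshold is
#'   never crossed (no-event).
#' @export
detect_anaphase_onset <- function(spb1, spb2, pixel_size_um,
                                  threshold_um = 3, min_consecutive = 2L) {
  stopifnot(pixel_size_um > 0, nrow(spb1) == nrow(spb2))
  d_um <- sqrt(rowSums((spb1 - spb2)^2)) * pixel_size_um
  spindle_onset(d_um, threshold_um, min_consecutive)
}

#' @rdname detect_anaphase_onset
#' @param spindle_um Per-frame spindle lengths in um (alternative entry
#'   point when lengths are already computed).
#' @export
spindle_onset <- function(spindle_um, threshold_um = 3, min_consecutive = 2L) {
  above <- !is.na(spindle_um) & spindle_um > threshold_um
  if (min_consecutive <= 1L) {
    idx <- which(above)
    return(if (length(idx)) idx[1] else NA_integer_)
  }
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= min_consecutive) return(i - min_consecutive + 1L)
  }
  NA_integer_
}

#' Detect entry of the daughter SPB into the bud
#'
#' First frame at which the tracked SPB point lies inside the bud mask.
#'
#' @param spb_track Two-column matrix of per-frame SPB (row, col) pixel
#'   coordinates (`NA` where untracked).
#' @param bud_masks List of logical matrices, the bud mask per frame (`NULL`
#'   or all-`FALSE` before the bud exists).
#' @return Frame index of entry, or `NA_integer_` (no-event).
#' @export
detect_bud_entry <- function(spb_track, bud_masks) {
  stopifnot(nrow(spb_track) == length(bud_masks))
  for (i in seq_len(nrow(spb_track))) {
    p <- spb_track[i, ]
    m <- bud_masks[[i]]
    if (is.null(m) || any(is.na(p))) next
    r <- round(p[1]); c <- round(p[2])
    if (r >= 1 && c >= 1 && r <= nrow(m) && c <= ncol(m) && isTRUE(m[r, c])) {
      return(i)
    }
  }
  NA_integer_
}

#' Optogenetic recruitment slope
#'
#' Quantifies recruitment of a PIF-tagged target to a PhyB-anchored region
#' by ordinary least squares of target pixel intensities on anchor pixel
#' intensities within the cell, `I_PIF = alpha + beta * I_PhyB`. The slope
#' `beta` measures enrichment of the target in the anchored region and is
#' robust to target photobleaching and to the size/shape of the anchored
#' region.
#'
#' @param pif Target-channel pixel intensities (vector).
#' @param phyb Anchor-channel pixel intensities, same length.
#' @param min_pixels Minimum number of pixel pairs (default 10).
#' @return A `recruitment_fit`: list with `alpha`, `beta`, `se_beta`,
#'   `r_squared` and `n`.
#' @export
recruitment_slope <- function(pif, phyb, min_pixels = 10L) {
  ok <- !is.na(pif) & !is.na(phyb)
  pif <- as.numeric(pif[ok]); phyb <- as.numeric(phyb[ok])
  if (length(pif) < min_pixels) {
    stop(sprintf("need at least %d pixels", min_pixels))
  }
  if (stats::var(phyb) == 0) stop("zero variance in the PhyB channel")
  fit <- stats::lm(pif ~ phyb)
  sm <- summary(fit)
  structure(
    list(alpha = unname(stats::coef(fit)[1]),
         beta = unname(stats::coef(fit)[2]),
         se_beta = sm$coefficients["phyb", "Std. Error"],
         r_squared = sm$r.squared, n = length(pif)),
    class = "recruitment_fit"
  )
}

#' @export
print.recruitment_fit <- function(x, ...) {
  cat(sprintf("Recruitment fit: beta = %.4g (se %.3g), alpha = %.4g, n = %d\n",
              x$beta, x$se_beta, x$alpha, x$n))
  invisible(x)
}
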