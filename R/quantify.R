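#' Select the calibration ROI for the signal-intensity correction factor
#'
#' A square region of interest of physical extent `extent_mm` (default
#' 30 x 30 mm) is centred at the breast mask's in-plane centroid, on an
#' axial slice near the mask centroid that contains both fat and water:
#' candidate slices are visited in order of distance from the centroid
#' slice, and a slice qualifies when at least `min_class_fraction` of its
#' ROI voxels lie on each side of 0.5 on the uncorrected water-fraction map
#' `W / (W + F)`. If no slice reaches that balance but some slice contains
#' voxels of both classes, the slice with the most balanced class mix is
#' used with a warning; a breast whose ROI never contains both tissues is
#' an error. The ROI must lie inside the mask. The fat and water signal
#' maxima over the ROI become `f_max` and `w_max`.
#'
#' @param pair a `DixonPair`.
#' @param mask a `SegmentationMask` for one breast, on the pair's grid.
#' @param extent_mm in-plane ROI extent, mm (length 1 or 2).
#' @param min_class_fraction minimum fraction of ROI voxels in each tissue
#'   class for a slice to qualify.
#' @param robust if `TRUE`, use the 99th percentile instead of the absolute
#'   maximum (noise safety; the plain maximum is the default).
#' @return an `ROIRecord`: list with `slice`, `centre` (x, y voxel indices),
#'   `extent_mm`, `half_size_vox`, `f_max`, `w_max`.
#' @export
select_calibration_roi <- function(pair, mask, extent_mm = c(30, 30),
                                   min_class_fraction = 0.05,
                                   robust = FALSE) {
  stopifnot(inherits(pair, "DixonPair"), inherits(mask, "SegmentationMask"))
  if (!identical(dim(pair$water$data), dim(mask$mask)))
    stop("pair and mask must share one grid")
  if (length(extent_mm) == 1L) extent_mm <- rep(extent_mm, 2L)
  m <- mask$mask
  if (!any(m)) stop("empty mask")
  d <- dim(m)
  sp <- pair$water$spacing_mm
  nroi <- pmax(1L, as.integer(round(extent_mm / sp[1:2])))

  idx <- which(m, arr.ind = TRUE)
  ctr <- round(colMeans(idx))
  half_lo <- (nroi - 1L) %/% 2L
  half_hi <- nroi - 1L - half_lo
  x_rng <- (ctr[1] - half_lo[1]):(ctr[1] + half_hi[1])
  y_rng <- (ctr[2] - half_lo[2]):(ctr[2] + half_hi[2])
  if (min(x_rng) < 1L || max(x_rng) > d[1] || min(y_rng) < 1L || max(y_rng) > d[2])
    stop("calibration ROI does not fit inside the grid; reduce extent_mm")

  w <- pair$water$data; f <- pair$fat$data
  slices <- order(abs(seq_len(d[3]) - ctr[3]))
  pick <- if (robust) function(x) stats::quantile(x, 0.99, names = FALSE) else max
  record <- function(k, wroi, froi) {
    structure(list(slice = k, centre = ctr[1:2], extent_mm = extent_mm,
                   half_size_vox = nroi, f_max = pick(froi),
                   w_max = pick(wroi)),
              class = "ROIRecord")
  }
  best <- NULL; best_balance <- 0
  for (k in slices) {
    roi_mask <- m[x_rng, y_rng, k]
    if (!all(roi_mask)) next
    wroi <- w[x_rng, y_rng, k]; froi <- f[x_rng, y_rng, k]
    tot <- wroi + froi
    wf <- ifelse(tot > 0, wroi / tot, 0)
    frac_water <- mean(wf > 0.5)
    balance <- min(frac_water, 1 - frac_water)
    if (balance >= min_class_fraction) return(record(k, wroi, froi))
    if (balance > best_balance) {
      best_balance <- balance
      best <- record(k, wroi, froi)
    }
  }
  if (!is.null(best)) {
    warning("no calibration slice reaches a ", signif(100 * min_class_fraction, 3),
            "% fat/water mix; using the most balanced slice (minority class ",
            signif(100 * best_balance, 3), "% of the ROI)")
    return(best)
  }
  stop("no slice containing both fat and water within the calibration ROI")
}

#' Signal-intensity correction factor
#'
#' `c = f_max / w_max`: the ratio of the maximum fat to maximum water signal
#' in the calibration ROI. Multiplying the water image by `c` normalises it
#' so that a voxel of pure fibroglandular tissue and a voxel of pure fat
#' reach the same intensity in their respective images, making the water
#' fraction a volume surrogate.
#'
#' @param roi an `ROIRecord`, or a list with `f_max` and `w_max`.
#' @return a `CorrectionFactor`: list with `c` and `source`.
#' @export
correction_factor <- function(roi) {
  if (is.null(roi$w_max) || is.null(roi$f_max)) stop("roi must carry f_max and w_max")
  if (roi$w_max <= 0) stop("w_max must be positive to form a correction factor")
  if (roi$f_max <= 0) stop("f_max must be positive to form a correction factor")
  structure(list(c = roi$f_max / roi$w_max, source = roi), class = "CorrectionFactor")
}

#' Corrected water-fraction map
#'
#' Per voxel inside the mask, `WF = c W / (c W + F)`; the fat image is left
#' uncorrected. Voxels where `c W + F = 0` are assigned `WF = 0` and
#' counted in `attr(, "degenerate_voxels")`.
#'
#' @param pair a `DixonPair`.
#' @param c a `CorrectionFactor`, or a positive scalar.
#' @param mask a `SegmentationMask` on the pair's grid.
#' @return a `WFVolume`: a `VolumeImage` whose data are the water fractions
#'   (zero outside the mask), with the mask and `c` attached.
#' @export
water_fraction_map <- function(pair, c, mask) {
  stopifnot(inherits(pair, "DixonPair"), inherits(mask, "SegmentationMask"))
  if (!identical(dim(pair$water$data), dim(mask$mask)))
    stop("pair and mask must share one grid")
  cval <- if (inherits(c, "CorrectionFactor")) c$c else as.numeric(c)
  if (!is.finite(cval) || cval <= 0) stop("correction factor must be a positive number")
  w <- pair$water$data[mask$mask]
  f <- pair$fat$data[mask$mask]
  denom <- cval * w + f
  wf <- numeric(length(w))
  ok <- denom > 0
  wf[ok] <- cval * w[ok] / denom[ok]
  out <- array(0, dim = dim(mask$mask))
  out[mask$mask] <- wf
  vol <- volume_image(out, pair$water$spacing_mm)
  vol$mask <- mask
  vol$c <- cval
  class(vol) <- append("WFVolume", class(vol))  # note: `c` is shadowed by the argument here
  attr(vol, "degenerate_voxels") <- sum(!ok)
  vol
}

#' FGT volume and percent FGT of one breast
#'
#' The fibroglandular tissue volume is the sum of voxel water fractions over
#' the mask times the voxel volume; the total breast volume is the mask
#' volume; %FGT is their ratio times 100.
#'
#' @param wf a `WFVolume` (or a `VolumeImage` of water fractions).
#' @param mask a `SegmentationMask` on the same grid (defaults to the mask
#'   attached to `wf`).
#' @param dataset label carried into the result.
#' @return an `FGTResult`: one-row data.frame with columns `dataset`,
#'   `laterality`, `fgt_cm3`, `total_cm3`, `pct_fgt`, `c`.
#' @export
fgt_summary <- function(wf, mask = NULL, dataset = NA_character_) {
  mask <- mask %||% wf$mask
  stopifnot(inherits(mask, "SegmentationMask"))
  if (!identical(dim(wf$data), dim(mask$mask)))
    stop("water-fraction map and mask must share one grid")
  if (!any(mask$mask)) stop("empty mask")
  vv <- voxel_volume_mm3(wf$spacing_mm)
  fgt <- sum(wf$data[mask$mask]) * vv / 1000
  tot <- sum(mask$mask) * vv / 1000
  data.frame(dataset = dataset, laterality = mask$laterality,
             fgt_cm3 = fgt, total_cm3 = tot, pct_fgt = 100 * fgt / tot,
             c = wf$c %||% NA_real_, stringsAsFactors = FALSE)
}

#' Sensitivity of %FGT to the correction factor
#'
#' Recomputes the water-fraction map and %FGT with the correction factor
#' deliberately over- and under-estimated by `delta_fraction` (default
#' 15%), reporting the signed %FGT changes.
#'
#' @param pair a `DixonPair`.
#' @param mask a `SegmentationMask`.
#' @param c a `CorrectionFactor` or positive scalar.
#' @param delta_fraction non-negative perturbation fraction.
#' @return list with `pct_fgt` (unperturbed), `pct_fgt_plus`,
#'   `pct_fgt_minus`, `delta_plus`, `delta_minus`.
#' @export
sensitivity <- function(pair, mask, c, delta_fraction = 0.15) {
  if (delta_fraction < 0) stop("delta_fraction must be >= 0")
  cval <- if (inherits(c, "CorrectionFactor")) c$c else as.numeric(c)
  pct <- function(cc) fgt_summary(water_fraction_map(pair, cc, mask), mask)$pct_fgt
  p0 <- pct(cval)
  pp <- pct(cval * (1 + delta_fraction))
  pm <- pct(cval * (1 - delta_fraction))
  list(pct_fgt = p0, pct_fgt_plus = pp, pct_fgt_minus = pm,
       delta_plus = pp - p0, delta_minus = pm - p0)
}

#' Quantify one breast from a Dixon pair
#'
#' Convenience wrapper running ROI selection, correction-factor calibration,
#' water-fraction mapping and FGT summary in sequence.
#'
#' @param pair a `DixonPair`.
#' @param mask a `SegmentationMask` for one breast.
#' @param dataset label carried into the result.
#' @param c optional fixed correction factor (skips calibration).
#' @param ... passed to [select_calibration_roi()].
#' @return an `FGTResult` row (see [fgt_summary()]).
#' @export
quantify_breast <- function(pair, mask, dataset = NA_character_, c = NULL, ...) {
  cf <- if (is.null(c)) correction_factor(select_calibration_roi(pair, mask, ...))
        else c
  fgt_summary(water_fraction_map(pair, cf, mask), mask, dataset = dataset)
}
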