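# Threshold-masked compartment intensities and the somatodendritic-to-
# axonal intensity ratio.

#' Set sub-threshold voxels to missing
#'
#' Mirrors the 32-bit "values below the threshold set to not-a-number"
#' masking step: voxels strictly below `t` become `NA` in the quantified
#' channel; voxels equal to or above `t` are unchanged, and all other
#' channels are left untouched.
#'
#' @param stack an [image_stack()]
#' @param t finite intensity threshold
#' @param channel channel to mask (0-based index or name; default channel 0,
#'   the mitochondrial marker)
#' @return The masked [image_stack()].
#' @export
threshold_to_missing <- function(stack, t, channel = 0L) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.finite(t)) stop("threshold must be finite")
  i <- resolve_channel(stack, channel)
  ch <- stack$voxels[, , , i]
  ch[ch < t] <- NA_real_
  stack$voxels[, , , i] <- ch
  stack
}

#' Mean intensity of non-missing voxels inside an ROI
#'
#' The ROI (a [poly_roi()] or [rect_roi()]) is defined in the xy plane and
#' applied as a prism across all z-slices. The mean is the summed intensity
#' of non-missing voxels divided by their count -- the "summed intensity
#' divided by the non-zero area" rule for thresholded images.
#'
#' @param stack an [image_stack()] (typically already thresholded)
#' @param roi a [poly_roi()] or [rect_roi()]
#' @param channel channel to quantify (0-based index or name)
#' @return A list with `mean` and `area` (non-missing voxel count).
#' @export
roi_mean_intensity <- function(stack, roi, channel = 0L) {
  stopifnot(inherits(stack, "image_stack"))
  ch <- stack_channel(stack, channel)
  d <- dim(ch)
  mask <- roi_mask(roi, d[1L], d[2L],
                   stack$voxel_size[c("y", "x")])
  if (!any(mask)) stop("ROI does not intersect the image")
  vals <- ch[rep(mask, times = d[3L])]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    stop("empty ROI after threshold: no non-missing voxels in ROI")
  list(mean = sum(vals) / length(vals), area = length(vals))
}

#' Somatodendritic-to-axonal mitochondrial intensity ratio
#'
#' Thresholds the mitochondrial channel, computes the mean supra-threshold
#' intensity in the calyx (somatodendritic) and dorsal/alpha-lobe (axonal)
#' ROIs, and returns their ratio together with both component means and
#' non-missing areas.
#'
#' @param stack an [image_stack()] (unthresholded; masking is applied here)
#' @param calyx_roi,lobe_roi compartment ROIs ([poly_roi()])
#' @param t intensity threshold (one value per experiment)
#' @param channel mitochondrial channel (0-based index or name)
#' @param fly_id,hemisphere,genotype,age identifiers carried into the result
#' @return A one-row data frame (fields of a compartment measurement).
#' @export
somatodendritic_axonal_ratio <- function(stack, calyx_roi, lobe_roi, t,
                                         channel = 0L, fly_id = NA_character_,
                                         hemisphere = NA_integer_,
                                         genotype = NA_character_,
                                         age = NA_character_) {
  masked <- threshold_to_missing(stack, t, channel)
  calyx <- tryCatch(roi_mean_intensity(masked, calyx_roi, channel),
                    error = function(e) stop("calyx ROI: ",
                                             conditionMessage(e)))
  lobe <- tryCatch(roi_mean_intensity(masked, lobe_roi, channel),
                   error = function(e) stop("lobe ROI: ",
                                            conditionMessage(e)))
  data.frame(fly_id = fly_id, hemisphere = hemisphere, genotype = genotype,
             age = age, calyx_mean = calyx$mean, lobe_mean = lobe$mean,
             ratio = calyx$mean / lobe$mean,
             nonmissing_area_calyx = calyx$area,
             nonmissing_area_lobe = lobe$area)
}
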