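# The fluorescence index: FI = MFI_n / MFI_b, the ratio of the mean FITC
# intensity over the nucleus region to the mean over the non-nucleus
# background. A ratio (not a difference) makes FI independent of camera
# exposure/gain before 8-bit quantisation.

#' Mean intensity over a region
#'
#' @param image A [channel_image()].
#' @param region Logical matrix with the image's dimensions; at least one
#'   TRUE pixel.
#' @return Arithmetic mean of the intensities at TRUE pixels, in full
#'   floating precision.
#' @export
mean_intensity <- function(image, region) {
  if (!inherits(image, "channel_image")) ana_format_error("image must be a channel_image")
  if (!is.logical(region) || !identical(dim(region), dim(image$intensities))) {
    ana_format_error("region must be a logical matrix matching the image dimensions")
  }
  if (!any(region)) ana_analysis_error("empty region")
  mean(image$intensities[region])
}

#' Compute the fluorescence index of a well
#'
#' Superimposes the DAPI-derived nucleus mask on the FITC channel:
#' `mfi_nucleus` is the mean FITC intensity over the mask, `mfi_background`
#' the mean over its inversion, and `fi` their ratio. If more than 1\% of
#' nuclear FITC pixels sit at 255 the well is flagged `saturated`
#' (saturation compresses the ratio downwards); if the background signal is
#' exactly zero the ratio is undefined and the well is unevaluable.
#' Classification is left unset — see [classify()].
#'
#' @param capture A [paired_capture()].
#' @param seg The [segment_nuclei()] result for `capture$dapi`.
#' @return An object of class `fi_result` with `well_id`, `mfi_nucleus`,
#'   `mfi_background`, `fi`, `classification` (`NA` until classified, or
#'   `"unevaluable"`), `cutoff_used`, `saturated`, `reason`.
#' @export
compute_fi <- function(capture, seg) {
  if (!inherits(capture, "paired_capture")) ana_format_error("capture must be a paired_capture")
  if (!inherits(seg, "segmentation")) ana_format_error("seg must be a segmentation")
  if (!identical(dim(seg$mask), dim(capture$dapi$intensities))) {
    ana_format_error("segmentation does not match the capture dimensions")
  }
  bg_region <- invert_mask(seg)
  if (!any(seg$mask) || !any(bg_region)) {
    ana_analysis_error("mask and its inversion must both be nonempty")
  }
  mfi_n <- mean_intensity(capture$fitc, seg$mask)
  mfi_b <- mean_intensity(capture$fitc, bg_region)
  saturated <- mean(capture$fitc$intensities[seg$mask] == 255L) > 0.01
  if (mfi_b == 0) {
    return(structure(
      list(well_id = capture$well_id, mfi_nucleus = mfi_n, mfi_background = 0,
           fi = NA_real_, classification = "unevaluable", cutoff_used = NA_real_,
           saturated = saturated, reason = "zero background signal"),
      class = "fi_result"))
  }
  structure(
    list(well_id = capture$well_id, mfi_nucleus = mfi_n, mfi_background = mfi_b,
         fi = mfi_n / mfi_b, classification = NA_character_,
         cutoff_used = NA_real_, saturated = saturated, reason = NA_character_),
    class = "fi_result")
}

#' Cutoff configuration
#'
#' @param cutoff Positive FI threshold; wells with FI at or above it are
#'   called positive. Default 1.246, the calibration shipped with the
#'   package; recalibrate with [cmd_calibrate()] for a new imaging setup.
#' @return An object of class `cutoff_config`.
#' @export
cutoff_config <- function(cutoff = 1.246) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff) || cutoff <= 0) {
    ana_domain_error("cutoff must be a positive number")
  }
  structure(list(cutoff = cutoff), class = "cutoff_config")
}

#' Classify a well against an FI cutoff
#'
#' A well is positive when `fi >= cutoff` — a boundary FI counts as
#' positive, favouring sensitivity in a screening setting. Unevaluable
#' wells stay unevaluable.
#'
#' @param result An `fi_result` from [compute_fi()].
#' @param config A [cutoff_config()] (or a bare numeric cutoff).
#' @return The `fi_result` with `classification` and `cutoff_used` set.
#' @export
classify <- function(result, config = cutoff_config()) {
  if (!inherits(result, "fi_result")) ana_format_error("result must be an fi_result")
  if (is.numeric(config)) config <- cutoff_config(config)
  if (!inherits(config, "cutoff_config")) ana_format_error("config must be a cutoff_config")
  if (identical(result$classification, "unevaluable")) return(result)
  if (!is.finite(result$fi)) ana_analysis_error("fi has not been computed")
  result$classification <- if (result$fi >= config$cutoff) "positive" else "negative"
  result$cutoff_used <- config$cutoff
  result
}
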