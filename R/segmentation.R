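# Nucleus segmentation from the DAPI channel.
#
# The background intensity of the DAPI image is the first (lowest-intensity)
# peak of its histogram; pixels at or above twice that intensity form the
# nucleus region. The region is pooled — no per-cell instance separation —
# because the fluorescence index averages over the whole nuclear area.

# Reference frame for scaling the small-object cleanup: nuclei imaged at
# 20x on a 1392 x 1040 sensor.
.reference_area <- 1392 * 1040

#' Intensity histogram of a channel
#'
#' @param image A [channel_image()].
#' @return Integer vector of length 256; entry `v + 1` counts the pixels
#'   with intensity `v`. Counts always sum to the pixel count of the image.
#' @export
compute_histogram <- function(image) {
  if (!inherits(image, "channel_image")) ana_format_error("image must be a channel_image")
  tabulate(as.integer(image$intensities) + 1L, nbins = 256L)
}

#' Locate the background peak of a DAPI histogram
#'
#' The background of a DAPI capture is dark and dominates the frame, so its
#' histogram shows a large low-intensity mode with the (smaller) nucleus
#' mode further right. The background intensity is the first peak: counts
#' are smoothed with a centred moving average (`window` bins, partial at the
#' edges), runs of equal smoothed values are collapsed, and the
#' lowest-intensity run that (a) exceeds both neighbouring runs and (b)
#' holds at least `min_fraction` of all pixels is taken. The reported
#' intensity is the modal raw bin within that run (plus a 2-bin margin),
#' lowest bin on ties, so a single-bin spike is reported at its exact
#' location despite the smoothing.
#'
#' @param hist Integer vector of length 256 from [compute_histogram()].
#' @param min_fraction Minimum smoothed count at the peak, as a fraction of
#'   total pixels (default 0.01); rejects hot-pixel spikes.
#' @param window Moving-average width in bins (default 5).
#' @return The background intensity (integer in 0..255).
#' @export
find_background_peak <- function(hist, min_fraction = 0.01, window = 5) {
  if (length(hist) != 256L || any(hist < 0)) {
    ana_format_error("hist must be 256 nonnegative counts")
  }
  total <- sum(hist)
  if (total <= 0) ana_domain_error("empty histogram")
  half <- (window - 1L) %/% 2L
  smoothed <- vapply(seq_along(hist), function(i) {
    lo <- max(1L, i - half); hi <- min(256L, i + half)
    mean(hist[lo:hi])
  }, numeric(1))

  r <- rle(smoothed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  floor_count <- min_fraction * total
  n_runs <- length(r$values)
  if (n_runs == 1L) ana_analysis_error("no background peak (flat histogram)")
  for (k in seq_len(n_runs)) {
    left_ok <- k == 1L || r$values[k - 1L] < r$values[k]
    right_ok <- k == n_runs || r$values[k + 1L] < r$values[k]
    if (left_ok && right_ok && r$values[k] >= floor_count) {
      lo <- max(1L, starts[k] - 2L)
      hi <- min(256L, ends[k] + 2L)
      seg <- hist[lo:hi]
      return(as.integer(lo + which.max(seg) - 1L) - 1L)  # 0-based intensity
    }
  }
  ana_analysis_error("no background peak")
}

#' Segmentation threshold from a background intensity
#'
#' The nucleus threshold is twice the background intensity, clamped to
#' \[1, 255\]: the floor keeps a zero background from selecting every pixel
#' and the ceiling respects the 8-bit range.
#'
#' @param background Background intensity in 0..255.
#' @return Threshold intensity (integer in 1..255).
#' @export
compute_threshold <- function(background) {
  if (background < 0 || background > 255) {
    ana_domain_error("background intensity must be in [0, 255]")
  }
  as.integer(min(max(2 * background, 1), 255))
}

# 8-connectivity labelling: EBImage::bwlabel is edge-connected, so labels
# that only touch diagonally are merged with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  idx <- which(a > 0 & b > 0 & a != b)
  for (i in idx) union2(a[i], b[i])
  a <- lab[-nr, -1]; b <- lab[-1, -nc]
  idx <- which(a > 0 & b > 0 & a != b)
  for (i in idx) union2(a[i], b[i])
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment the nucleus region of a DAPI channel
#'
#' Pixels at or above twice the histogram background peak form the nucleus
#' mask; connected components (8-connectivity) smaller than
#' `min_object_size` pixels — a size stated for a 1392 x 1040 frame and
#' scaled proportionally to image area for other sizes — are then removed
#' as noise speckle. Set `min_object_size = 0` to keep the raw threshold
#' mask.
#'
#' @param dapi A DAPI [channel_image()].
#' @param min_object_size Minimum component area in pixels on the reference
#'   1392 x 1040 frame (default 50; 0 disables cleanup).
#' @param peak_min_fraction,smoothing_window Passed to
#'   [find_background_peak()].
#' @return An object of class `segmentation`: `mask` (logical matrix, TRUE =
#'   nucleus), `background_intensity`, `threshold`, `nucleus_pixel_count`,
#'   `nucleus_fraction`.
#' @export
segment_nuclei <- function(dapi, min_object_size = 50, peak_min_fraction = 0.01,
                           smoothing_window = 5) {
  if (!inherits(dapi, "channel_image")) ana_format_error("dapi must be a channel_image")
  hist <- compute_histogram(dapi)
  background <- find_background_peak(hist, min_fraction = peak_min_fraction,
                                     window = smoothing_window)
  threshold <- compute_threshold(background)
  mask <- dapi$intensities >= threshold
  n_total <- length(mask)

  if (min_object_size > 0 && any(mask)) {
    eff <- round(min_object_size * n_total / .reference_area)
    if (eff >= 2) {
      lab <- label_components8(mask)
      sizes <- tabulate(lab[lab > 0])
      keep <- which(sizes >= eff)
      mask <- matrix(lab %in% keep, nrow = nrow(mask))
    }
  }

  n_nuc <- sum(mask)
  if (n_nuc == 0L) ana_analysis_error("no nuclei detected")
  if (n_nuc > 0.9 * n_total) ana_analysis_error("background/nucleus inversion suspected")
  structure(
    list(mask = mask,
         background_intensity = background,
         threshold = threshold,
         nucleus_pixel_count = n_nuc,
         nucleus_fraction = n_nuc / n_total),
    class = "segmentation"
  )
}

#' Complement of the nucleus mask
#'
#' Inverting the nucleus selection yields the non-nucleus background region
#' over which the background fluorescence is measured. The mask and its
#' inversion partition the frame exactly.
#'
#' @param result A `segmentation` object from [segment_nuclei()], or a
#'   logical mask matrix.
#' @return Logical matrix, TRUE on non-nucleus pixels.
#' @export
invert_mask <- function(result) {
  mask <- if (inherits(result, "segmentation")) result$mask else result
  if (!is.logical(mask) || !is.matrix(mask)) {
    ana_format_error("result must be a segmentation or a logical mask")
  }
  !mask
}
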