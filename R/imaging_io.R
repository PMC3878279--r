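# Reading microscope captures and cohort tables, writing per-well results.
#
# All pixel intensities are carried as integer matrices on the 8-bit scale
# 0..255, row-major with origin at the top-left corner (never exposed in
# outputs). Captures are 24-bit RGB TIFF: the DAPI signal lives in the blue
# plane, the FITC signal in the green plane.

#' RGB image container
#'
#' Three 8-bit intensity planes of identical dimensions, as read from a
#' 24-bit colour TIFF capture.
#'
#' @param red,green,blue Integer matrices with values in 0..255 and
#'   identical dimensions.
#' @return An object of class `rgb_image` with elements `red`, `green`,
#'   `blue`, `width`, `height`.
#' @export
rgb_image <- function(red, green, blue) {
  planes <- list(red = red, green = green, blue = blue)
  d <- dim(red)
  for (nm in names(planes)) {
    p <- planes[[nm]]
    if (!is.matrix(p) || !identical(dim(p), d)) {
      ana_format_error("RGB planes must be matrices of identical dimensions")
    }
    if (anyNA(p) || min(p) < 0 || max(p) > 255) {
      ana_format_error(sprintf("%s plane has intensities outside [0, 255]", nm))
    }
  }
  if (d[1] < 1L || d[2] < 1L) ana_format_error("image dimensions must be positive")
  structure(
    list(red = red, green = green, blue = blue,
         width = d[2], height = d[1]),
    class = "rgb_image"
  )
}

#' Single-channel image
#'
#' One 8-bit intensity plane extracted from a capture, tagged with the stain
#' it carries (DAPI marks nuclei, FITC carries the antibody signal).
#'
#' @param intensities Integer matrix with values in 0..255.
#' @param stain `"DAPI"` or `"FITC"`.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(intensities, stain = c("DAPI", "FITC")) {
  stain <- match.arg(stain)
  if (!is.matrix(intensities)) ana_format_error("intensities must be a matrix")
  if (anyNA(intensities) || min(intensities) < 0 || max(intensities) > 255) {
    ana_format_error("channel intensities outside [0, 255]")
  }
  structure(
    list(intensities = intensities, stain = stain,
         width = ncol(intensities), height = nrow(intensities)),
    class = "channel_image"
  )
}

#' Paired DAPI/FITC capture of one microscope field
#'
#' The two excitation captures of the same central field of one well. Both
#' channels must have identical dimensions; the pair is assumed pre-aligned
#' (no registration correction is applied).
#'
#' @param well_id Well identifier (opaque string).
#' @param dapi,fitc `channel_image` objects with stains `"DAPI"` and
#'   `"FITC"` respectively.
#' @return An object of class `paired_capture`.
#' @export
paired_capture <- function(well_id, dapi, fitc) {
  if (!inherits(dapi, "channel_image") || !inherits(fitc, "channel_image")) {
    ana_format_error("dapi and fitc must be channel_image objects")
  }
  if (dapi$stain != "DAPI" || fitc$stain != "FITC") {
    ana_format_error("channel stains must be DAPI and FITC respectively")
  }
  if (!identical(dim(dapi$intensities), dim(fitc$intensities))) {
    ana_format_error("DAPI and FITC channels must share dimensions (same field)")
  }
  structure(list(well_id = as.character(well_id), dapi = dapi, fitc = fitc),
            class = "paired_capture")
}

#' Read a colour TIFF capture
#'
#' Reads a 24-bit RGB TIFF (uncompressed, LZW or deflate). 16-bit inputs are
#' rescaled to the 8-bit range with a warning; an alpha plane is dropped
#' with a warning. Grayscale, palette and CMYK images are rejected because
#' the analysis requires a channel split.
#'
#' @param path Path to a TIFF file.
#' @return An [rgb_image()].
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) ana_io_error(sprintf("cannot read image file '%s'", path))
  raw <- tryCatch(
    tiff::readTIFF(path, info = TRUE),
    error = function(e) ana_io_error(sprintf("cannot decode '%s': %s", path, conditionMessage(e)))
  )
  cs <- attr(raw, "color.space")
  if (!is.null(cs) && !cs %in% c("RGB", "sRGB")) {
    ana_format_error(sprintf("'%s' is %s; only RGB captures are supported", path, cs))
  }
  if (is.matrix(raw) || (length(dim(raw)) == 3L && dim(raw)[3] < 3L)) {
    ana_format_error(sprintf("'%s' is grayscale; cannot split RGB channels", path))
  }
  nch <- dim(raw)[3]
  if (nch > 3L) {
    warning(sprintf("'%s': dropping alpha channel", path), call. = FALSE)
    raw <- raw[, , 1:3, drop = FALSE]
  }
  bits <- attr(raw, "bits.per.sample")
  if (!is.null(bits) && any(bits > 8L)) {
    warning(sprintf("'%s': %d-bit input rescaled to 8-bit", path, max(bits)), call. = FALSE)
  }
  # readTIFF normalises samples to [0, 1] regardless of bit depth, so one
  # rescale recovers (8-bit) or produces (16-bit) the 8-bit intensities.
  to8 <- function(p) {
    m <- round(p * 255)
    storage.mode(m) <- "integer"
    m
  }
  rgb_image(red = to8(raw[, , 1]), green = to8(raw[, , 2]), blue = to8(raw[, , 3]))
}

#' Extract the analysis channel for a stain
#'
#' The DAPI capture is analysed through its blue plane, the FITC capture
#' through its green plane; the other planes are discarded. The extraction
#' is a pure projection — intensities are never altered.
#'
#' @param image An [rgb_image()].
#' @param stain `"DAPI"` (blue plane) or `"FITC"` (green plane).
#' @return A [channel_image()].
#' @export
extract_channel <- function(image, stain = c("DAPI", "FITC")) {
  stain <- match.arg(stain)
  if (!inherits(image, "rgb_image")) ana_format_error("image must be an rgb_image")
  plane <- if (stain == "DAPI") image$blue else image$green
  channel_image(plane, stain)
}

# Accepted reciprocal-dilution tokens; ">800" sorts above 800.
.titer_tokens <- c("100", "200", "400", "800", ">800")

#' Read a cohort table
#'
#' A cohort table is a UTF-8 CSV with a header naming at least `well_id`,
#' `dapi_path` and `fitc_path`. Optional columns: `visual_label`
#' (`negative`/`positive`), `visual_titer` (reciprocal dilution in
#' 100, 200, 400, 800 or `>800`) and `visual_pattern` (free text). A titer
#' may only be present on wells labelled positive, and well IDs must be
#' unique.
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `cohort_table`, one row per well, with
#'   character columns `well_id`, `dapi_path`, `fitc_path`, `visual_label`,
#'   `visual_titer`, `visual_pattern` (`NA` where absent).
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) ana_io_error(sprintf("cannot read cohort table '%s'", path))
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
             fileEncoding = "UTF-8"),
    error = function(e) ana_io_error(sprintf("cannot parse '%s': %s", path, conditionMessage(e)))
  )
  mandatory <- c("well_id", "dapi_path", "fitc_path")
  missing <- setdiff(mandatory, names(df))
  if (length(missing)) {
    ana_schema_error(sprintf("cohort table is missing mandatory column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  for (col in c("visual_label", "visual_titer", "visual_pattern")) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_character_, nrow(df))
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  }
  if (anyDuplicated(df$well_id)) {
    dup <- unique(df$well_id[duplicated(df$well_id)])
    ana_validation_error(sprintf("duplicate well_id(s): %s", paste(dup, collapse = ", ")))
  }
  lab <- df$visual_label
  if (any(!is.na(lab) & !lab %in% c("negative", "positive"))) {
    ana_validation_error("visual_label must be 'negative' or 'positive'")
  }
  tit <- df$visual_titer
  bad_tok <- !is.na(tit) & !tit %in% .titer_tokens
  if (any(bad_tok)) {
    ana_validation_error(sprintf("invalid visual_titer value(s): %s",
                                 paste(unique(tit[bad_tok]), collapse = ", ")))
  }
  # a titer is the reciprocal of the highest still-staining dilution and only
  # exists for wells read as positive
  orphan <- !is.na(tit) & (is.na(lab) | lab != "positive")
  if (any(orphan)) {
    ana_validation_error(sprintf(
      "visual_titer present without a positive visual_label for well(s): %s",
      paste(df$well_id[orphan], collapse = ", ")))
  }
  df <- df[, c(mandatory, "visual_label", "visual_titer", "visual_pattern")]
  class(df) <- c("cohort_table", "data.frame")
  df
}

# numeric rank of a titer token, for ordering/correlation (">800" -> 1600)
titer_value <- function(titer) {
  v <- ifelse(titer == ">800", 1600, suppressWarnings(as.numeric(titer)))
  v
}

#' Write per-well screening results
#'
#' Writes one CSV row per well with the fixed columns `well_id`,
#' `mfi_nucleus`, `mfi_background`, `fi`, `classification`,
#' `background_intensity`, `threshold`, plus `saturated` (flag raised when
#' more than 1\% of nuclear FITC pixels sit at 255) and `reason` (why a
#' well was unevaluable). Numeric fields are written at full precision.
#'
#' @param results List of per-well result records (as produced by
#'   [screen_well()]), or an empty list for a header-only file.
#' @param path Output CSV path.
#' @return The output path, invisibly.
#' @export
write_results <- function(results, path) {
  cols <- c("well_id", "mfi_nucleus", "mfi_background", "fi", "classification",
            "background_intensity", "threshold", "saturated", "reason")
  if (length(results) == 0L) {
    df <- data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(df) <- cols
  } else {
    rows <- lapply(results, function(r) {
      num <- function(x) if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x)
      chr <- function(x) if (is.null(x) || length(x) == 0L) NA_character_ else as.character(x)
      data.frame(
        well_id = chr(r$well_id),
        mfi_nucleus = num(r$mfi_nucleus),
        mfi_background = num(r$mfi_background),
        fi = num(r$fi),
        classification = chr(r$classification),
        background_intensity = num(r$background_intensity),
        threshold = num(r$threshold),
        saturated = isTRUE(r$saturated),
        reason = chr(r$reason),
        stringsAsFactors = FALSE
      )
    })
    df <- do.call(rbind, rows)
  }
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) ana_io_error(sprintf("cannot write results to '%s'", path))
  invisible(path)
}
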