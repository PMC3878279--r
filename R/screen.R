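# Batch workflows: screen a cohort, calibrate the cutoff, simulate a
# cohort to disk. Per-well analysis failures never abort a batch — the well
# is reported unevaluable with a reason; hard errors are reserved for
# schema and I/O problems.

#' Run configuration for batch screening
#'
#' @param cutoff FI threshold for a positive call (default 1.246).
#' @param min_object_size Segmentation cleanup size in pixels on the
#'   reference 1392 x 1040 frame (default 50; 0 disables cleanup).
#' @param peak_min_fraction Minimum histogram-peak mass as a fraction of
#'   total pixels (default 0.01).
#' @param smoothing_window Histogram moving-average width in bins
#'   (default 5).
#' @param save_masks Write each well's nucleus mask as an 8-bit TIFF next
#'   to its DAPI input (default `FALSE`).
#' @param log_level `"info"` (progress messages on stderr) or `"quiet"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cutoff = 1.246, min_object_size = 50,
                       peak_min_fraction = 0.01, smoothing_window = 5,
                       save_masks = FALSE, log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (cutoff <= 0 || min_object_size < 0 || peak_min_fraction <= 0 ||
      smoothing_window <= 0) {
    ana_domain_error("run_config numeric fields must be positive")
  }
  structure(
    list(cutoff = cutoff, min_object_size = min_object_size,
         peak_min_fraction = peak_min_fraction,
         smoothing_window = smoothing_window,
         save_masks = isTRUE(save_masks), log_level = log_level),
    class = "run_config")
}

log_info <- function(config, fmt, ...) {
  if (config$log_level == "info") message(sprintf(fmt, ...))
}

unevaluable_record <- function(well_id, reason) {
  list(well_id = well_id, mfi_nucleus = NA_real_, mfi_background = NA_real_,
       fi = NA_real_, classification = "unevaluable",
       background_intensity = NA_real_, threshold = NA_real_,
       saturated = FALSE, reason = reason)
}

#' Screen one paired capture
#'
#' Runs segmentation, FI computation and classification on one well.
#' Analysis failures (no nuclei, suspected inversion, zero background
#' signal, no histogram peak) yield an unevaluable record with the reason,
#' never an error.
#'
#' @param capture A [paired_capture()].
#' @param config A [run_config()].
#' @return A per-well result record (list) with fields `well_id`,
#'   `mfi_nucleus`, `mfi_background`, `fi`, `classification`,
#'   `background_intensity`, `threshold`, `saturated`, `reason`, plus the
#'   `segmentation` object (element `seg`, `NULL` when unevaluable).
#' @export
screen_well <- function(capture, config = run_config()) {
  tryCatch({
    seg <- segment_nuclei(capture$dapi,
                          min_object_size = config$min_object_size,
                          peak_min_fraction = config$peak_min_fraction,
                          smoothing_window = config$smoothing_window)
    fi <- classify(compute_fi(capture, seg), config$cutoff)
    list(well_id = fi$well_id, mfi_nucleus = fi$mfi_nucleus,
         mfi_background = fi$mfi_background, fi = fi$fi,
         classification = fi$classification,
         background_intensity = seg$background_intensity,
         threshold = seg$threshold, saturated = fi$saturated,
         reason = fi$reason, seg = seg)
  }, ana_analysis_error = function(e) {
    unevaluable_record(capture$well_id, conditionMessage(e))
  })
}

# Load one well's channels from disk; I/O and format problems become an
# unevaluable record.
load_capture <- function(row) {
  tryCatch({
    dapi <- extract_channel(read_rgb_image(row$dapi_path), "DAPI")
    fitc <- extract_channel(read_rgb_image(row$fitc_path), "FITC")
    paired_capture(row$well_id, dapi, fitc)
  }, anascreen_error = function(e) {
    structure(list(reason = conditionMessage(e)), class = "capture_failure")
  })
}

mask_output_path <- function(dapi_path) {
  paste0(sub("\\.[^.]*$", "", dapi_path), "_mask.tif")
}

#' Screen a cohort table
#'
#' Reads the cohort table, computes FI and a positive/negative call for
#' every well, and writes the per-well results CSV. Wells whose images are
#' missing or whose analysis fails are reported unevaluable and the batch
#' continues.
#'
#' @param table_path Cohort CSV (see [read_cohort_table()]).
#' @param out_path Output results CSV (see [write_results()]).
#' @param config A [run_config()].
#' @return Invisibly, a list with `results` (per-well records) and
#'   `summary` (`n_wells`, `n_positive`, `n_negative`, `n_unevaluable`).
#' @export
cmd_screen <- function(table_path, out_path, config = run_config()) {
  tbl <- read_cohort_table(table_path)
  log_info(config, "screening %d wells (cutoff %.4g)", nrow(tbl), config$cutoff)
  results <- vector("list", nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    row <- tbl[i, ]
    capture <- load_capture(row)
    if (inherits(capture, "capture_failure")) {
      results[[i]] <- unevaluable_record(row$well_id, capture$reason)
      next
    }
    rec <- screen_well(capture, config)
    if (config$save_masks && !is.null(rec$seg)) {
      tiff::writeTIFF(rec$seg$mask * 1, mask_output_path(row$dapi_path),
                      bits.per.sample = 8L)
    }
    rec$seg <- NULL
    results[[i]] <- rec
  }
  write_results(results, out_path)
  cls <- vapply(results, function(r) r$classification, character(1))
  summary <- list(n_wells = length(results),
                  n_positive = sum(cls == "positive"),
                  n_negative = sum(cls == "negative"),
                  n_unevaluable = sum(cls == "unevaluable"))
  log_info(config, "%d wells: %d positive, %d negative, %d unevaluable",
           summary$n_wells, summary$n_positive, summary$n_negative,
           summary$n_unevaluable)
  invisible(list(results = results, summary = summary))
}

#' Calibrate the FI cutoff on a visually labelled cohort
#'
#' Computes FI for every labelled, evaluable well, determines the cutoff
#' from the accuracy curve (or Youden's J), and reports AUC, the screening
#' metrics and Cohen's kappa of the algorithm against the visual read at
#' that cutoff. The report is written as JSON; the ROC and accuracy curves
#' can additionally be dumped as CSV.
#'
#' @param table_path Cohort CSV with `visual_label` filled in for at least
#'   one positive and one negative well.
#' @param out_path Output JSON report path.
#' @param config A [run_config()].
#' @param curves_out Optional CSV path for the threshold sweep
#'   (`threshold`, `sensitivity`, `specificity`, `accuracy`).
#' @param criterion Cutoff selection rule, `"max-accuracy"` (default) or
#'   `"youden"`.
#' @return Invisibly, the report list (also written to `out_path`).
#' @export
cmd_calibrate <- function(table_path, out_path, config = run_config(),
                          curves_out = NULL,
                          criterion = c("max-accuracy", "youden")) {
  criterion <- match.arg(criterion)
  tbl <- read_cohort_table(table_path)
  labelled <- !is.na(tbl$visual_label)
  if (!any(labelled)) ana_domain_error("calibration requires visual labels")
  tbl <- tbl[labelled, , drop = FALSE]
  log_info(config, "calibrating on %d labelled wells", nrow(tbl))

  fis <- rep(NA_real_, nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    capture <- load_capture(tbl[i, ])
    if (inherits(capture, "capture_failure")) next
    rec <- screen_well(capture, config)
    if (rec$classification != "unevaluable") fis[i] <- rec$fi
  }
  ok <- is.finite(fis)
  scores <- fis[ok]
  labels <- tbl$visual_label[ok] == "positive"
  if (!any(labels) || all(labels)) {
    ana_domain_error("calibration requires evaluable wells in both classes")
  }

  cut <- determine_cutoff(scores, labels, criterion = criterion)
  roc <- roc_curve(scores, labels)
  pred <- scores >= cut$cutoff
  ct <- confusion_table(tp = sum(pred & labels), fn = sum(!pred & labels),
                        fp = sum(pred & !labels), tn = sum(!pred & !labels))
  metrics <- screening_metrics(ct)
  kappa <- cohen_kappa(ct)

  report <- list(
    cutoff = cut$cutoff, criterion = cut$criterion, auc = roc$auc,
    metrics = list(sensitivity = metrics$sensitivity,
                   specificity = metrics$specificity,
                   ppv = metrics$ppv, npv = metrics$npv,
                   accuracy = metrics$accuracy),
    kappa = kappa,
    kappa_interpretation = kappa_interpretation(kappa),
    n_pos = sum(labels), n_neg = sum(!labels),
    n_unevaluable = sum(!ok),
    config = config[c("cutoff", "min_object_size", "peak_min_fraction",
                      "smoothing_window")])
  jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(curves_out)) {
    acc <- accuracy_curve(scores, labels)
    curves <- data.frame(threshold = roc$points$threshold,
                         sensitivity = roc$points$sensitivity,
                         specificity = 1 - roc$points$fpr,
                         accuracy = acc$accuracy)
    write.csv(curves, curves_out, row.names = FALSE)
  }
  log_info(config, "cutoff %.4g (AUC %.3f, kappa %.3f)", cut$cutoff, roc$auc, kappa)
  invisible(report)
}

#' Simulate a cohort to disk
#'
#' Generates a synthetic cohort with [generate_cohort()] and writes the
#' TIFF pairs, a manifest CSV readable by [read_cohort_table()] and a
#' ground-truth JSON (per-well expected FI, stratum and generation
#' parameters).
#'
#' @param out_dir Output directory (created if needed).
#' @param n_negative,n_weak,n_positive Stratum sizes.
#' @param seed Integer RNG seed.
#' @param width,height Frame size per capture.
#' @param ... Further generator arguments (see [generate_cohort()]).
#' @return Invisibly, the manifest CSV path.
#' @export
cmd_simulate <- function(out_dir, n_negative, n_weak, n_positive, seed = 1L,
                         width = 348L, height = 260L, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(n_negative, n_weak, n_positive, seed = seed,
                            width = width, height = height, ...)
  tbl <- cohort$table
  dapi_paths <- file.path(out_dir, paste0(tbl$well_id, "_dapi.tif"))
  fitc_paths <- file.path(out_dir, paste0(tbl$well_id, "_fitc.tif"))
  for (i in seq_along(cohort$wells)) {
    write_capture(cohort$wells[[i]]$capture, dapi_paths[i], fitc_paths[i])
  }
  manifest <- data.frame(
    well_id = tbl$well_id, dapi_path = dapi_paths, fitc_path = fitc_paths,
    visual_label = tbl$visual_label, visual_titer = tbl$visual_titer,
    visual_pattern = tbl$visual_pattern, stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE, na = "")
  truth <- list(
    seed = seed, width = width, height = height,
    wells = data.frame(well_id = tbl$well_id, stratum = tbl$stratum,
                       expected_fi = tbl$expected_fi,
                       stringsAsFactors = FALSE))
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest_path)
}
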