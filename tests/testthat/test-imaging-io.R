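# Reading captures, channel extraction and cohort/result tables.

test_that("an RGB TIFF is read back pixel for pixel", {
  red <- matrix(c(10, 0, 0, 0), 2, 2)
  green <- matrix(c(20, 0, 0, 0), 2, 2)
  blue <- matrix(c(30, 0, 0, 0), 2, 2)
  path <- make_rgb_tiff(withr::local_tempfile(fileext = ".tif"), red, green, blue)
  img <- read_rgb_image(path)
  expect_identical(img$red[1, 1], 10L)
  expect_identical(img$green[1, 1], 20L)
  expect_identical(img$blue[1, 1], 30L)
  expect_equal(img$width, 2)
  expect_equal(img$height, 2)
})

test_that("an all-black frame reads as zeros with its stated dimensions", {
  z <- matrix(0, 13, 29)
  path <- make_rgb_tiff(withr::local_tempfile(fileext = ".tif"), z, z, z)
  img <- read_rgb_image(path)
  expect_true(all(img$red == 0L) && all(img$green == 0L) && all(img$blue == 0L))
  expect_equal(c(img$height, img$width), c(13, 29))
})

test_that("simulator captures survive a disk round trip bit-exactly", {
  g <- generate_capture(sim_config(seed = 21, width = 120, height = 90, n_nuclei = 6))
  dp <- withr::local_tempfile(fileext = ".tif")
  fp <- withr::local_tempfile(fileext = ".tif")
  write_capture(g$capture, dp, fp)
  dapi <- extract_channel(read_rgb_image(dp), "DAPI")
  fitc <- extract_channel(read_rgb_image(fp), "FITC")
  expect_identical(dapi$intensities, g$capture$dapi$intensities)
  expect_identical(fitc$intensities, g$capture$fitc$intensities)
})

test_that("unreadable and grayscale inputs are rejected with typed errors", {
  expect_error(read_rgb_image(file.path(tempdir(), "nope.tif")),
               class = "ana_io_error")
  gpath <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 4, 4), gpath, bits.per.sample = 8L)
  expect_error(read_rgb_image(gpath), class = "ana_format_error")
})

test_that("16-bit input is rescaled to 8-bit with a warning", {
  arr <- array(0, dim = c(3, 3, 3))
  arr[, , 1] <- 1  # full-scale red
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(arr, path, bits.per.sample = 16L)
  expect_warning(img <- read_rgb_image(path), "rescaled")
  expect_identical(img$red[1, 1], 255L)
})

test_that("channel extraction keeps blue for DAPI and green for FITC, unaltered", {
  img <- rgb_image(red = matrix(7L, 2, 2), green = matrix(99L, 2, 2),
                   blue = matrix(42L, 2, 2))
  expect_identical(extract_channel(img, "DAPI")$intensities, matrix(42L, 2, 2))
  expect_identical(extract_channel(img, "FITC")$intensities, matrix(99L, 2, 2))
  z <- rgb_image(matrix(0L, 2, 2), matrix(0L, 2, 2), matrix(0L, 2, 2))
  expect_true(all(extract_channel(z, "FITC")$intensities == 0L))
  # projection: re-extracting never alters intensities
  g <- generate_capture(sim_config(seed = 4, width = 120, height = 90, n_nuclei = 6))
  dp <- withr::local_tempfile(fileext = ".tif")
  fp <- withr::local_tempfile(fileext = ".tif")
  write_capture(g$capture, dp, fp)
  rgb <- read_rgb_image(dp)
  once <- extract_channel(rgb, "DAPI")
  expect_identical(once$intensities, rgb$blue)
})

test_that("cohort tables parse, validate and enforce the titer invariant", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "well_id,dapi_path,fitc_path,visual_label,visual_titer",
    "A,da.tif,fa.tif,positive,100",
    "B,db.tif,fb.tif,negative,",
    "C,dc.tif,fc.tif,,"), path)
  tbl <- read_cohort_table(path)
  expect_equal(tbl$well_id, c("A", "B", "C"))
  expect_equal(tbl$visual_titer, c("100", NA, NA))
  expect_true(is.na(tbl$visual_label[3]))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well_id,dapi_path", "A,x.tif"), bad)
  expect_error(read_cohort_table(bad), "fitc_path", class = "ana_schema_error")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well_id,dapi_path,fitc_path", "A,x,y", "A,z,w"), dup)
  expect_error(read_cohort_table(dup), class = "ana_validation_error")

  orphan <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well_id,dapi_path,fitc_path,visual_label,visual_titer",
               "A,x,y,,100"), orphan)
  expect_error(read_cohort_table(orphan), class = "ana_validation_error")
})

test_that("results files round-trip the computed values", {
  # header-only for an empty batch
  p0 <- withr::local_tempfile(fileext = ".csv")
  write_results(list(), p0)
  df0 <- read.csv(p0)
  expect_equal(nrow(df0), 0)
  expect_true(all(c("well_id", "mfi_nucleus", "mfi_background", "fi",
                    "classification", "background_intensity", "threshold")
                  %in% names(df0)))

  # ten simulated wells re-parse to the computed FI values
  co <- generate_cohort(5, 0, 5, seed = 9, width = 120, height = 90, n_nuclei = 6)
  recs <- lapply(co$wells, function(w) screen_well(w$capture))
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_results(recs, p1)
  df1 <- read.csv(p1)
  expect_equal(nrow(df1), 10)
  expect_equal(df1$fi, vapply(recs, function(r) r$fi, numeric(1)),
               tolerance = 1e-12)
})
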