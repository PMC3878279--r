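# Synthetic paired DAPI/FITC captures with known ground truth, for testing
# segmentation, the fluorescence index and the evaluation statistics
# without microscopy data.
#
# The generator emulates what the analysis actually measures: a dark
# background with a dominant low-intensity histogram mode, bright
# non-overlapping ellipsoidal nuclei in the DAPI channel, FITC nuclear
# staining whose mean encodes the antibody level through a multiplicative
# nuclear gain, pattern texture that redistributes but never changes the
# on-mask mean, and Gaussian camera read noise. Antibody dilution follows a
# linear-in-concentration model: effective_gain =
# 1 + (nuclear_gain - 1) * (100 / dilution_factor), so FI decreases
# strictly as the dilution factor doubles.

.patterns <- c("homogenous", "speckled", "nucleolar", "centromeric", "nuclear_dots")

# run code with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration for one synthetic capture
#'
#' Defaults describe a desk-scale frame (348 x 260, 1/16 the area of a
#' 1392 x 1040 sensor) so tests run fast; scale `width`/`height` up for
#' fidelity runs. Intensity defaults mimic a dark DAPI background (mean 10)
#' with clearly resolvable nuclei (mean 120, comfortably above twice
#' background) and a moderate FITC background (mean 40) that keeps positive
#' wells away from 8-bit saturation.
#'
#' @param seed Integer RNG seed; identical configs yield bit-identical
#'   captures.
#' @param width,height Frame size in pixels.
#' @param n_nuclei Number of nuclei to place.
#' @param nucleus_radius_range Semi-axis range in pixels, `c(min, max)`.
#' @param dapi_background,dapi_nucleus Mean DAPI intensity off/on nuclei;
#'   `dapi_nucleus` must exceed twice `dapi_background` so the ground truth
#'   is recoverable by the thresholding rule.
#' @param fitc_background Mean FITC intensity off nuclei.
#' @param nuclear_gain Multiplier (>= 1) applied to `fitc_background`
#'   inside nuclei at screening dilution — the programmed FI analogue.
#' @param pattern Staining texture: `"homogenous"`, `"speckled"`,
#'   `"nucleolar"`, `"centromeric"` or `"nuclear_dots"`. Texture modulates
#'   the on-mask intensities but preserves their mean.
#' @param dilution_factor Reciprocal serum dilution, one of 100, 200, 400,
#'   800 (100 = screening dilution).
#' @param noise_sigma Gaussian read-noise SD in intensity units
#'   (default 3).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, width = 348L, height = 260L, n_nuclei = 15L,
                       nucleus_radius_range = c(6, 11), dapi_background = 10,
                       dapi_nucleus = 120, fitc_background = 40,
                       nuclear_gain = 2, pattern = "homogenous",
                       dilution_factor = 100, noise_sigma = 3) {
  if (width < 1 || height < 1) ana_domain_error("frame dimensions must be positive")
  if (length(nucleus_radius_range) != 2L || nucleus_radius_range[1] <= 0 ||
      nucleus_radius_range[1] > nucleus_radius_range[2]) {
    ana_domain_error("nucleus_radius_range must be increasing and positive")
  }
  if (dapi_nucleus <= 2 * dapi_background) {
    ana_domain_error("dapi_nucleus must exceed twice dapi_background")
  }
  if (nuclear_gain < 1) ana_domain_error("nuclear_gain must be >= 1")
  if (!pattern %in% .patterns) {
    ana_domain_error(sprintf("pattern must be one of: %s", paste(.patterns, collapse = ", ")))
  }
  if (!dilution_factor %in% c(100, 200, 400, 800)) {
    ana_domain_error("dilution_factor must be 100, 200, 400 or 800")
  }
  if (noise_sigma < 0) ana_domain_error("noise_sigma must be nonnegative")
  if (fitc_background <= 0 || fitc_background > 255) {
    ana_domain_error("fitc_background must be in (0, 255]")
  }
  structure(
    list(seed = as.integer(seed), width = as.integer(width), height = as.integer(height),
         n_nuclei = as.integer(n_nuclei), nucleus_radius_range = nucleus_radius_range,
         dapi_background = dapi_background, dapi_nucleus = dapi_nucleus,
         fitc_background = fitc_background, nuclear_gain = nuclear_gain,
         pattern = pattern, dilution_factor = dilution_factor,
         noise_sigma = noise_sigma),
    class = "sim_config")
}

# Place n non-overlapping ellipses inside the frame by rejection sampling.
place_ellipses <- function(n, width, height, radius_range, max_tries = 200L) {
  r_max <- radius_range[2]
  if (width <= 2 * (r_max + 1) || height <= 2 * (r_max + 1)) {
    ana_generation_error("frame too small for the requested nucleus size")
  }
  ell <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      ax <- runif(1, radius_range[1], radius_range[2])
      bx <- runif(1, radius_range[1], radius_range[2])
      a <- max(ax, bx); b <- min(ax, bx)  # a = major semi-axis
      cx <- runif(1, a + 1, width - a)
      cy <- runif(1, a + 1, height - a)
      ok <- TRUE
      if (i > 1L) for (e in ell[seq_len(i - 1L)]) {
        if ((cx - e$cx)^2 + (cy - e$cy)^2 < (a + e$a)^2) { ok <- FALSE; break }
      }
      if (ok) {
        ell[[i]] <- list(cx = cx, cy = cy, a = a, b = b, theta = runif(1, 0, pi))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      ana_generation_error(sprintf("could not place %d non-overlapping nuclei", n))
    }
  }
  ell
}

# Rasterise ellipses into a logical mask (row = y, col = x, top-left origin).
ellipse_mask <- function(ell, width, height) {
  mask <- matrix(FALSE, nrow = height, ncol = width)
  for (e in ell) {
    x0 <- max(1L, floor(e$cx - e$a)); x1 <- min(width, ceiling(e$cx + e$a))
    y0 <- max(1L, floor(e$cy - e$a)); y1 <- min(height, ceiling(e$cy + e$a))
    xs <- x0:x1; ys <- y0:y1
    dx <- outer(rep(1, length(ys)), xs - e$cx)
    dy <- outer(ys - e$cy, rep(1, length(xs)))
    u <- dx * cos(e$theta) + dy * sin(e$theta)
    v <- -dx * sin(e$theta) + dy * cos(e$theta)
    inside <- (u / e$a)^2 + (v / e$b)^2 <= 1
    mask[ys, xs] <- mask[ys, xs] | inside
  }
  mask
}

# Multiplicative texture field for the FITC nuclear staining; after
# normalisation its on-mask mean is exactly 1, so texture never moves the
# programmed mean (pre-noise).
pattern_field <- function(pattern, mask, ell, width, height) {
  if (pattern == "homogenous") {
    f <- matrix(1, nrow = height, ncol = width)
    return(f)
  }
  if (pattern == "speckled") {
    f <- matrix(exp(rnorm(height * width, 0, 0.6)), nrow = height, ncol = width)
    brush <- EBImage::makeBrush(7, shape = "Gaussian", sigma = 1.5)
    f <- EBImage::filter2(f, brush)
  } else {
    # focal patterns: bright foci over a dimmer base
    spec <- switch(pattern,
      nucleolar    = list(n = c(2L, 3L), r = NA, amp = 3),   # r set per nucleus
      centromeric  = list(n = c(25L, 40L), r = 1.3, amp = 4),
      nuclear_dots = list(n = c(5L, 10L), r = 2.2, amp = 4))
    f <- matrix(0.6, nrow = height, ncol = width)
    for (e in ell) {
      k <- sample(spec$n[1]:spec$n[2], 1)
      for (j in seq_len(k)) {
        # focus centre inside the ellipse (uniform in the unit disc, scaled)
        repeat {
          p <- runif(2, -1, 1)
          if (sum(p^2) <= 1) break
        }
        u <- 0.75 * p[1] * e$a; v <- 0.75 * p[2] * e$b
        fx <- e$cx + u * cos(e$theta) - v * sin(e$theta)
        fy <- e$cy + u * sin(e$theta) + v * cos(e$theta)
        r <- if (is.na(spec$r)) 0.25 * e$b else spec$r
        x0 <- max(1L, floor(fx - r)); x1 <- min(width, ceiling(fx + r))
        y0 <- max(1L, floor(fy - r)); y1 <- min(height, ceiling(fy + r))
        xs <- x0:x1; ys <- y0:y1
        d2 <- outer((ys - fy)^2, rep(1, length(xs))) +
              outer(rep(1, length(ys)), (xs - fx)^2)
        f[ys, xs] <- f[ys, xs] + spec$amp * (d2 <= r^2)
      }
    }
  }
  f / mean(f[mask])
}

quantize8 <- function(x) {
  m <- pmin(pmax(round(x), 0), 255)
  storage.mode(m) <- "integer"
  m
}

#' Generate one synthetic paired capture with ground truth
#'
#' Builds the DAPI and FITC channels from a [sim_config()]: nuclei as
#' non-overlapping ellipses; DAPI at the background mean off-mask and the
#' nucleus mean on-mask; FITC at the background mean off-mask and
#' `fitc_background * effective_gain` on-mask (mean-preserving pattern
#' texture applied), with `effective_gain = 1 + (nuclear_gain - 1) *
#' (100 / dilution_factor)`. Gaussian read noise is added, then intensities
#' are clipped to \[0, 255\] and quantised. The same config (including
#' seed) always yields bit-identical captures.
#'
#' @param config A [sim_config()].
#' @return List with `capture` (a [paired_capture()]) and `truth` (class
#'   `ground_truth`: the nucleus `mask`, `expected_fi` — the effective gain,
#'   i.e. the pre-noise FI — and the `config`).
#' @export
generate_capture <- function(config) {
  if (!inherits(config, "sim_config")) ana_format_error("config must be a sim_config")
  with_seed(config$seed, {
    w <- config$width; h <- config$height
    ell <- place_ellipses(config$n_nuclei, w, h, config$nucleus_radius_range)
    mask <- ellipse_mask(ell, w, h)
    eff_gain <- 1 + (config$nuclear_gain - 1) * (100 / config$dilution_factor)

    dapi_real <- matrix(config$dapi_background, nrow = h, ncol = w)
    dapi_real[mask] <- config$dapi_nucleus

    fitc_real <- matrix(config$fitc_background, nrow = h, ncol = w)
    tex <- pattern_field(config$pattern, mask, ell, w, h)
    on_mask <- config$fitc_background * eff_gain * tex[mask]
    # compress texture deviations into the 8-bit headroom so clipping at 255
    # cannot shift the on-mask mean away from its programmed value
    m <- config$fitc_background * eff_gain
    mx <- max(on_mask)
    if (mx > 255 && m < 255) on_mask <- m + (on_mask - m) * (255 - m) / (mx - m)
    fitc_real[mask] <- on_mask

    if (config$noise_sigma > 0) {
      dapi_real <- dapi_real + rnorm(h * w, 0, config$noise_sigma)
      fitc_real <- fitc_real + rnorm(h * w, 0, config$noise_sigma)
    }
    capture <- paired_capture(
      well_id = sprintf("sim-%d", config$seed),
      dapi = channel_image(quantize8(dapi_real), "DAPI"),
      fitc = channel_image(quantize8(fitc_real), "FITC"))
    truth <- structure(list(mask = mask, expected_fi = eff_gain, config = config),
                       class = "ground_truth")
    list(capture = capture, truth = truth)
  })
}

#' Write a paired capture as two RGB TIFF files
#'
#' The DAPI channel is stored in the blue plane and the FITC channel in the
#' green plane of 24-bit RGB TIFFs, mirroring how two-excitation captures
#' come off a colour camera.
#'
#' @param capture A [paired_capture()].
#' @param dapi_path,fitc_path Output TIFF paths.
#' @return Invisibly, `c(dapi_path, fitc_path)`.
#' @export
write_capture <- function(capture, dapi_path, fitc_path) {
  if (!inherits(capture, "paired_capture")) ana_format_error("capture must be a paired_capture")
  h <- capture$dapi$height; w <- capture$dapi$width
  compose <- function(plane, channel) {
    arr <- array(0, dim = c(h, w, 3))
    arr[, , channel] <- plane / 255
    arr
  }
  ok <- tryCatch({
    tiff::writeTIFF(compose(capture$dapi$intensities, 3), dapi_path, bits.per.sample = 8L)
    tiff::writeTIFF(compose(capture$fitc$intensities, 2), fitc_path, bits.per.sample = 8L)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) ana_io_error("cannot write capture TIFFs")
  invisible(c(dapi_path, fitc_path))
}

# draw from Normal(mean, sd) truncated to [1, Inf)
rnorm_trunc1 <- function(n, mean, sd) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- rnorm(1, mean, sd)
      if (v >= 1) { out[i] <- v; break }
    }
  }
  out
}

#' Generate a synthetic screening cohort
#'
#' Draws one well per subject in three visual strata whose programmed FI
#' (the nuclear gain at screening dilution) follows the FI distributions
#' observed in routine screening: negatives Normal(1.13, 0.06), weak
#' positives (titer 100) Normal(1.33, 0.11), positives (titer >= 200)
#' Normal(2.06, 1.18), all truncated at 1. Positive-stratum staining
#' patterns are sampled with routine-cohort frequencies (speckled
#' dominating); negatives are homogenous, which is irrelevant at gain ~1.
#' Titers for the positive stratum increase with the programmed FI through
#' its quartiles (200, 400, 800, >800).
#'
#' @param n_negative,n_weak,n_positive Stratum sizes (>= 0).
#' @param seed Integer RNG seed; cohorts are reproducible.
#' @param width,height Frame size per capture.
#' @param ... Further arguments passed to [sim_config()] (e.g.
#'   `noise_sigma`, `n_nuclei`); a `pattern` argument forces that staining
#'   pattern on every non-negative well instead of sampling.
#' @return An object of class `sim_cohort`: `wells`, a list with one
#'   element per well (`capture`, `truth`), and `table`, a data frame with
#'   `well_id`, `visual_label`, `visual_titer`, `visual_pattern`,
#'   `stratum`, `expected_fi`.
#' @export
generate_cohort <- function(n_negative, n_weak, n_positive, seed = 1L,
                            width = 348L, height = 260L, ...) {
  if (n_negative < 0 || n_weak < 0 || n_positive < 0) {
    ana_domain_error("stratum sizes must be nonnegative")
  }
  n_total <- n_negative + n_weak + n_positive
  empty_table <- data.frame(
    well_id = character(0), visual_label = character(0),
    visual_titer = character(0), visual_pattern = character(0),
    stratum = character(0), expected_fi = numeric(0),
    stringsAsFactors = FALSE)
  if (n_total == 0L) {
    return(structure(list(wells = list(), table = empty_table), class = "sim_cohort"))
  }
  dots <- list(...)
  forced_pattern <- dots$pattern
  dots$pattern <- NULL
  with_seed(seed, {
    gains <- c(rnorm_trunc1(n_negative, 1.13, 0.06),
               rnorm_trunc1(n_weak, 1.33, 0.11),
               rnorm_trunc1(n_positive, 2.06, 1.18))
    stratum <- rep(c("negative", "weak", "positive"),
                   c(n_negative, n_weak, n_positive))
    # routine single-pattern frequencies among positives
    pat_freq <- c(speckled = 91, centromeric = 10, nucleolar = 7,
                  homogenous = 5, nuclear_dots = 5)
    pattern <- ifelse(stratum == "negative", "homogenous",
                      sample(names(pat_freq), n_total, replace = TRUE,
                             prob = pat_freq / sum(pat_freq)))
    if (!is.null(forced_pattern)) pattern[stratum != "negative"] <- forced_pattern
    titer <- rep(NA_character_, n_total)
    titer[stratum == "weak"] <- "100"
    if (n_positive > 0L) {
      g_pos <- gains[stratum == "positive"]
      qs <- unique(stats::quantile(g_pos, c(0, 0.25, 0.5, 0.75, 1)))
      if (length(qs) < 2L) {
        titer[stratum == "positive"] <- "200"
      } else {
        lev <- c("200", "400", "800", ">800")[seq_len(length(qs) - 1)]
        titer[stratum == "positive"] <-
          as.character(cut(g_pos, qs, labels = lev, include.lowest = TRUE))
      }
    }
    well_seed <- sample.int(.Machine$integer.max - 1L, n_total)
    wells <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      cfg <- do.call(sim_config, c(
        list(seed = well_seed[i], width = width, height = height,
             nuclear_gain = gains[i], pattern = pattern[i]), dots))
      wells[[i]] <- generate_capture(cfg)
      wells[[i]]$capture$well_id <- sprintf("W%04d", i)
    }
    table <- data.frame(
      well_id = sprintf("W%04d", seq_len(n_total)),
      visual_label = ifelse(stratum == "negative", "negative", "positive"),
      visual_titer = titer,
      visual_pattern = ifelse(stratum == "negative", NA_character_, pattern),
      stratum = stratum,
      expected_fi = gains,
      stringsAsFactors = FALSE)
    structure(list(wells = wells, table = table), class = "sim_cohort")
  })
}
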