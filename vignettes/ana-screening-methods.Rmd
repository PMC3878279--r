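---
title: "Quantitative ANA screening on HEp-2 images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ANA screening on HEp-2 images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

Indirect immunofluorescence on HEp-2 cells reveals antinuclear antibodies
as nuclear FITC staining; the DAPI counterstain marks every nucleus
regardless of serostatus. `anascreen` reduces a paired capture of the same
microscope field to one score, the fluorescence index

$$\mathrm{FI} = \frac{\mathrm{MFI}_n}{\mathrm{MFI}_b},$$

where $\mathrm{MFI}_n$ is the mean FITC intensity over the DAPI-derived
nucleus region and $\mathrm{MFI}_b$ the mean over its complement. The
ratio form matters: multiplying the FITC channel by any positive gain —
longer exposure, brighter lamp — cancels exactly, so FI is
exposure-independent up to 8-bit quantisation and saturation. A seronegative
well has no specific nuclear staining, so
$\mathrm{MFI}_n \approx \mathrm{MFI}_b$ and FI ≈ 1; antibody binding pushes
FI above 1 in proportion to the bound antibody level, which is why FI also
tracks endpoint titer.

Assumptions inherited from the acquisition protocol:

* both captures image the **same field** and are pre-aligned — no
  registration correction is applied;
* the DAPI background is **dark and dominant**, so the lowest-intensity
  histogram mode is the background;
* nuclei are **substantially brighter than twice background** in DAPI, the
  condition under which the thresholding rule isolates them.

## Segmentation

The nucleus region comes from the DAPI channel alone:

1. compute the 256-bin intensity histogram of the full frame (no central
   crop — nothing in the protocol restricts the field);
2. find the **background peak**: smooth the counts with a centred moving
   average (default width 5 bins), collapse runs of equal smoothed values,
   and take the lowest-intensity run that exceeds both neighbouring runs
   and holds at least `peak_min_fraction` (default 1%) of all pixels. The
   reported intensity is the modal *raw* bin within that run plus a 2-bin
   margin, lowest bin on ties. Locating on the smoothed curve rejects
   single-bin camera noise; refining on the raw counts keeps a clean
   single-bin spike reported at its exact location instead of two bins low
   (the moving average spreads a spike into a 5-bin plateau). The 1% floor
   rejects hot-pixel spikes. A histogram with no qualifying run (e.g.
   perfectly flat) is an analysis error, not a guess.
3. threshold at **twice the background intensity**, clamped to [1, 255]:
   the floor keeps a zero background from selecting the whole frame, the
   ceiling respects the intensity range;
4. optionally remove connected components (8-connectivity) smaller than
   `min_object_size` pixels — a size quoted for the reference
   1392 × 1040 frame and scaled proportionally to image area for other
   sizes. Nuclei at 20x span thousands of pixels, so the default of 50
   suppresses noise speckle without touching them. Setting it to 0 keeps
   the raw threshold mask, since nothing in the underlying procedure
   mandates cleanup.

The region is deliberately **pooled**: FI averages over all nuclear pixels,
so per-cell instance separation, watershed splitting of touching nuclei and
mitotic-figure handling are irrelevant to the score and are not attempted.

Degenerate outcomes are hard per-well errors rather than silent numbers: an
empty mask ("no nuclei detected") and a mask covering more than 90% of the
frame ("background/nucleus inversion suspected") both mark the well
unevaluable — FI is only meaningful when both regions exist.

## Classification and calibration

A well is positive when FI ≥ cutoff; the boundary counts as positive
because a screening test should err toward sensitivity. The shipped
default cutoff of 1.246 is a calibration constant, not a law of nature —
`cmd_calibrate()` re-derives it for a new optical setup from any visually
labelled cohort:

* candidate thresholds are the midpoints between consecutive sorted unique
  scores, bracketed by ±∞ sentinels — a sweep invariant to monotone
  relabeling;
* the default criterion picks the candidate maximising **accuracy**
  (correct calls / total), breaking ties toward the smallest cutoff (again
  favouring sensitivity); Youden's J is available via
  `criterion = "youden"`;
* AUC is the trapezoidal area under the ROC, which equals the tie-adjusted
  probability that a random positive outscores a random negative — an
  identity the tests verify against an exhaustive pairwise count.

If more than 1% of nuclear FITC pixels sit at 255 the well is flagged
`saturated` (classification still reported): saturation compresses the
ratio downward, and a flagged well is best re-captured at shorter exposure.

## Statistics conventions

* **Cohen's kappa** on the 2×2 visual-vs-algorithm table, with the usual
  interpretation bands (< 0.4 poor, 0.4–0.75 fair to good, > 0.75
  excellent) exposed as `kappa_interpretation()`.
* **Mann-Whitney U**: average ranks on ties; exact two-sided p by
  enumerating all group assignments when both groups have ≤ 8 observations
  (valid under ties, where the classical exact tables are not), otherwise
  the normal approximation with tie-corrected variance and continuity
  correction.
* **Spearman's rho**: Pearson correlation of average-ranked data; p from
  the two-tailed t-approximation on n − 2 degrees of freedom.
* **Coefficient of variation**: 100 · sd/mean with the sample (n − 1)
  standard deviation, the convention for replicate-well reproducibility.
* Metrics with empty denominators are reported as `NA` (undefined), never
  as 0.

## The synthetic capture generator

`sim_config()`/`generate_capture()` emulate exactly the features the
analysis measures:

* non-overlapping ellipsoidal nuclei placed by rejection sampling (overlap
  realism is irrelevant because the score pools the region; an infeasible
  packing request fails loudly);
* DAPI at a dark background mean (default 10) with nuclei at 120 —
  comfortably above twice background, so ground truth is recoverable;
* FITC at a background mean of 40 with the on-mask mean multiplied by an
  **effective gain** $1 + (g - 1)\cdot 100/d$ for nuclear gain $g$ and
  reciprocal dilution $d$: a linear-in-concentration model, the simplest
  one that makes FI decrease strictly as the dilution factor doubles from
  1:100 to 1:800;
* staining-pattern texture (homogenous, speckled, nucleolar, centromeric,
  nuclear dots) that redistributes intensity but **preserves the on-mask
  mean** — texture fields are normalised to mean 1 over the mask, and
  their deviations are affinely compressed into the 8-bit headroom so
  clipping at 255 cannot bias the mean. FI is therefore
  pattern-independent by construction, mirroring how the index behaves
  across staining patterns in practice;
* Gaussian read noise (default σ = 3 intensity units) added to both
  channels before clipping and quantisation. Shot noise is not modelled:
  at 8-bit scale the read-noise term dominates what the pooled means see.

`generate_cohort()` draws a three-stratum screening cohort with programmed
FI following the distributions observed in routine screening — negatives
Normal(1.13, 0.06), weak positives Normal(1.33, 0.11), positives
Normal(2.06, 1.18), truncated at 1 — assigns titers increasing with
programmed FI, and samples positive-well patterns at routine frequencies
(speckled dominating). The truncated normal for the positive stratum is a
modelling convenience: the real distribution is right-skewed (its SD
exceeds half its mean), and truncation piles some high-titer wells just
above FI 1 where a real cohort has almost none. Synthetic cohorts are
therefore slightly *harder* to separate than real ones, and
cohort-dependent published values (AUC 0.991, cutoff 1.246, the Spearman
correlations, the replicate CVs) are treated as configuration defaults or
qualitative properties, not as quantities the simulator should reproduce.

What passing tests show, and what they do not: exact mask recovery and FI
identities hold on noiseless synthetic frames, and the end-to-end cohort
recovery (AUC, kappa, Mann-Whitney separation) holds under the synthetic
noise model. Real captures add vignetting/flat-field structure, focus
variation, debris, cytoplasmic staining and mitotic plates, none of which
are simulated — no flat-field or dark-frame correction is applied anywhere,
since the underlying procedure specifies none. Performance on real slides
must be established by calibration on a labelled cohort from the same
instrument.

## Problem sizes and determinism

The generator's default frame is 348 × 260 (1/16 the area of the reference
1392 × 1040 sensor) with 15 nuclei; the cleanup size scales with area, so
results are representative while a full 237-well cohort simulates, screens
and calibrates in well under a minute. Tests use frames down to 120 × 90
with proportionally fewer nuclei. Every stochastic component is seeded:
identical configs produce bit-identical TIFF bytes, and batch screening of
identical inputs is byte-idempotent.

## Known limitations

* No fluorescence **pattern recognition** — the package screens
  positive/negative and reports FI; pattern calls remain with the reader.
* One pooled nucleus region per field: no per-cell statistics.
* 2×2 agreement only; no multi-reader designs, no confidence intervals on
  kappa or AUC.
* FI correlates with titer but no titer-prediction calibration curve is
  fitted.
* 16-bit inputs are linearly rescaled to 8-bit on read; native 16-bit
  analysis is not supported.
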