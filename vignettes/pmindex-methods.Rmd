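---
title: "Quantifying plasma-membrane biosensor dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plasma-membrane biosensor dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmindex)
```

## The measurement problem

Anionic phosphoinositides — PI4P and PI(4,5)P2 — define the inner leaflet of
the plasma membrane (PM) and anchor polybasic proteins such as Lgl there by
electrostatics. Under energetic stress (hypoxia, ATP inhibition) these lipids
are acutely but reversibly depleted, and the PM pool of each reporter
relocates to the cytosol. Live imaging with genetically encoded biosensors
(P4M for PI4P, PLCδ-PH for PIP2, Lgl itself, intensimetric ATP sensors such
as MaLionR) turns this into a quantitative readout: per cell and per frame,
how enriched is the reporter at the PM relative to the cytosol?

The central statistic is the **PM index**

$$\mathrm{PMI} = \frac{\overline{I}_{\mathrm{PM}} - b}{\overline{I}_{\mathrm{cyto}} - b},$$

the background-corrected ratio of the mean intensity over a PM mask to the
mean over a cytosol mask. A fully cytosolic reporter gives PMI = 1. The
**normalized PM index** rescales the enrichment above 1 by its pre-stress
baseline,

$$N(t) = \frac{\mathrm{PMI}(t) - 1}{\left\langle \mathrm{PMI} - 1 \right\rangle_{\mathrm{baseline}}},$$

so 1 means baseline PM enrichment and 0 means fully cytosolic. The baseline
is the mean over the first `baseline_n` valid frames (default 3); a
"time-zero only" convention is `baseline_n = 1`. A `plain` convention
(PMI divided by its baseline mean) is provided for figures whose axis is the
raw PM index. Normalizing an already-normalized series is a no-op by
design, which is what makes the operation idempotent.

## Pipeline

`quantify_stack()` chains the stages; each is exported on its own.

1. **Registration** (`estimate_drift`, `apply_drift`). Stage drift is
   estimated per frame by cross-correlation against a reference frame,
   computed in the Fourier domain and refined on an upsampled local grid to
   `1/upsample` px. The cross power is only softly regularized
   (`|C| + 10^{-6}\max|C|`): full spectral whitening ("phase correlation"
   in the strict sense) divides numerically dead high frequencies of smooth
   microscopy images by their own magnitude and the resulting noise can
   dominate the peak. Only translation is modeled; rotation is a documented
   limitation. Correction defaults to lossless integer shifts — masks are
   recomputed per frame anyway, so resampling the intensities buys nothing
   and bilinear interpolation would smear the thin membrane band. Vacated
   margins are filled with the frame's robust background (low percentile,
   not the noise-biased minimum) so they cannot poison background detection
   downstream.
2. **Denoising** (`denoise`). The noise model is Poisson–Gaussian
   (shot noise with scaling `gain`, read noise `read_sigma`). The
   generalized Anscombe transform stabilizes the variance to 1, the à trous
   detail planes are soft-thresholded at `strength` (default 3) times the
   known per-level noise sigmas, and the algebraic inverse maps back.
   Compared to Gaussian smoothing this preserves the 3–4 px membrane band
   that both masks and means depend on; soft (not hard) thresholding leaves
   no isolated full-amplitude noise survivors to bias minimum/percentile
   background estimates. The inverse is exact on noiseless constants and
   carries an `O(gain/4)` low-count bias, negligible for region means at
   realistic intensities. The denoised copy is a *working copy*: by default
   it drives masks and background only, while intensities are measured on
   raw pixels (`measure_on = "raw"`), because thresholded wavelet shrinkage
   slightly flattens band amplitudes.
3. **Segmentation** (`segment_stack`). Two mask routes mirror the two
   imaging protocols. For epithelial junctions, the PM mask is the set of
   ROI pixels at or above the ROI's mean pixel value; the cytosol mask is
   the strict complement below the mean (ties go to the PM side so the
   partition is exhaustive), minus exclusions and minus a 1 px guard ring
   around the PM mask (`guard_px`) against PSF bleed-through. For cultured
   cells, the PM mask comes from an à trous B3-spline wavelet decomposition
   (kernel `[1,4,6,4,1]/16` with holes, mirrored borders): the sum of
   detail levels {2, 3} is thresholded at `k_sigma = 3` robust noise sigmas
   *and* at half the ROI's peak detail sum (an FWHM criterion — mid-scale
   details of a sharp band carry a halo several pixels wide that a
   noise-only threshold cannot reject), then components under `min_area =
   10` px are dropped. Masks are driven by a membrane-dye channel whenever
   one exists: a translocating sensor cannot define the PM once its signal
   has left it. Without a dye, per-frame sensor masks fall back to the last
   valid mask when the PM signal collapses, and such frames are flagged.
   Nuclei and intracellular puncta are excluded automatically
   (`detect_exclusions`): bright small wavelet blobs (4–80 px) and large
   dim regions (< half the ROI median, ≥ 50 px sized over the whole frame,
   so a nucleus corner intruding into an ROI still qualifies).
4. **Background** (`detect_background`). The protocol rule is the minimal
   pixel value of the whole frame; that is the default of the low-level
   function. The high-level pipeline instead uses the 0.1th percentile of
   the *denoised* frame: the raw minimum of a 256×256 frame sits ~2–4 noise
   sigmas below the true background, which inflates the PM index noticeably
   when the cytosol term is small.
5. **Measurement** (`pm_index_series`, `cyto_intensity_series`). Means are
   taken over the masks with saturated pixels (at the bit-depth maximum)
   excluded and counted per frame. The PM mean uses the mask eroded by
   `pm_core_px = 1`: rim pixels of any PM mask are partial-volume mixtures
   of membrane and cytosol (point-spread, residual subpixel motion), the
   exact bleed-through the guard ring removes on the cytosol side. Frames
   with an empty mask or a non-positive denominator are *flagged invalid*,
   never silently NaN. Intensimetric cytosolic sensors (ATP) get a
   background-subtracted, baseline-normalized cytosolic intensity ("cyto
   index") instead of a ratio.
6. **Kinetics** (`fit_kinetics`, `compare_onsets`). Each normalized series
   is fit by bounded least squares to a continuous piecewise-exponential
   trajectory: baseline B until `t_hypoxia + delay`, exponential decay to a
   floor, then from `t_reoxy + recovery_delay` exponential rise to a
   plateau — three deterministic starts from a coarse rate grid seeded by
   raw half-crossings, then a tight polish. The half-transition times are
   computed from fitted parameters: `t50_dep` where the curve crosses
   halfway from baseline to floor, `t50_rec` halfway from the
   recovery-onset value to the plateau. The source figures report temporal
   orderings without defining a t50, so this definition is the package's
   own. `compare_onsets` takes per-cell paired t50 differences, the median,
   and a seeded percentile bootstrap CI over cells — cells, not frames, are
   the independent replicates. Constant series are flagged (rate 0, t50
   undefined); total optimizer failure falls back to raw crossings, also
   flagged.

## The synthetic world

Because the source study deposits no imaging data, every stage is validated
against `render_stack()`, a ground-truthed simulator. Its defaults *are* the
stated experimental world, chosen once:

* **Timeline**: 90 frames at 60 s/frame; hypoxia onset at frame 10 (600 s),
  reoxygenation at frame 60 (3600 s) — the ~50 min stress / ~30 min recovery
  window of the live-imaging assays.
* **Kinetics** (`default_kinetic_model()`): piecewise-exponential occupancy
  per sensor, the minimal form reproducing every described feature (delayed
  onset, graded depletion over ~30–60 min, floor, fast recovery within ~10
  min, optional early transient overshoot). Depletion delays/rates order the
  half-times Lgl (≈260 s) < PIP2 (≈470 s) < PI4P (≈860 s) after onset and
  recovery half-times PI4P (≈120 s) < PIP2 (≈240 s) < Lgl (≈410 s) after
  reoxygenation, the study's qualitative headline. The PI4P overshoot
  amplitude is 0.15 — a free choice, only the existence of the transient is
  established — rendered as a continuous pulse `A (s/\tau) e^{1 - s/\tau}`
  (a discontinuous decaying exponential would contradict the continuity the
  trajectory must have). The PI4P puncta pool (25 % of sensor mass) empties
  before PM PI4P and refills after it.
* **Geometry**: jittered-seed Voronoi tissue (polygonal epithelium tiling
  the field) or non-touching blobby single cells; membrane band `w_mem = 3`
  px at 0.2 µm/px (~0.6 µm, a PSF-limited junction), dark nuclei (sensor-
  excluded, as in real movies, which is also what makes the whole-frame
  minimum a sensible background rule in tissue), 2–4 px puncta.
* **Rendering**: per cell and frame the sensor mass is conserved and
  partitioned PM : puncta : cytosol by the occupancy curves; membrane and
  puncta carry *excess* signal on top of the cytosolic level because they
  overlay cytoplasm in projection — this is why a fully depleted sensor
  gives PMI → 1 rather than 0, and why the noiseless normalized PM index
  equals the occupancy curve exactly. The ATP channel is intensimetric by
  design (brightness, not location, is its signal) and is the one channel
  exempt from mass conservation. Whole-frame random-walk drift
  (`step_sigma = 0.5` px/frame), then Poisson noise (`gain = 2`) and
  Gaussian read noise (`read_sigma = 2`) on top of a constant background
  offset (10). At the default amplitude (100) this gives membrane SNR ≈ 15
  and cytosol SNR ≈ 6.
* **Series-level shortcut** (`simulate_index_series`): for kinetics
  simulation studies the normalized index is generated directly as
  occupancy + i.i.d. Gaussian noise (SD 0.05, matching the frame-to-frame
  scatter of the image-level pipeline at default SNR). This is what the
  ordering power/false-positive studies use; rendering 100 full movies
  would test the same code path at ~1000× the cost.

What the simulator deliberately does **not** emulate: optics (no PSF
convolution; band edges are sharp), photobleaching, 3-D structure, rotation,
cell movement or shape change, and autofluorescence gradients. A green test
therefore establishes correctness of the measurement chain on data whose
kinetic and noise structure matches the real assays — not robustness to
every optical artifact of a real microscope.

## Numerical choices and degenerate inputs

* Coordinates are pixel-centered `(row, col)`, 0-based, row 0 at top, in
  all on-disk formats; R matrices are 1-based internally.
* Polygon rasterization uses the even-odd rule with a half-open boundary
  convention, so shoelace area and pixel count agree on axis-aligned
  rectangles; self-intersecting polygons are rejected at parse time with
  the ROI's label.
* The à trous reconstruction identity (input = Σ details + smooth) holds to
  machine precision by construction and is property-tested; per-level noise
  sigmas are the L2 norms of the equivalent filters, computed from an
  impulse response and cached.
* Mean-threshold ties: PM takes `≥ mean`, cytosol takes `< mean` — the
  partition is exhaustive before exclusions; the tie rule is unspecified in
  the source protocol.
* The PM-index denominator must exceed `10^{-6}` of its own scale; below
  that the scalar function errors and the series context flags the frame.
* Degenerate cases with defined behavior: constant ROI (warning, PM mask =
  whole ROI), all-saturated frame (invalid flag, `sat_frac = 1`), empty
  cytosol mask after exclusions (error advising a larger ROI), baseline
  index ≈ 1 (normalization error naming the ROI), constant series (flagged
  fit, undefined t50), flat frame (registration error naming the frame).
* TIFF I/O is a self-contained baseline implementation (uncompressed,
  grayscale, uint8/16/32 and float32/64, both endiannesses, multi-strip
  reads) because no TIFF package exists in the supported environment; stack
  metadata travels in the ImageDescription tag as prefixed JSON, and the
  files are validated against an independent reader in the tests.

## Known limitations

* Registration is translation-only; rotating samples need upstream
  correction.
* The wavelet PM mask's FWHM criterion assumes the membrane is the
  brightest ridge structure in the ROI — true for membrane dyes and
  baseline sensors, not necessarily during deep depletion (which is why
  masks should be driven by the dye channel).
* The bootstrap ordering test reports percentile CIs; with ~20 cells their
  coverage is approximate (~93–96 %), adequate for the effect sizes here
  but not a calibrated exact test.
* The fitted trajectory has no overshoot term; for sensors with a strong
  early transient the depletion delay absorbs it, slightly biasing
  `t50_dep` upward (the orderings, separated by hundreds of seconds, are
  unaffected).
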