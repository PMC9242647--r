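# pmindex

Quantification of plasma-membrane (PM) biosensor dynamics in multi-channel
time-lapse fluorescence movies.

## The problem

The inner leaflet of the plasma membrane is defined by the anionic lipids
PI4P and PI(4,5)P2, which anchor polybasic polarity proteins (e.g. Lgl)
there electrostatically. Under energetic stress — hypoxia, or direct ATP
inhibition — both lipids are acutely and reversibly depleted from the PM,
and everything that binds them relocates to the cytosol; on reoxygenation
they return within minutes, in a characteristic order (PM PI4P first, then
PIP2, then Lgl; depletion runs in the opposite order, Lgl first). Live
imaging with translocating biosensors (P4M for PI4P, PLCδ-PH for PIP2, Lgl
itself) and intensimetric sensors (MaLionR for ATP) turns these events into
time series, but extracting comparable numbers from movies requires a
pipeline: stabilization, denoising, PM/cytosol segmentation, background
correction, normalization, and kinetic summary statistics.

`pmindex` implements that pipeline in R, end to end, for people analysing
such movies (or building on the protocol): the central statistic is the
**PM index**

    PMI = (mean_PM - background) / (mean_cyto - background)

(1 = no PM enrichment) and its baseline-normalized form

    N(t) = (PMI(t) - 1) / <PMI - 1>_baseline

(1 = baseline enrichment, 0 = fully cytosolic), computed per ROI, channel
and frame, plus piecewise-exponential depletion/recovery fits with
half-transition times (t50) and bootstrap ordering statistics between
sensors. Because public imaging data for this protocol do not exist, the
package ships a ground-truthed synthetic movie generator
(`generate_geometry()`, `default_kinetic_model()`, `render_stack()`) that
emulates the kinetic structure of the real experiments, so every stage is
testable offline.

## Worked example

Simulate a 90-minute hypoxia/reoxygenation movie of a 16-cell epithelium
(stress at 10 min, reoxygenation at 60 min), quantify junction ROIs, fit
kinetics, and test which sensor moves first:

```r
library(pmindex)

geom  <- generate_geometry(n_cells = 16, image_shape = c(256, 256),
                           mode = "tissue", seed = 1)
model <- default_kinetic_model()
sim   <- render_stack(geom, model, channels = c("PIP2", "PI4P", "dye"),
                      n_frames = 90, seed = 1)
sim$stack
#> ImageStack: 90 frames x 3 channels x 256 x 256 px
#>   channels: PIP2, PI4P, dye
#>   pixel_size: 0.2 um/px, frame_interval: 60 s

rois <- synthetic_rois(geom, n = 6, seed = 1)     # junction ROIs
res  <- quantify_stack(sim$stack, rois, channels = c("PIP2", "PI4P"))

s <- res$series[["junction_10_14:PIP2"]]
round(s[c(1, 10, 30, 60, 75, 90), c("frame", "time_s", "pm_index", "norm_pm_index")], 3)
#>    frame time_s pm_index norm_pm_index
#> 1      1      0    5.864         1.012
#> 10    10    540    5.423         0.920
#> 30    30   1740    1.181         0.038
#> 60    60   3540    1.081         0.017
#> 75    75   4440    5.576         0.952
#> 90    90   5340    5.817         1.002
```

The PM index starts around 5.9 (strong PM enrichment), collapses to ~1.1
(essentially cytosolic) during hypoxia, and recovers fully after
reoxygenation; the normalized index maps the same trajectory onto a 1 → 0
→ 1 scale.

```r
fit <- fit_kinetics(s$time_s, s$norm_pm_index, model$t_hypoxia, model$t_reoxy)
fit
#> kinetics_fit:
#>       baseline          delay depletion_rate          floor recovery_delay
#>       0.981497     239.010458       0.003870       0.021394     128.469374
#>  recovery_rate        plateau
#>       0.004697       0.977354
#>   t50_dep = 1018.1 s, t50_rec = 3876.0 s, rmse = 0.02071
```

The fit recovers the generator's PIP2 parameters (240 s depletion delay,
0.003/s rate, 120 s recovery delay): half-depletion ~418 s after stress
onset, half-recovery ~276 s after reoxygenation.

```r
pick <- function(ch) lapply(grep(paste0(":", ch, "$"), names(res$series)),
                            function(i) { x <- res$series[[i]]
                              fit_kinetics(x$time_s, x$norm_pm_index,
                                           model$t_hypoxia, model$t_reoxy) })
compare_onsets(pick("PIP2"), pick("PI4P"), "depletion", n_boot = 1000, seed = 1)
#> OrderingResult (depletion): median dt50 = -243.7 s, 95% CI [-247.9, -232.0],
#>   n = 6, frac(a first) = 1.00
```

PIP2 reaches half-depletion ~4 min before PI4P in every ROI, with a
bootstrap CI excluding zero — the temporal ordering the assay is built to
detect.

Other entry points: `estimate_drift()`/`apply_drift()` (stabilization),
`denoise()` (Poisson–Gaussian), `atrous_decompose()`/`wavelet_pm_mask()`
(B3-spline à trous segmentation for cultured cells), `reslice_max()`
(wide-line maximum-projection kymographs), `cyto_intensity_series()`
(intensimetric ATP "cyto index"), `plot_series()` (figure-style panels),
and a CLI umbrella (`inst/cli/pmindex.R`) with subcommands
`simulate | preprocess | segment | quantify | kymograph | fit | compare | report`.

See `vignettes/pmindex-methods.Rmd` for the models, parameter meanings,
defaults and their rationale, and known limitations.

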