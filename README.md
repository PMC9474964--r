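# dtwpet

Kinetic quantification of dynamic ¹⁸F-FDG PET under the irreversible
two-tissue compartment model (2T3k), built around the **dual-time-window
(DTW) protocol**: an early dynamic scan over [0, t₁] and a late scan ending
at 60 min, with the un-acquired middle of the scan bridged computationally.
The package is for imaging scientists who want to study — or run — shortened
dynamic protocols without giving up the micro-parameters K₁, k₂, k₃, V_b or
the net influx rate

&nbsp;&nbsp;&nbsp;&nbsp;K_i = K₁·k₃ / (k₂ + k₃)  (mL/g/min).

What it provides, end to end:

* **Forward model and fitting** — analytic 2T3k solution against
  piecewise-linear input functions (exact per-segment convolution, no
  quadrature grid), frame-averaged or midpoint sampling on the 66-frame
  total-body schedule (24×5 s, 6×10 s, 6×30 s, 6×60 s, 24×120 s), bounded
  multi-start weighted least squares.
* **DTW machinery** — gap truncation, completion of the missing TAC segment
  with a pole-free 3rd-degree rational function
  C_E(t) = (p₃t + p₅t² + p₇t³)/(1 + p₄t + p₆t² + p₈t³) (nonnegative
  coefficients, variable-projection NNLS fit), and MAPE / percent-bias error
  metrics.
* **Input functions** — ROI extraction from 4D images, population-based
  IDIF averaging, the continuity-matched hybrid bridge
  μ·e^(−γ(t−t₁))·C_p0(t) for DTW, the α-scaled static variant for FUR and
  Patlak, and ±60 s delay-correction search.
* **Simplified measures** — SUV, FUR and Patlak graphical analysis
  (t* = 30 min), with broom-style `tidy()`/`glance()` methods.
* **Parametric imaging** — voxel-wise linearized 2T3k via Lawson–Hanson
  nonnegative least squares (implemented in the package) with the verified
  back-mapping to (K₁, k₂, k₃, V_b, K_i), Patlak K_i images, and ROI
  coefficient-of-variation map-noise metrics.
* **Synthetic data** — seed-deterministic virtual subjects (Feng-type
  arterial inputs with population jitter, tissue priors for cortex / muscle
  / tumor, count-limited frame noise at voxel and ROI scales) and small 4D
  phantoms, so every pipeline stage runs without patient data.
* **Cohort evaluation** — reference-vs-surrogate regressions (R², slope,
  intercept, p), Bland–Altman agreement, bias distributions, ggplot2
  `autoplot()` methods, deterministic JSON reports.

Everything tabular is a tibble and pipes through dplyr; 4D images are plain
arrays carried in a light `dynamic_image` container (NIfTI export via
RNifti). A thin command-line front end lives at `inst/cli/dtwpet.R`.

## Worked example

```r
library(dtwpet)

# a noise-free virtual subject and its measured blood curve
subject <- simulate_subject(7, noise = noise_model(0))
idif <- input_function(frame_mid(subject$idif_tac), subject$idif_tac$value)

# reference: full 60-min scan, 2T3k fit
ref <- fit_2t3k(subject$tacs$cortex, idif, sampling = "midpoint", n_starts = 2)
ref
#> 2T3k fit (ok)
#>   K1 = 0.1109 mL/g/min, k2 = 0.1061, k3 = 0.0583 min^-1, Vb = 0.0325
#>   Ki = 0.03934 mL/g/min, weighted RSS = 3.264e-06, delay = 0 s

# DTW (10+5 min): drop the middle of the scan, complete it, bridge the
# input with a population curve, refit
cohort <- simulate_cohort(5, 7, noise = noise_model(0))
pb <- build_pb_idif(purrr::map(cohort, "idif_tac"),
                    purrr::map_dbl(cohort, ~ .x$meta$dose_MBq),
                    purrr::map_dbl(cohort, ~ .x$meta$weight_kg))
dtw <- quantify_dtw(subject$tacs$cortex, subject$idif_tac, pb, c(10, 55),
                    sampling = "midpoint", n_starts = 2)
dtw$fit$params$Ki
#> [1] 0.03823786
percent_bias(ref$params$Ki, dtw$fit$params$Ki)   # positive = underestimate
#> [1] 2.792494
```

The generating truth for this subject's cortex is K_i = 0.0393: the
full-scan fit recovers it essentially exactly, and the 15-minute DTW
protocol lands within ~3% of the reference;
across the package's 50-subject noise-free validation cohort the per-subject
K_i bias stays within a few percent (see the methods vignette,
`vignettes/dtw-quantification.Rmd`, for the model, the design decisions and
the conditions under which that holds).

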