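#' Feng tri-exponential arterial input model
#'
#' The standard parametric FDG arterial curve:
#' C_p(t) = (A1 (t - td) - A2 - A3) exp(l1 (t - td)) + A2 exp(l2 (t - td))
#' + A3 exp(l3 (t - td)) for t >= td, 0 before. Defaults are the widely
#' used FDG population values (amplitudes rescaled to kBq/mL), which give a
#' sharp bolus peak within ~2 min of arrival and a slowly clearing tail --
#' the shape the hybrid-input machinery assumes.
#'
#' @param A1 Peak amplitude slope, kBq/mL/min (default 851.1).
#' @param A2,A3 Tail amplitudes, kBq/mL (defaults 21.9, 20.8).
#' @param l1,l2,l3 Decay rates, min^-1 (negative; defaults -4.1339,
#'   -0.1191, -0.0104, so l1 < l2 <= l3 < 0).
#' @param t_delay Arrival delay, minutes (default 0.5).
#' @return A `feng_params` tibble row.
#' @export
feng_params <- function(A1 = 851.1, A2 = 21.9, A3 = 20.8,
                        l1 = -4.1339, l2 = -0.1191, l3 = -0.0104,
                        t_delay = 0.5) {
  if (!(l1 < l2 && l2 <= l3 && l3 < 0)) stop("need l1 < l2 <= l3 < 0")
  structure(tibble::tibble(A1 = A1, A2 = A2, A3 = A3,
                           l1 = l1, l2 = l2, l3 = l3, t_delay = t_delay),
            class = c("feng_params", class(tibble::tibble())))
}

#' Evaluate a Feng input function on a grid
#'
#' @param params A `feng_params` row.
#' @param grid Time grid in minutes; the default is dense (0.02 min) over
#'   the first 3 minutes to resolve the bolus peak, then 0.25 min to 60.
#' @return A `pet_if`.
#' @export
feng_input <- function(params, grid = default_if_grid()) {
  tt <- grid - params$t_delay
  v <- ifelse(tt <= 0, 0,
              (params$A1 * tt - params$A2 - params$A3) * exp(params$l1 * tt) +
                params$A2 * exp(params$l2 * tt) +
                params$A3 * exp(params$l3 * tt))
  if (any(v < -1e-6 * max(abs(v)))) stop("Feng parameters give a negative curve")
  input_function(grid, pmax(v, 0))
}

default_if_grid <- function() {
  unique(c(seq(0, 3, by = 0.02), seq(3, 60, by = 0.25)))
}

#' Tissue kinetic priors for the synthetic cohort
#'
#' Uniform ranges for (K1, k2, k3, Vb) per tissue class. The defaults give
#' cerebral-cortex-like (Ki ~ 0.02-0.04), skeletal-muscle-like
#' (Ki ~ 0.002-0.005) and tumor-like (Ki up to ~0.1 mL/g/min) FDG kinetics
#' -- configuration defaults spanning the regimes the quantification
#' methods are compared over, not fits to any dataset.
#'
#' @return A tibble, one row per tissue, with `*_lo` / `*_hi` range columns.
#' @export
tissue_priors <- function() {
  tibble::tribble(
    ~tissue,  ~K1_lo, ~K1_hi, ~k2_lo, ~k2_hi, ~k3_lo, ~k3_hi, ~Vb_lo, ~Vb_hi,
    "cortex",   0.08,   0.12,   0.10,   0.16,   0.04,   0.08,   0.03,   0.06,
    "muscle",   0.02,   0.04,   0.10,   0.25,   0.01,   0.03,   0.01,   0.04,
    "tumor",    0.10,   0.60,   0.20,   0.60,   0.04,   0.15,   0.04,   0.15)
}

#' Count-limited frame noise model
#'
#' Gaussian frame noise with standard deviation
#' sigma_i = scale * sqrt(C(t_i) / dt_i): variance proportional to the
#' frame-mean concentration and inversely to frame duration, emulating
#' count statistics. The default `scale = 0.3` (kBq/mL units) is the
#' voxel-scale calibration: late 2-min frames of a typical tissue curve
#' carry ~5-15% relative noise, as in total-body reconstructions. A region
#' averaging N voxels has scale smaller by sqrt(N); [simulate_subject()]
#' uses 0.05 for its ROI-level curves on that basis.
#'
#' @param scale Noise scale (default 0.3); 0 disables noise.
#' @return A `noise_model` list.
#' @export
noise_model <- function(scale = 0.3) {
  if (scale < 0) stop("scale must be >= 0")
  structure(list(scale = scale), class = "noise_model")
}

add_frame_noise <- function(values, schedule, noise) {
  if (noise$scale == 0) return(values)
  sigma <- noise$scale * sqrt(pmax(values, 0) / frame_dur(schedule))
  pmax(values + stats::rnorm(length(values), 0, sigma), 0)
}

draw_params <- function(priors_row) {
  r <- function(lo, hi) stats::runif(1, lo, hi)
  kinetic_params(r(priors_row$K1_lo, priors_row$K1_hi),
                 r(priors_row$k2_lo, priors_row$k2_hi),
                 r(priors_row$k3_lo, priors_row$k3_hi),
                 r(priors_row$Vb_lo, priors_row$Vb_hi))
}

jitter_feng <- function(base, cv) {
  f <- function() exp(stats::rnorm(1, -cv^2 / 2, cv))   # mean-1 log-normal
  feng_params(A1 = base$A1 * f(), A2 = base$A2 * f(), A3 = base$A3 * f(),
              l1 = base$l1, l2 = base$l2, l3 = base$l3,
              t_delay = base$t_delay * exp(stats::rnorm(1, 0, 0.1)))
}

#' Simulate one virtual subject
#'
#' Draws tissue kinetic parameters from the priors and a subject-specific
#' arterial input (population-jittered Feng curve scaled by injected dose
#' per body weight), synthesises frame-averaged tissue TACs through the
#' forward 2T3k model, and adds count-limited frame noise. The generating
#' truth is recorded alongside the data.
#'
#' @param seed Integer seed; the subject is fully reproducible from it.
#' @param schedule Frame schedule (default the 66-frame protocol).
#' @param priors Tissue prior table (default [tissue_priors()]).
#' @param noise A `noise_model`; the default scale 0.05 is the ROI-level
#'   counterpart of the voxel-scale model (a region averaging ~36 voxels of
#'   voxel-scale noise 0.3 has frame noise 0.3/sqrt(36)).
#' @param if_cv Log-normal coefficient of variation of the Feng amplitudes
#'   across the population (default 0.15).
#' @param base_if Base `feng_params` for the population.
#' @return A `pet_subject`: list with `idif` (true continuous `pet_if`),
#'   `idif_tac` (measured blood-pool `pet_tac`, noisy), `tacs` (named list
#'   of tissue `pet_tac`s), `truth` (tibble of generating parameters per
#'   tissue), and `meta` (dose_MBq, weight_kg, seed).
#' @export
simulate_subject <- function(seed, schedule = frame_schedule_66(),
                             priors = tissue_priors(),
                             noise = noise_model(0.05),
                             if_cv = 0.15, base_if = feng_params()) {
  set.seed(seed)
  weight_kg <- stats::rnorm(1, 61, 8)
  weight_kg <- min(max(weight_kg, 40), 100)
  dose_MBq <- stats::rnorm(1, 230, 35)
  dose_MBq <- min(max(dose_MBq, 120), 380)
  fp <- jitter_feng(base_if, if_cv)
  ## amplitude tracks injected dose per body mass around the population mean
  s <- (dose_MBq / weight_kg) / (230 / 61)
  fp <- feng_params(fp$A1 * s, fp$A2 * s, fp$A3 * s, fp$l1, fp$l2, fp$l3,
                    fp$t_delay)
  idif <- feng_input(fp)
  idif_frames <- frame_average(idif, schedule)
  idif_tac <- tac(schedule, add_frame_noise(idif_frames$value, schedule, noise))

  truth <- purrr::map_dfr(seq_len(nrow(priors)), function(i) {
    dplyr::bind_cols(tibble::tibble(tissue = priors$tissue[i]),
                     draw_params(priors[i, ]))
  })
  tacs <- purrr::map(seq_len(nrow(truth)), function(i) {
    curve <- model_tac(idif, truth[i, ], schedule)
    tac(schedule, add_frame_noise(curve$value, schedule, noise))
  })
  names(tacs) <- truth$tissue
  structure(list(idif = idif, idif_tac = idif_tac, tacs = tacs, truth = truth,
                 meta = tibble::tibble(dose_MBq = dose_MBq,
                                       weight_kg = weight_kg, seed = seed)),
            class = "pet_subject")
}

#' Frame-sampled forward-model TAC
#'
#' Convenience wrapper: evaluates the 2T3k forward model for `params`
#' driven by `input_fn` and samples it on `schedule` (frame averages by
#' default, midpoints optionally).
#'
#' @inheritParams fit_2t3k
#' @param params A `kinetic_params` row.
#' @param schedule A `frame_schedule`.
#' @param nsub Quadrature subintervals per frame in average mode.
#' @return A `pet_tac`.
#' @export
model_tac <- function(input_fn, params, schedule,
                      sampling = c("average", "midpoint"), nsub = 6) {
  sampling <- match.arg(sampling)
  model <- tissue_model_factory(input_fn, schedule, sampling, nsub)
  tac(schedule, pmax(model(params$K1, params$k2, params$k3, params$Vb), 0))
}

#' Simulate a cohort of virtual subjects
#'
#' @param n Number of subjects.
#' @param seed Base seed; subject i uses `seed * 1000 + i` (kept well below
#'   2^31).
#' @param ... Passed to [simulate_subject()].
#' @return List of `pet_subject`s.
#' @export
simulate_cohort <- function(n, seed, ...) {
  base <- (as.integer(seed) %% 1000000L) * 1000L
  purrr::map(seq_len(n), function(i) simulate_subject(base + i, ...))
}

#' Simulate a small dynamic phantom
#'
#' Builds a 4D dynamic image from disjoint box regions, each filled with
#' the frame-averaged TAC of its tissue class plus i.i.d. per-voxel frame
#' noise. A blood-pool region carrying the (frame-averaged) input function
#' is always included, so image-derived input extraction is exercisable.
#'
#' @param seed Integer seed.
#' @param dims Spatial dimensions (default `c(24, 24, 8)`).
#' @param schedule Frame schedule (default 66 frames).
#' @param noise A `noise_model` (default scale 0.3).
#' @param regions A tibble with columns `tissue`, `x0`, `x1`, `y0`, `y1`,
#'   `z0`, `z1` (inclusive voxel index ranges); must be disjoint. `tissue`
#'   may be `"blood"` or a row name of [tissue_priors()]. Default: four
#'   disjoint boxes (blood, cortex, muscle, tumor).
#' @return A `pet_phantom`: list with `image` (`dynamic_image`), `masks`
#'   (named list of logical arrays), `truth` (tibble per region), and
#'   `input_fn` (the generating `pet_if`).
#' @export
simulate_phantom <- function(seed, dims = c(24, 24, 8),
                             schedule = frame_schedule_66(),
                             noise = noise_model(),
                             regions = default_phantom_regions()) {
  set.seed(seed)
  check_regions_disjoint(regions, dims)
  fp <- jitter_feng(feng_params(), 0.1)
  input_fn <- feng_input(fp)
  priors <- tissue_priors()
  nframe <- nrow(schedule)
  img <- array(0, c(dims, nframe))
  masks <- list()
  truth <- NULL
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    mask <- array(FALSE, dims)
    mask[r$x0:r$x1, r$y0:r$y1, r$z0:r$z1] <- TRUE
    masks[[r$tissue]] <- mask
    if (r$tissue == "blood") {
      curve <- frame_average(input_fn, schedule)
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        tissue = "blood", K1 = NA, k2 = NA, k3 = NA, Vb = NA, Ki = NA))
    } else {
      p <- draw_params(priors[priors$tissue == r$tissue, ])
      curve <- model_tac(input_fn, p, schedule)
      truth <- dplyr::bind_rows(truth,
                                dplyr::bind_cols(tibble::tibble(tissue = r$tissue), p))
    }
    vox <- which(mask)
    sigma <- noise$scale * sqrt(pmax(curve$value, 0) / frame_dur(schedule))
    for (f in seq_len(nframe)) {
      slab <- img[, , , f]
      slab[vox] <- pmax(curve$value[f] +
                          stats::rnorm(length(vox), 0, sigma[f]), 0)
      img[, , , f] <- slab
    }
  }
  structure(list(image = dynamic_image(img, schedule), masks = masks,
                 truth = truth, input_fn = input_fn,
                 meta = tibble::tibble(seed = seed)),
            class = "pet_phantom")
}

default_phantom_regions <- function() {
  tibble::tribble(
    ~tissue,  ~x0, ~x1, ~y0, ~y1, ~z0, ~z1,
    "blood",    2,   7,   2,   7,   2,   6,
    "cortex",  10,  15,   2,   7,   2,   6,
    "muscle",   2,   7,  10,  15,   2,   6,
    "tumor",   10,  15,  10,  15,   2,   6)
}

check_regions_disjoint <- function(regions, dims) {
  occ <- array(FALSE, dims)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (r$x1 > dims[1] || r$y1 > dims[2] || r$z1 > dims[3] ||
        min(r$x0, r$y0, r$z0) < 1) {
      stop("region outside the phantom volume")
    }
    sub <- occ[r$x0:r$x1, r$y0:r$y1, r$z0:r$z1]
    if (any(sub)) stop("phantom regions must be disjoint")
    occ[r$x0:r$x1, r$y0:r$y1, r$z0:r$z1] <- TRUE
  }
  invisible(TRUE)
}
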