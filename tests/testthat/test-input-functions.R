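test_that("piecewise-linear evaluation, integration and shifting are exact", {
  inp <- input_function(c(0, 1, 2, 4), c(0, 10, 2, 2))
  expect_equal(if_value(inp, c(0.5, 1, 1.5, 3, 10)), c(5, 10, 6, 2, 2))
  expect_equal(if_value(inp, -1), 0)
  # trapezoid areas: bolus triangle-ish segments
  expect_equal(if_auc(inp, 0, 1), 5)
  expect_equal(if_auc(inp, 0, 2), 11)
  expect_equal(if_cumint(inp, 4), 15)
  # monotone running integral
  tt <- seq(0, 4, by = 0.1)
  expect_true(all(diff(if_cumint(inp, tt)) >= 0))
  # shifting by +60 s delays the bolus by a minute
  sh <- if_shift(inp, 60)
  expect_equal(if_value(sh, 2), 10)
  expect_equal(if_value(sh, 0.5), 0)
  # negative shift advances it
  sh2 <- if_shift(inp, -30)
  expect_equal(if_value(sh2, 0.5), 10)
})

test_that("input-function construction rejects invalid grids", {
  expect_error(input_function(c(0, 1, 1), c(1, 2, 3)), "strictly increasing")
  expect_error(input_function(c(0, 1), c(1, -2)), ">= 0")
  expect_error(input_function(0, 1), "two grid nodes")
})

test_that("ROI extraction averages the voxels of the mask", {
  sched <- frame_schedule(list(c(3, 60)))
  arr <- array(0, c(2, 2, 1, 3))
  arr[1, 1, 1, ] <- c(1, 2, 3)
  arr[2, 1, 1, ] <- c(3, 4, 5)
  img <- dynamic_image(arr, sched)
  mask1 <- array(FALSE, c(2, 2, 1)); mask1[1, 1, 1] <- TRUE
  expect_equal(extract_roi_tac(img, mask1)$value, c(1, 2, 3))
  mask2 <- mask1; mask2[2, 1, 1] <- TRUE
  expect_equal(extract_roi_tac(img, mask2)$value, c(2, 3, 4))
  expect_error(extract_roi_tac(img, array(FALSE, c(2, 2, 1))), "empty")
})

test_that("phantom blood-pool extraction recovers the simulated input frame averages", {
  ph <- simulate_phantom(7, noise = noise_model(0))
  got <- extract_roi_tac(ph$image, ph$masks$blood)
  want <- frame_average(ph$input_fn, ph$image$schedule)
  expect_equal(got$value, want$value, tolerance = 1e-10)
})

test_that("population input averaging normalises and averages correctly", {
  sched <- frame_schedule_66()
  inp <- fix_input()
  base <- frame_average(inp, sched)
  # two identical normalized TACs -> PB-IDIF equals either input
  pb <- build_pb_idif(list(base, base), c(200, 200), c(60, 60))
  expect_equal(pb$value, base$value / (200 / 60), tolerance = 1e-12)
  # TACs c and 3c at equal dose/weight average to 2c
  t3 <- tac(sched, 3 * base$value)
  pb2 <- build_pb_idif(list(base, t3), c(100, 100), c(50, 50))
  expect_equal(pb2$value, 2 * base$value / 2, tolerance = 1e-12)
  expect_error(build_pb_idif(list(base), 100, 50), "at least 2")
})

test_that("population mean curve is recovered across a simulated cohort", {
  cohort <- simulate_cohort(15, 7, noise = noise_model(0))
  pb <- build_pb_idif(purrr::map(cohort, "idif_tac"),
                      purrr::map_dbl(cohort, ~ .x$meta$dose_MBq),
                      purrr::map_dbl(cohort, ~ .x$meta$weight_kg))
  # each subject curve normalised by dose/weight should scatter around pb
  mids <- frame_mid(cohort[[1]]$idif_tac)
  late <- mids > 30
  norm_curves <- purrr::map(cohort, function(s)
    s$idif_tac$value / (s$meta$dose_MBq / s$meta$weight_kg))
  pop_mean <- Reduce(`+`, norm_curves) / length(norm_curves)
  expect_equal(pb$value[late], pop_mean[late], tolerance = 1e-10)
  # and the PB curve lies within the cohort envelope
  env_lo <- purrr::reduce(norm_curves, pmin)
  env_hi <- purrr::reduce(norm_curves, pmax)
  expect_true(all(pb$value >= env_lo - 1e-9 & pb$value <= env_hi + 1e-9))
})

test_that("hybrid bridge is exact when the population curve is the subject's own", {
  sched <- frame_schedule_66()
  inp <- fix_input()
  blood <- frame_average(inp, sched)
  pb <- input_function(frame_mid(blood), blood$value)
  mid <- frame_mid(blood)
  g <- truncate_to_dtw(blood, c(10, 55))
  gm <- frame_mid(g)
  hy <- hybrid_if_dtw(g[gm < 10, ], g[gm > 55, ], pb, 10, 55)
  expect_equal(hy$params$mu, 1, tolerance = 1e-10)
  expect_equal(hy$params$gamma, 0, tolerance = 1e-10)
  # doubled population curve halves mu, leaves gamma at zero
  pb2 <- input_function(pb$time, 2 * pb$value)
  hy2 <- hybrid_if_dtw(g[gm < 10, ], g[gm > 55, ], pb2, 10, 55)
  expect_equal(hy2$params$mu, 0.5, tolerance = 1e-10)
  expect_equal(hy2$params$gamma, 0, tolerance = 1e-10)
})

test_that("hybrid curves join continuously and stay nonnegative", {
  cohort <- simulate_cohort(3, 21, noise = noise_model(0))
  s <- cohort[[1]]
  pb <- build_pb_idif(purrr::map(cohort, "idif_tac"),
                      purrr::map_dbl(cohort, ~ .x$meta$dose_MBq),
                      purrr::map_dbl(cohort, ~ .x$meta$weight_kg))
  blood <- s$idif_tac
  mid <- frame_mid(blood)
  g <- truncate_to_dtw(blood, c(10, 55))
  gm <- frame_mid(g)
  hy <- hybrid_if_dtw(g[gm < 10, ], g[gm > 55, ], pb, 10, 55)
  eps <- 1e-7
  for (tj in c(10, 55)) {
    expect_lt(abs(if_value(hy$input_fn, tj - eps) -
                    if_value(hy$input_fn, tj + eps)), 1e-4)
  }
  expect_true(all(hy$input_fn$value >= 0))
})

test_that("static PB scaling recovers alpha as the late AUC ratio", {
  sched <- frame_schedule_66()
  inp <- fix_input()
  blood <- frame_average(inp, sched)
  pb <- input_function(frame_mid(blood), blood$value)
  sc <- scale_pbif_static(blood, pb)
  expect_equal(sc$params$alpha, 1, tolerance = 1e-10)
  pb_half <- input_function(pb$time, pb$value / 2)
  sc2 <- scale_pbif_static(blood, pb_half)
  expect_equal(sc2$params$alpha, 2, tolerance = 1e-10)
  # before the window the curve is alpha * pb
  expect_equal(if_value(sc2$input_fn, 20), 2 * if_value(pb_half, 20),
               tolerance = 1e-9)
  expect_error(scale_pbif_static(blood, input_function(c(50, 60), c(0, 0))),
               "zero")
})

test_that("delay search recovers simulated input delays", {
  inp <- fix_input()
  sched <- fix_schedule()
  p <- fix_params("cortex")
  # no delay: best shift 0
  tt0 <- model_tac(inp, p, sched, sampling = "midpoint")
  d0 <- correct_delay(tt0, inp, range_s = 20, step_s = 10,
                      sampling = "midpoint", n_starts = 1)
  expect_equal(d0$delay_s, 0)
  # tissue generated from a +20 s delayed input
  tt20 <- model_tac(if_shift(inp, 20), p, sched, sampling = "midpoint")
  d20 <- correct_delay(tt20, inp, range_s = 30, step_s = 10,
                       sampling = "midpoint", n_starts = 1)
  expect_equal(d20$delay_s, 20)
  # grid objective is minimised at the returned shift
  expect_equal(min(d20$grid$weighted_rss),
               d20$grid$weighted_rss[d20$grid$shift_s == 20])
  expect_error(correct_delay(tt0, inp, range_s = 10, step_s = 3), "divide")
})
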