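test_that("Lawson-Hanson NNLS matches unconstrained least squares when it is feasible", {
  set.seed(41)
  for (i in 1:20) {
    A <- matrix(rnorm(60), 20, 3)
    x_true <- runif(3, 0.5, 2)          # interior solution
    b <- A %*% x_true
    got <- nnls_lh(A, b)
    expect_equal(got$x, as.numeric(qr.solve(A, b)), tolerance = 1e-8)
  }
})

test_that("NNLS clamps active coordinates at zero and never goes negative", {
  set.seed(42)
  for (i in 1:20) {
    A <- matrix(rnorm(80), 20, 4)
    b <- rnorm(20)
    got <- nnls_lh(A, b)
    expect_true(all(got$x >= 0))
    # KKT: gradient nonpositive on active set, ~zero on passive set
    grad <- as.numeric(crossprod(A, b - A %*% got$x))
    expect_true(all(grad[got$x == 0] <= 1e-6))
    expect_true(all(abs(grad[got$x > 0]) <= 1e-6))
  }
})

test_that("linearized basis integrals match closed forms for constant input", {
  sched <- frame_schedule(list(c(4, 600)))      # 10-min frames
  c0 <- 3
  inp <- input_function(c(0, 60), c(c0, c0))
  tt <- tac(sched, rep(0, 4))
  b <- linearized_basis(tt, inp)
  mid <- frame_mid(sched)
  expect_equal(b$cp, rep(c0, 4))
  expect_equal(b$icp, c0 * mid, tolerance = 1e-12)
  expect_equal(b$iicp, c0 * mid^2 / 2, tolerance = 1e-12)
  expect_equal(b$ict, rep(0, 4))
  expect_equal(b$iict, rep(0, 4))
})

test_that("voxel NNLS back-mapping recovers micro-parameters and matches NLLS", {
  inp <- fix_input()
  sched <- fix_schedule()
  for (tis in c("cortex", "muscle", "tumor")) {
    p <- fix_params(tis)
    tt <- model_tac(inp, p, sched, sampling = "midpoint")
    res <- nnls_2t3k_voxel(linearized_basis(tt, inp), tt$value)
    expect_equal(res$flag, "ok")
    for (nm in c("K1", "k2", "k3", "Vb", "Ki")) {
      expect_lt(abs(res$params[[nm]] - p[[nm]]) / p[[nm]], 0.02)
    }
    # agreement with the nonlinear fit on the same data
    nlls <- fit_2t3k(tt, inp, sampling = "midpoint", n_starts = 2)
    expect_lt(abs(res$params$Ki - nlls$params$Ki) / nlls$params$Ki, 0.02)
  }
})

test_that("degenerate voxels are flagged, never thrown", {
  inp <- fix_input()
  sched <- fix_schedule()
  # blood-only voxel
  blood <- model_tac(inp, kinetic_params(0, 0, 0, 0.05), sched,
                     sampling = "midpoint")
  res <- nnls_2t3k_voxel(linearized_basis(blood, inp), blood$value)
  expect_equal(res$coeffs$P1, 0.05, tolerance = 0.01)
  expect_lt(res$params$K1, 0.01)
  # zero voxel
  zero <- tac(sched, rep(0, 66))
  res0 <- nnls_2t3k_voxel(linearized_basis(zero, inp), zero$value)
  expect_equal(res0$flag, "zero")
  expect_equal(res0$params$Ki, 0)
})

test_that("parametric maps recover a noise-free phantom and are order-independent", {
  ph <- simulate_phantom(13, dims = c(10, 10, 2), noise = noise_model(0),
                         regions = tibble::tribble(
                           ~tissue,  ~x0, ~x1, ~y0, ~y1, ~z0, ~z1,
                           "blood",    1,   3,   1,   3,   1,   2,
                           "cortex",   5,   7,   1,   3,   1,   2,
                           "tumor",    5,   7,   5,   7,   1,   2))
  maps <- fit_parametric_images(ph$image, ph$input_fn, method = "nnls")
  for (tis in c("cortex", "tumor")) {
    truth <- ph$truth[ph$truth$tissue == tis, ]
    med <- median(maps$maps$Ki[ph$masks[[tis]]])
    expect_lt(abs(med - truth$Ki) / truth$Ki, 0.03)
    # uniform region: spatially constant map
    expect_lt(diff(range(maps$maps$Ki[ph$masks[[tis]]])), 1e-9)
  }
  # Ki map equals K1 k3/(k2+k3) voxel-wise
  theta <- maps$maps$k2 + maps$maps$k3
  ki_re <- ifelse(theta > 0, maps$maps$K1 * maps$maps$k3 / theta, 0)
  expect_equal(as.numeric(maps$maps$Ki), as.numeric(ki_re), tolerance = 1e-12)
  # restricting to a mask reproduces the same values inside it
  sub <- fit_parametric_images(ph$image, ph$input_fn, method = "nnls",
                               mask = ph$masks$tumor)
  expect_equal(sub$maps$Ki[ph$masks$tumor], maps$maps$Ki[ph$masks$tumor])
})

test_that("Patlak Ki maps are noisier than full-data NNLS Ki maps", {
  ph <- simulate_phantom(17, dims = c(8, 8, 2), noise = noise_model(0.3),
                         regions = tibble::tribble(
                           ~tissue,  ~x0, ~x1, ~y0, ~y1, ~z0, ~z1,
                           "blood",    1,   3,   1,   3,   1,   2,
                           "muscle",   5,   8,   1,   4,   1,   2,
                           "tumor",    5,   8,   6,   8,   1,   2))
  inp <- ph$input_fn
  nnls_maps <- fit_parametric_images(ph$image, inp, method = "nnls",
                                     mask = ph$masks$muscle)
  pat_maps <- fit_parametric_images(ph$image, inp, method = "patlak",
                                    mask = ph$masks$muscle)
  cov_nnls <- roi_cov(nnls_maps$maps$Ki, ph$masks$muscle)
  cov_pat <- roi_cov(pat_maps$maps$Ki, ph$masks$muscle)
  expect_gt(cov_pat, cov_nnls)
})

test_that("ROI CoV follows its definition and decreases with noise", {
  vol <- array(0, c(2, 2, 1))
  vol[1, 1, 1] <- 1; vol[2, 1, 1] <- 3
  mask <- array(FALSE, c(2, 2, 1)); mask[1:2, 1, 1] <- TRUE
  expect_equal(roi_cov(vol, mask), 0.5)                       # population SD
  expect_equal(roi_cov(vol, mask, sd_type = "sample"),
               sd(c(1, 3)) / 2)
  expect_equal(roi_cov(array(5, c(2, 2, 1)), mask), 0)
  expect_error(roi_cov(array(0, c(2, 2, 1)), mask), "zero")
  # monotone in noise scale
  set.seed(55)
  base <- array(10, c(4, 4, 2)); m <- array(TRUE, c(4, 4, 2))
  lo <- base + rnorm(32, 0, 0.5); hi <- base + rnorm(32, 0, 2)
  expect_lt(roi_cov(lo, m), roi_cov(hi, m))
})
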