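test_that("net influx rate follows Ki = K1 k3 / (k2 + k3) with its limits", {
  expect_equal(net_influx_rate(0.1, 0.1, 0.1), 0.05)
  expect_equal(net_influx_rate(0.1, 0.1, 0), 0)      # no trapping
  expect_equal(net_influx_rate(0.1, 0, 0.1), 0.1)    # full trapping: Ki = K1
  expect_equal(net_influx_rate(0.1, 0, 0), 0)        # degenerate denominator
  expect_error(net_influx_rate(-0.1, 0.1, 0.1), ">= 0")
})

test_that("Ki <= K1 across random nonnegative rate sets", {
  set.seed(11)
  for (i in 1:200) {
    K1 <- runif(1, 0, 2); k2 <- runif(1, 0, 2); k3 <- runif(1, 0, 2)
    ki <- net_influx_rate(K1, k2, k3)
    expect_lte(ki, K1 + 1e-12)
    expect_gte(ki, 0)
  }
})

test_that("degenerate parameter sets reduce the forward model to closed forms", {
  inp <- fix_toy_input()
  t <- seq(0, 30, by = 0.5)
  # pure blood: C = Vb * Cp
  p <- kinetic_params(0, 0, 0, 0.05)
  expect_equal(solve_2t3k(inp, p, t), 0.05 * if_value(inp, t), tolerance = 1e-12)
  # theta = 0: C = K1 * int Cp
  p2 <- kinetic_params(0.1, 0, 0, 0)
  expect_equal(solve_2t3k(inp, p2, t), 0.1 * if_cumint(inp, t), tolerance = 1e-12)
})

test_that("forward model matches a stiff ODE integration of the compartment system", {
  skip_if_not_installed("deSolve")
  inp <- fix_input()
  p <- kinetic_params(0.1, 0.12, 0.06, 0.05)
  t <- seq(0, 60, by = 0.5)
  mine <- solve_2t3k(inp, p, t)
  cpf <- function(t) if_value(inp, t)
  rhs <- function(t, s, parms) {
    cp <- cpf(t)
    list(c(parms["K1"] * cp - (parms["k2"] + parms["k3"]) * s[1],
           parms["k3"] * s[1]))
  }
  sol <- deSolve::ode(c(0, 0), t, rhs, c(K1 = p$K1, k2 = p$k2, k3 = p$k3),
                      rtol = 1e-10, atol = 1e-12, hmax = 0.02)
  ref <- p$Vb * cpf(t) + (1 - p$Vb) * (sol[, 2] + sol[, 3])
  expect_lt(max(abs(mine[-1] - ref[-1]) / pmax(ref[-1], 1e-6)), 1e-3)
})

test_that("forward model is linear in the input and monotone when k2 = 0", {
  inp <- fix_input()
  p <- kinetic_params(0.2, 0.3, 0.1, 0.04)
  t <- seq(0, 60, by = 1)
  y1 <- solve_2t3k(inp, p, t)
  inp3 <- input_function(inp$time, 3 * inp$value)
  expect_equal(solve_2t3k(inp3, p, t), 3 * y1, tolerance = 1e-10)
  # irreversible uptake without efflux can only accumulate
  pm <- kinetic_params(0.2, 0, 0.1, 0.0)
  ym <- solve_2t3k(inp, pm, seq(0, 60, by = 0.25))
  expect_true(all(diff(ym) >= -1e-10))
})

test_that("frame averaging reproduces analytic means and refined quadrature", {
  sched <- frame_schedule(list(c(1, 60), c(2, 30)))
  # constant curve
  expect_equal(frame_average(function(t) rep(3, length(t)), sched)$value,
               rep(3, 3))
  # linear curve a*t over [0,1]: mean a/2
  lin <- frame_average(function(t) 2 * t, sched)
  expect_equal(lin$value[1], 1)
  # 2T3k curve: nsub convergence
  inp <- fix_input()
  p <- fix_params("cortex")
  f <- function(t) solve_2t3k(inp, p, t)
  coarse <- frame_average(f, frame_schedule_66(), nsub = 6)
  fine <- frame_average(f, frame_schedule_66(), nsub = 60)
  expect_lt(max(abs(coarse$value[-1] - fine$value[-1]) /
                  pmax(fine$value[-1], 1e-6)), 5e-3)
})

test_that("2T3k fitting recovers generating parameters on noise-free data", {
  inp <- fix_input()
  sched <- fix_schedule()
  p <- kinetic_params(0.1, 0.12, 0.06, 0.05)
  tt <- model_tac(inp, p, sched)
  fit <- fit_2t3k(tt, inp)
  expect_true(fit$converged)
  for (nm in c("K1", "k2", "k3", "Vb")) {
    expect_lt(abs(fit$params[[nm]] - p[[nm]]) / p[[nm]], 0.01)
  }
  expect_lt(abs(fit$params$Ki - p$Ki) / p$Ki, 0.01)
  # returned objective beats every default start
  sched_df <- tt[c("start", "end")]
  w <- fit$weights
  for (s in seq_len(4)) {
    st <- dtwpet:::default_starts_2t3k()[s, ]
    m <- model_tac(inp, kinetic_params(st[1], st[2], st[3], st[4]), sched)
    expect_lte(fit$weighted_rss, sum(w * (tt$value - m$value)^2) + 1e-12)
  }
})

test_that("blood-only tissue fits to K1 ~ 0, Vb ~ the blood fraction", {
  inp <- fix_input()
  sched <- fix_schedule()
  tt <- model_tac(inp, kinetic_params(0, 0, 0, 0.05), sched)
  fit <- fit_2t3k(tt, inp)
  expect_lt(fit$params$K1, 1e-3)
  expect_equal(fit$params$Vb, 0.05, tolerance = 0.01)
})

test_that("all-zero TACs return flagged zero fits rather than errors", {
  inp <- fix_input()
  tt <- tac(fix_schedule(), rep(0, 66))
  fit <- fit_2t3k(tt, inp)
  expect_equal(fit$params$K1, 0)
  expect_equal(fit$flag, "zero_tac")
  expect_false(fit$converged)
})

test_that("noisy replicates recover Ki without bias beyond Monte-Carlo error", {
  inp <- fix_input()
  sched <- fix_schedule()
  p <- fix_params("cortex")
  clean <- model_tac(inp, p, sched, sampling = "midpoint")
  set.seed(99)
  n_rep <- 40
  kis <- replicate(n_rep, {
    noisy <- tac(sched, dtwpet:::add_frame_noise(clean$value, sched,
                                                 noise_model(0.15)))
    fit_2t3k(noisy, inp, sampling = "midpoint", n_starts = 2)$params$Ki
  })
  se <- sd(kis) / sqrt(n_rep)
  expect_lt(abs(mean(kis) - p$Ki), 3 * se + 0.02 * p$Ki)
})

test_that("tidy and glance expose the fit in broom shape", {
  inp <- fix_input()
  tt <- fix_tac("muscle")
  fit <- fit_2t3k(tt, inp, n_starts = 2)
  td <- tidy(fit)
  expect_equal(td$term, c("K1", "k2", "k3", "Vb", "Ki"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$weighted_rss >= 0)
})
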