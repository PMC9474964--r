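#' Kinetic parameters of the irreversible two-tissue model
#'
#' The 2T3k model has free parameters K1 (plasma-to-tissue transport,
#' mL/g/min), k2 (efflux, min^-1), k3 (phosphorylation / trapping, min^-1)
#' and Vb (fractional blood volume); k4 is fixed at 0 (irreversible
#' trapping). The derived macro-parameter is the net influx rate
#' Ki = K1 k3 / (k2 + k3).
#'
#' @param K1,k2,k3,Vb Nonnegative rates; `Vb` must lie in \[0, 1\].
#' @return A one-row `kinetic_params` tibble with a `Ki` column.
#' @export
kinetic_params <- function(K1, k2, k3, Vb) {
  if (any(c(K1, k2, k3) < 0)) stop("rate constants must be >= 0")
  if (Vb < 0 || Vb > 1) stop("Vb must be in [0, 1]")
  structure(
    tibble::tibble(K1 = K1, k2 = k2, k3 = k3, Vb = Vb,
                   Ki = net_influx_rate(K1, k2, k3)),
    class = c("kinetic_params", class(tibble::tibble())))
}

#' Net influx rate Ki
#'
#' Ki = K1 k3 / (k2 + k3), with Ki := 0 when k2 + k3 = 0. Ki is the
#' macro-parameter surrogate of the glucose metabolic influx; 0 <= Ki <= K1
#' always, with Ki = K1 at full trapping (k2 = 0).
#'
#' @param K1,k2,k3 Nonnegative rates, or a `kinetic_params` row as the first
#'   argument.
#' @return Ki in mL/g/min.
#' @export
net_influx_rate <- function(K1, k2, k3) {
  if (is.data.frame(K1)) {
    p <- K1; K1 <- p$K1; k2 <- p$k2; k3 <- p$k3
  }
  if (any(c(K1, k2, k3) < 0)) stop("rate constants must be >= 0")
  theta <- k2 + k3
  ifelse(theta == 0, 0, K1 * k3 / theta)
}

#' Forward 2T3k tissue curve
#'
#' Solves the irreversible two-tissue compartment model driven by a
#' piecewise-linear input function and returns the measurable signal
#' C_PET(t) = Vb Cp(t) + (1 - Vb) (C1(t) + C2(t)). With theta = k2 + k3 the
#' solution is analytic: C1 + C2 = Ki * int_0^t Cp + (K1 k2 / theta) *
#' (exp(-theta t) conv Cp)(t), computed exactly per linear segment of Cp
#' (no quadrature-grid error); theta = 0 gives K1 * int_0^t Cp.
#'
#' @param input_fn A `pet_if`.
#' @param params A `kinetic_params` row (or list with K1, k2, k3, Vb).
#' @param t Evaluation times, minutes.
#' @return Numeric vector of tissue activity concentrations (kBq/mL) at `t`.
#' @export
solve_2t3k <- function(input_fn, params, t) {
  K1 <- params$K1; k2 <- params$k2; k3 <- params$k3; Vb <- params$Vb
  if (any(c(K1, k2, k3) < 0)) stop("rate constants must be >= 0")
  theta <- k2 + k3
  icp <- if_cumint(input_fn, t)
  if (theta == 0) {
    extra <- K1 * icp
  } else {
    ki <- K1 * k3 / theta
    extra <- ki * icp + (K1 * k2 / theta) * conv_exp_pl(input_fn, theta, t)
  }
  Vb * if_value(input_fn, t) + (1 - Vb) * extra
}

#' Average a continuous curve over acquisition frames
#'
#' Each frame value is the time-average of the curve over \[start, end\],
#' computed by trapezoidal quadrature on `nsub` equal subintervals per frame.
#'
#' @param curve A function of time (minutes) returning concentrations, or a
#'   `pet_if` (evaluated piecewise-linearly).
#' @param schedule A `frame_schedule`.
#' @param nsub Subintervals per frame for the quadrature (default 6).
#' @return A `pet_tac` with the frame-averaged values.
#' @export
frame_average <- function(curve, schedule, nsub = 6) {
  validate_schedule(schedule)
  f <- if (inherits(curve, "pet_if")) function(t) if_value(curve, t) else curve
  vals <- vapply(seq_len(nrow(schedule)), function(i) {
    tt <- seq(schedule$start[i], schedule$end[i], length.out = nsub + 1)
    y <- f(tt)
    sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) /
      (schedule$end[i] - schedule$start[i])
  }, numeric(1))
  tac(schedule, vals)
}

# Precomputed fast evaluator: returns function(K1, k2, k3, Vb) -> per-frame
# model values. Builds one merged grid (input nodes + frame sample points),
# caches Cp and its running integral there, and reduces each call to a single
# exponential-convolution recursion plus a weighted sum per frame.
tissue_model_factory <- function(input_fn, schedule, sampling = c("average", "midpoint"),
                                 nsub = 6) {
  sampling <- match.arg(sampling)
  if (sampling == "midpoint") {
    pts <- lapply(seq_len(nrow(schedule)), function(i) frame_mid(schedule)[i])
  } else {
    pts <- lapply(seq_len(nrow(schedule)), function(i)
      seq(schedule$start[i], schedule$end[i], length.out = nsub + 1))
  }
  g <- if_nodes(input_fn)
  tt <- sort(unique(c(g$t, unlist(pts))))
  vv <- stats::approx(g$t, g$v, xout = tt, rule = 2)$y
  icp <- c(0, cumsum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2))
  d <- diff(tt)
  c0 <- utils::head(vv, -1)
  c1 <- diff(vv) / d
  ## per-frame row weights mapping grid values to the frame value
  n <- length(tt)
  W <- matrix(0, nrow(schedule), n)
  for (i in seq_len(nrow(schedule))) {
    idx <- match(round(pts[[i]], 12), round(tt, 12))
    if (sampling == "midpoint") {
      W[i, idx] <- 1
    } else {
      sub <- tt[idx]
      w <- numeric(length(idx))
      dsub <- diff(sub)
      w[-length(w)] <- w[-length(w)] + dsub / 2
      w[-1] <- w[-1] + dsub / 2
      W[i, idx] <- w / (schedule$end[i] - schedule$start[i])
    }
  }
  cp_frame <- as.numeric(W %*% vv)
  icp_frame <- as.numeric(W %*% icp)

  function(K1, k2, k3, Vb) {
    theta <- k2 + k3
    if (theta == 0) {
      extra <- K1 * icp_frame
    } else {
      E <- exp(-theta * d)
      A <- -expm1(-theta * d) / theta
      B <- ifelse(theta * d < 1e-6, d^2 / 2 * (1 - theta * d / 3), (d - A) / theta)
      seg <- c0 * A + c1 * B
      y <- numeric(n)
      for (k in seq_len(n - 1)) y[k + 1] <- y[k] * E[k] + seg[k]
      conv_frame <- as.numeric(W %*% y)
      extra <- (K1 * k3 / theta) * icp_frame + (K1 * k2 / theta) * conv_frame
    }
    Vb * cp_frame + (1 - Vb) * extra
  }
}

#' Fit the 2T3k model to a time-activity curve
#'
#' Estimates (K1, k2, k3, Vb) by bounded multi-start minimisation of the
#' weighted residual sum of squares
#' chi^2 = sum_i w_i (C_PET(t_i) - C_model(t_i))^2 over the frames. The
#' default weights are frame durations (normalised to sum to 1), which
#' approximate count-variance weighting; uniform weights or a custom numeric
#' vector may be supplied. Model frame values are frame averages by default;
#' `sampling = "midpoint"` samples the model at frame midpoints, which is
#' faster and is the mode intended for large loops.
#'
#' @param tac A `pet_tac`.
#' @param input_fn A `pet_if` covering the TAC time span.
#' @param weights `"duration"` (default), `"uniform"`, or a positive numeric
#'   vector with one entry per frame.
#' @param init Optional `kinetic_params` start added to the multi-start set.
#' @param lower,upper Box bounds on (K1, k2, k3, Vb); defaults span the
#'   physiologic envelope K1, k2, k3 in \[0, 5\], Vb in \[0, 1\].
#' @param n_starts Number of multi-start points (default 4).
#' @param sampling `"average"` or `"midpoint"` frame convention.
#' @param delay_s Input-function time shift in seconds applied before
#'   fitting (see [correct_delay()]).
#' @return A `fit_2t3k` object: list with `params` (a `kinetic_params`
#'   row), `weighted_rss`, `weights`, `delay_s`, `converged`, `fitted`
#'   (a `pet_tac` on the same schedule), and the data.
#' @export
fit_2t3k <- function(tac, input_fn, weights = c("duration", "uniform"),
                     init = NULL, lower = c(0, 0, 0, 0), upper = c(5, 5, 5, 1),
                     n_starts = 4, sampling = c("average", "midpoint"),
                     delay_s = 0) {
  sampling <- match.arg(sampling)
  w <- fit_weights(tac, weights)
  if (delay_s != 0) input_fn <- if_shift(input_fn, delay_s)

  schedule <- tac[c("start", "end")]
  if (all(tac$value == 0)) {
    params <- kinetic_params(0, 0, 0, 0)
    return(new_fit_2t3k(params, 0, w, delay_s, converged = FALSE,
                        flag = "zero_tac",
                        fitted = tac(schedule, rep(0, nrow(tac))), data = tac))
  }

  model <- tissue_model_factory(input_fn, schedule, sampling)
  obj <- function(p) {
    r <- tac$value - model(p[1], p[2], p[3], p[4])
    sum(w * r^2)
  }
  starts <- default_starts_2t3k()[seq_len(max(1, min(n_starts, 4))), , drop = FALSE]
  ## the linearized-NNLS estimate is an excellent start on clean data and a
  ## harmless extra one on noisy data
  lin_start <- tryCatch({
    lin <- nnls_2t3k_voxel(linearized_basis(tac, input_fn), tac$value)
    as.numeric(lin$params[1, c("K1", "k2", "k3", "Vb")])
  }, error = function(e) NULL)
  if (!is.null(lin_start)) starts <- rbind(lin_start, starts)
  if (!is.null(init)) {
    starts <- rbind(as.numeric(c(init$K1, init$k2, init$k3, init$Vb)), starts)
  }
  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(starts[s, ], lower), upper)
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    params <- kinetic_params(0, 0, 0, 0)
    return(new_fit_2t3k(params, Inf, w, delay_s, converged = FALSE,
                        flag = "failed",
                        fitted = tac(schedule, rep(0, nrow(tac))), data = tac))
  }
  p <- best$par
  params <- kinetic_params(p[1], p[2], p[3], p[4])
  fitted_vals <- model(p[1], p[2], p[3], p[4])
  new_fit_2t3k(params, best$value, w, delay_s, converged = any_conv,
               flag = if (any_conv) "ok" else "no_convergence",
               fitted = tac(schedule, pmax(fitted_vals, 0)), data = tac)
}

fit_weights <- function(tac, weights) {
  if (is.numeric(weights)) {
    if (length(weights) != nrow(tac) || any(weights <= 0)) {
      stop("numeric weights must be positive, one per frame")
    }
    w <- weights
  } else {
    weights <- match.arg(weights, c("duration", "uniform"))
    w <- if (weights == "duration") frame_dur(tac) else rep(1, nrow(tac))
  }
  w / sum(w)
}

default_starts_2t3k <- function() {
  rbind(c(0.10, 0.10, 0.05, 0.05),
        c(0.50, 0.50, 0.10, 0.10),
        c(0.05, 0.30, 0.01, 0.03),
        c(0.30, 0.05, 0.20, 0.10))
}

new_fit_2t3k <- function(params, wrss, weights, delay_s, converged, flag,
                         fitted, data) {
  structure(list(params = params, weighted_rss = wrss, weights = weights,
                 delay_s = delay_s, converged = converged, flag = flag,
                 fitted = fitted, data = data),
            class = "fit_2t3k")
}

#' @export
print.fit_2t3k <- function(x, ...) {
  cat("2T3k fit (", x$flag, ")\n", sep = "")
  cat(sprintf("  K1 = %.4f mL/g/min, k2 = %.4f, k3 = %.4f min^-1, Vb = %.4f\n",
              x$params$K1, x$params$k2, x$params$k3, x$params$Vb))
  cat(sprintf("  Ki = %.5f mL/g/min, weighted RSS = %.4g, delay = %g s\n",
              x$params$Ki, x$weighted_rss, x$delay_s))
  invisible(x)
}

#' Tidy a 2T3k fit
#'
#' @param x A `fit_2t3k`.
#' @param ... Unused.
#' @return `tidy()`: a tibble of parameter estimates (K1, k2, k3, Vb, Ki);
#'   `glance()`: a one-row tibble of fit summaries.
#' @export
tidy.fit_2t3k <- function(x, ...) {
  tibble::tibble(
    term = c("K1", "k2", "k3", "Vb", "Ki"),
    estimate = as.numeric(x$params[1, c("K1", "k2", "k3", "Vb", "Ki")]),
    unit = c("mL/g/min", "1/min", "1/min", "fraction", "mL/g/min"))
}

#' @rdname tidy.fit_2t3k
#' @export
glance.fit_2t3k <- function(x, ...) {
  tibble::tibble(weighted_rss = x$weighted_rss, converged = x$converged,
                 flag = x$flag, delay_s = x$delay_s, n_frames = nrow(x$data),
                 Ki = x$params$Ki)
}
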