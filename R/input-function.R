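#' Continuous-time input functions
#'
#' An input function is the blood (here whole-blood, used as plasma) activity
#' concentration over time, stored as a tibble of grid nodes `time` (minutes)
#' and `value` (kBq/mL). Between nodes the curve is piecewise linear;
#' integrals are exact trapezoids of that piecewise-linear curve, so they are
#' nonnegative and monotone in the upper limit whenever the values are
#' nonnegative. Before the first node the curve is taken as rising linearly
#' from zero at t = 0 (and zero for t < 0); after the last node it is held
#' constant.
#'
#' @param time Strictly increasing numeric grid, minutes.
#' @param value Activity concentration at each node, kBq/mL.
#' @return A `pet_if` tibble with columns `time`, `value`.
#' @export
input_function <- function(time, value) {
  if (length(time) != length(value)) stop("time and value must match")
  if (length(time) < 2) stop("need at least two grid nodes")
  if (is.unsorted(time, strictly = TRUE)) stop("time grid must be strictly increasing")
  if (any(time < 0)) stop("times must be >= 0")
  if (any(!is.finite(value))) stop("values must be finite")
  if (any(value < -1e-9)) stop("input function values must be >= 0")
  structure(tibble::tibble(time = as.numeric(time), value = pmax(value, 0)),
            class = c("pet_if", class(tibble::tibble())))
}

# Internal node grid with the implicit (0, 0) anchor prepended when the
# stored grid starts after t = 0.
if_nodes <- function(inp) {
  t <- inp$time; v <- inp$value
  if (t[1] > 0) {
    t <- c(0, t); v <- c(0, v)
  }
  list(t = t, v = v)
}

#' Evaluate, integrate and shift input functions
#'
#' `if_value()` evaluates the piecewise-linear curve at `t` (held constant
#' past the last node). `if_auc()` integrates it exactly between `lower` and
#' `upper`. `if_cumint()` returns the running integral from 0 to each `t`.
#' `if_shift()` shifts the curve in time by `delay_s` seconds (positive =
#' tracer arrives later), zero-padding before t = 0.
#'
#' @param inp A `pet_if`.
#' @param t,lower,upper Times in minutes.
#' @param delay_s Shift in seconds.
#' @return Numeric vector (`if_value`, `if_cumint`), a scalar (`if_auc`), or
#'   a shifted `pet_if` (`if_shift`).
#' @export
if_value <- function(inp, t) {
  g <- if_nodes(inp)
  out <- stats::approx(g$t, g$v, xout = pmin(t, g$t[length(g$t)]), rule = 2)$y
  out[t < 0] <- 0
  out
}

#' @rdname if_value
#' @export
if_cumint <- function(inp, t) {
  g <- if_nodes(inp)
  tt <- sort(unique(c(g$t, pmax(t, 0))))
  vv <- stats::approx(g$t, g$v, xout = tt, rule = 2)$y
  ci <- c(0, cumsum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2))
  out <- stats::approx(tt, ci, xout = pmax(t, 0), rule = 2)$y
  out[t <= 0] <- 0
  out
}

#' @rdname if_value
#' @export
if_auc <- function(inp, lower, upper) {
  if (upper < lower) stop("upper must be >= lower")
  if_cumint(inp, upper) - if_cumint(inp, lower)
}

#' @rdname if_value
#' @export
if_shift <- function(inp, delay_s) {
  d <- delay_s / 60
  g <- if_nodes(inp)
  t <- g$t + d
  v <- g$v
  if (d > 0) {
    t <- c(0, t); v <- c(0, v)          # zero activity before arrival
  } else if (d < 0) {
    keep <- t > 0
    v0 <- stats::approx(t, v, xout = 0, rule = 2)$y
    t <- c(0, t[keep]); v <- c(v0, v[keep])
  }
  input_function(t, v)
}

# Exact causal convolution (exp(-theta * t) * Cp)(t) of the piecewise-linear
# input with an exponential kernel, evaluated at `t_query` (sorted unique
# internally). Closed form per linear segment; theta = 0 reduces to the
# running integral.
conv_exp_pl <- function(inp, theta, t_query) {
  g <- if_nodes(inp)
  tq <- pmax(t_query, 0)
  tt <- sort(unique(c(g$t, tq)))
  vv <- stats::approx(g$t, g$v, xout = tt, rule = 2)$y
  n <- length(tt)
  y <- numeric(n)
  if (theta < 0) stop("theta must be >= 0")
  for (k in seq_len(n - 1)) {
    d <- tt[k + 1] - tt[k]
    c0 <- vv[k]
    c1 <- (vv[k + 1] - vv[k]) / d
    if (theta == 0) {
      y[k + 1] <- y[k] + c0 * d + c1 * d^2 / 2
    } else {
      E <- exp(-theta * d)
      A <- -expm1(-theta * d) / theta
      B <- if (theta * d < 1e-6) d^2 / 2 * (1 - theta * d / 3) else (d - A) / theta
      y[k + 1] <- y[k] * E + c0 * A + c1 * B
    }
  }
  y[match(round(pmax(t_query, 0), 12), round(tt, 12))]
}
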