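#' Standardized uptake value
#'
#' SUV = C_PET(T) / (A / W): the window-mean activity concentration divided
#' by injected activity per body mass, using the 1 g ~ 1 mL tissue
#' convention so SUV is dimensionless. With concentrations in kBq/mL, dose
#' in MBq and weight in kg this reduces to C * W / A.
#'
#' @param tac A `pet_tac`.
#' @param dose_MBq Total injected activity, MBq.
#' @param weight_kg Body weight, kg.
#' @param window Static window in minutes (default `c(50, 60)`); the
#'   concentration is the duration-weighted mean over frames whose midpoint
#'   lies inside it.
#' @return A one-row `static_measure` tibble (`kind`, `value`,
#'   `window_lo`, `window_hi`, `dose_MBq`, `weight_kg`).
#' @export
suv <- function(tac, dose_MBq, weight_kg, window = c(50, 60)) {
  if (dose_MBq <= 0 || weight_kg <= 0) stop("dose and weight must be > 0")
  conc <- window_mean(tac, window)
  tibble::tibble(kind = "SUV", value = conc * weight_kg / dose_MBq,
                 window_lo = window[1], window_hi = window[2],
                 dose_MBq = dose_MBq, weight_kg = weight_kg)
}

#' Fractional uptake ratio
#'
#' FUR = C_PET(T) / int_0^T C_p(t) dt: the late-window mean concentration
#' normalised by the integral of the input function from injection to T.
#' T defaults to the window midpoint (55 min for the 50-60 min window);
#' `t_ref = "end"` uses the window end instead. FUR is a single-static-scan
#' surrogate of Ki.
#'
#' @param tac A `pet_tac`.
#' @param input_fn A `pet_if` covering \[0, T\].
#' @param window Static window, minutes (default `c(50, 60)`).
#' @param t_ref `"mid"` (default) or `"end"` of the window for the integral
#'   upper limit.
#' @return A one-row `static_measure` tibble with `value` in mL/g/min
#'   equivalents.
#' @export
fur <- function(tac, input_fn, window = c(50, 60), t_ref = c("mid", "end")) {
  t_ref <- match.arg(t_ref)
  T_ <- if (t_ref == "mid") mean(window) else window[2]
  denom <- if_cumint(input_fn, T_)
  if (denom <= 0) stop("input-function integral is zero")
  conc <- window_mean(tac, window)
  tibble::tibble(kind = "FUR", value = conc / denom,
                 window_lo = window[1], window_hi = window[2],
                 t_ref_min = T_)
}

window_mean <- function(tac, window) {
  mid <- frame_mid(tac)
  sel <- mid >= window[1] & mid <= window[2]
  if (!any(sel)) stop("no frames inside the window")
  sum(tac$value[sel] * frame_dur(tac)[sel]) / sum(frame_dur(tac)[sel])
}

#' Patlak graphical analysis
#'
#' For an irreversible tracer, beyond the equilibrium time t* the plot of
#' y = C_PET(T)/C_p(T) against x = int_0^T C_p / C_p(T) becomes linear with
#' slope Ki and intercept `int`. Ordinary least squares is applied to the
#' frames whose midpoints are >= t* (30 min by default).
#'
#' @param tac A `pet_tac`.
#' @param input_fn A `pet_if`.
#' @param t_star Equilibrium time, minutes (default 30).
#' @return A `patlak_fit`: list with `ki`, `intercept`, `r_squared`,
#'   `t_star`, `n_points`, and `points` (tibble of x, y, t).
#' @export
patlak <- function(tac, input_fn, t_star = 30) {
  mid <- frame_mid(tac)
  sel <- mid >= t_star
  if (sum(sel) < 2) stop("need at least 2 frames beyond t*")
  cp <- if_value(input_fn, mid[sel])
  if (any(cp <= 0)) stop("input function must be positive at the used frames")
  x <- if_cumint(input_fn, mid[sel]) / cp
  y <- tac$value[sel] / cp
  if (stats::sd(x) == 0) stop("degenerate Patlak design (constant x)")
  fit <- stats::lm(y ~ x)
  structure(list(ki = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 t_star = t_star, n_points = sum(sel),
                 points = tibble::tibble(t = mid[sel], x = x, y = y),
                 lm = fit),
            class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("Patlak analysis (t* = %g min, %d frames): Ki = %.5f mL/g/min, intercept = %.4f, R^2 = %.4f\n",
              x$t_star, x$n_points, x$ki, x$intercept, x$r_squared))
  invisible(x)
}

#' Tidy a Patlak fit
#'
#' @param x A `patlak_fit`.
#' @param ... Unused.
#' @return `tidy()`: tibble of slope (Ki) and intercept; `glance()`:
#'   one-row summary tibble.
#' @export
tidy.patlak_fit <- function(x, ...) {
  tibble::tibble(term = c("Ki", "intercept"),
                 estimate = c(x$ki, x$intercept),
                 unit = c("mL/g/min", "dimensionless"))
}

#' @rdname tidy.patlak_fit
#' @export
glance.patlak_fit <- function(x, ...) {
  tibble::tibble(Ki = x$ki, intercept = x$intercept,
                 r_squared = x$r_squared, t_star = x$t_star,
                 n_points = x$n_points)
}
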