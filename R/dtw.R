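#' Dual-time-window acquisition windows
#'
#' A DTW acquisition keeps an early dynamic scan on \[0, t1\] and a late scan
#' on \[t2, 60\]; the interval (t1, t2) is not acquired. The configurations
#' studied are (10, 55), (10, 50) and (10, 40) minutes, written
#' DTW (10 + 5 min), (10 + 10 min) and (10 + 20 min).
#'
#' @param t1 End of the early scan, minutes.
#' @param t2 Start of the late scan, minutes.
#' @param end Scan end time (default 60 minutes).
#' @return A `dtw_windows` tibble row.
#' @export
dtw_windows <- function(t1, t2, end = 60) {
  if (!(t1 > 0 && t1 < t2 && t2 < end)) stop("need 0 < t1 < t2 < end")
  structure(tibble::tibble(t1 = t1, t2 = t2, end = end),
            class = c("dtw_windows", class(tibble::tibble())))
}

#' Truncate a full dynamic TAC to a dual-time-window acquisition
#'
#' Removes the frames whose midpoint falls strictly inside (t1, t2),
#' emulating the un-acquired gap; all other frames are kept unchanged.
#' Truncation is idempotent.
#'
#' @param tac A `pet_tac` spanning the full scan.
#' @param windows A `dtw_windows` (or `c(t1, t2)`).
#' @return The gapped `pet_tac`.
#' @export
truncate_to_dtw <- function(tac, windows) {
  w <- as_windows(windows)
  mid <- frame_mid(tac)
  keep <- !(mid > w$t1 & mid < w$t2)
  if (!any(keep)) stop("windows would remove every frame")
  new_tac(tac[keep, ])
}

as_windows <- function(windows) {
  if (inherits(windows, "dtw_windows")) return(windows)
  dtw_windows(windows[1], windows[2])
}

#' Evaluate the 3rd-degree rational TAC model
#'
#' C_E(t) = (p3 t + p5 t^2 + p7 t^3) / (1 + p4 t + p6 t^2 + p8 t^3), with
#' all coefficients nonnegative so the denominator is >= 1 on t >= 0 (no
#' poles) and C_E(0) = 0.
#'
#' @param params A `rational_params` tibble row (columns p3, p4, p5, p6,
#'   p7, p8).
#' @param t Times in minutes.
#' @return Fitted concentrations at `t`.
#' @export
rational3_eval <- function(params, t) {
  num <- params$p3 * t + params$p5 * t^2 + params$p7 * t^3
  den <- 1 + params$p4 * t + params$p6 * t^2 + params$p8 * t^3
  num / den
}

#' Fit the rational TAC-completion model to a gapped TAC
#'
#' Least-squares fit of the 3rd-degree rational function to the retained
#' frames (midpoint, value) with uniform weights. The numerator is linear in
#' (p3, p5, p7), so for any candidate denominator (p4, p6, p8) the optimal
#' nonnegative numerator is found by NNLS (variable projection); the
#' denominator is optimised by bounded multi-start minimisation. Because the
#' rational parametrisation is non-unique, the contract is curve agreement,
#' not parameter identity.
#'
#' @param gapped_tac A `pet_tac` with >= 8 retained frames.
#' @param weights `"uniform"` (default) or `"duration"`.
#' @param n_starts Multi-start points for the denominator search (default 8).
#' @param t_min Frames with midpoint before `t_min` minutes are excluded
#'   from the fit domain (default 5). The bolus-transit seconds cannot be
#'   represented by a pole-free cubic rational anchored at C_E(0) = 0 and
#'   would otherwise distort the gap interpolation, which lies entirely at
#'   later times; set 0 to fit every retained frame.
#' @return A `rational_fit`: list with `params` (`rational_params` row),
#'   `rss`, `converged`, and `fitted` values on the retained frames.
#' @export
fit_rational3 <- function(gapped_tac, weights = c("uniform", "duration"),
                          n_starts = 8, t_min = 5) {
  weights <- match.arg(weights)
  sel <- frame_mid(gapped_tac) >= t_min
  if (sum(sel) < 8) sel <- rep(TRUE, nrow(gapped_tac))
  fit_tac <- new_tac(gapped_tac[sel, ])
  tt <- frame_mid(fit_tac)
  yy <- fit_tac$value
  if (length(tt) < 8) stop("need at least 8 retained frames")
  w <- if (weights == "duration") frame_dur(fit_tac) else rep(1, length(tt))
  w <- w / sum(w)
  sw <- sqrt(w)

  numerator_nnls <- function(den_par) {
    den <- 1 + den_par[1] * tt + den_par[2] * tt^2 + den_par[3] * tt^3
    A <- cbind(tt, tt^2, tt^3) / den * sw
    fit <- nnls_lh(A, yy * sw)
    list(coef = fit$x, rss = sum((A %*% fit$x - yy * sw)^2))
  }
  obj <- function(den_par) numerator_nnls(den_par)$rss

  starts <- rbind(c(0.05, 0, 0), c(0.5, 0, 0), c(0, 1, 0.1),
                  c(2, 0.1, 0), c(0, 0.1, 0.01), c(0.1, 0.01, 0.001),
                  c(1, 0.5, 0.05), c(5, 1, 0.1))
  starts <- starts[seq_len(max(1, min(n_starts, nrow(starts)))), , drop = FALSE]
  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                   lower = c(0, 0, 0), upper = c(100, 10, 1),
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) best <- list(par = c(0, 0, 0), value = obj(c(0, 0, 0)))
  num <- numerator_nnls(best$par)
  params <- structure(
    tibble::tibble(p3 = num$coef[1], p4 = best$par[1], p5 = num$coef[2],
                   p6 = best$par[2], p7 = num$coef[3], p8 = best$par[3]),
    class = c("rational_params", class(tibble::tibble())))
  structure(list(params = params, rss = num$rss, converged = any_conv,
                 fitted = rational3_eval(params, frame_mid(gapped_tac)),
                 data = gapped_tac, t_min = t_min),
            class = "rational_fit")
}

#' @export
print.rational_fit <- function(x, ...) {
  cat("rational TAC completion fit; RSS =", format(x$rss, digits = 4),
      if (x$converged) "(converged)\n" else "(not converged)\n")
  invisible(x)
}

#' Complete a gapped TAC on the full schedule
#'
#' Frames present in the gapped TAC keep their measured values verbatim;
#' missing frames are filled with the rational model evaluated at their
#' midpoints.
#'
#' @param gapped_tac The gapped `pet_tac` (as fitted).
#' @param fit A `rational_fit` (or `rational_params`) from
#'   [fit_rational3()] on this TAC.
#' @param full_schedule The full `frame_schedule` to restore.
#' @return A `pet_tac` on `full_schedule`.
#' @export
complete_tac <- function(gapped_tac, fit, full_schedule) {
  params <- if (inherits(fit, "rational_fit")) fit$params else fit
  validate_schedule(full_schedule)
  key <- round(full_schedule$start, 9)
  gk <- round(gapped_tac$start, 9)
  if (!all(gk %in% key)) stop("gapped TAC frames must be a subset of the full schedule")
  idx <- match(key, gk)
  vals <- pmax(rational3_eval(params, frame_mid(full_schedule)), 0)
  vals[!is.na(idx)] <- gapped_tac$value[idx[!is.na(idx)]]
  tac(full_schedule, vals)
}

#' TAC estimation error over an interval
#'
#' Mean absolute percentage error of an estimated TAC against the measured
#' one over the frames whose midpoints lie in `interval`:
#' MAPE(%) = mean_i |C_E(t_i) - C_M(t_i)| / C_M(t_i) x 100.
#'
#' @param estimated,measured `pet_tac`s on the same schedule.
#' @param interval `c(lo, hi)` in minutes; frames with midpoint in
#'   (lo, hi) are scored. Defaults to the full span.
#' @return A list with `mape` (percent) and `per_frame` (tibble of
#'   midpoint, estimated, measured, abs. percent error).
#' @export
mape_tac <- function(estimated, measured, interval = NULL) {
  if (nrow(estimated) != nrow(measured) ||
      any(abs(estimated$start - measured$start) > 1e-9)) {
    stop("TACs must share a schedule")
  }
  mid <- frame_mid(measured)
  sel <- if (is.null(interval)) rep(TRUE, length(mid)) else
    mid > interval[1] & mid < interval[2]
  if (!any(sel)) stop("no frames in the interval")
  if (any(measured$value[sel] <= 0)) stop("measured values in the interval must be > 0")
  ape <- abs(estimated$value[sel] - measured$value[sel]) / measured$value[sel] * 100
  list(mape = mean(ape),
       per_frame = tibble::tibble(mid = mid[sel],
                                  estimated = estimated$value[sel],
                                  measured = measured$value[sel],
                                  ape_pct = ape))
}

#' Signed percentage bias of a parameter estimate
#'
#' Bias(%) = (k_ref - k_est) / k_ref x 100; positive values mean the
#' shortened protocol underestimates the reference.
#'
#' @param k_ref Reference value(s), nonzero.
#' @param k_est Estimate(s) from the shortened protocol.
#' @return Percent bias, vectorised.
#' @export
percent_bias <- function(k_ref, k_est) {
  if (any(k_ref == 0)) stop("reference values must be nonzero")
  (k_ref - k_est) / k_ref * 100
}
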