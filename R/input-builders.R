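#' Population-based image-derived input function
#'
#' Builds a PB-IDIF by normalising each subject's IDIF by injected dose per
#' body weight (the SUV convention), resampling all curves to a common time
#' grid, and averaging. The result is stored in normalised units
#' (kBq/mL per MBq/kg); downstream hybrid assembly rescales it to each
#' subject, so the normalisation constant cancels.
#'
#' @param tacs List of `pet_tac` IDIFs (one per subject).
#' @param doses_MBq,weights_kg Injected doses and body weights, one per
#'   subject.
#' @param grid Common time grid (minutes); defaults to the midpoints of the
#'   first subject's schedule.
#' @param normalise `"dose_per_weight"` (default) or `"auc"` (each curve
#'   divided by its 0-60 min area).
#' @return A `pet_if` with attribute `normalisation`.
#' @export
build_pb_idif <- function(tacs, doses_MBq, weights_kg, grid = NULL,
                          normalise = c("dose_per_weight", "auc")) {
  normalise <- match.arg(normalise)
  if (length(tacs) < 2) stop("need at least 2 subjects")
  if (length(doses_MBq) != length(tacs) || length(weights_kg) != length(tacs)) {
    stop("doses and weights must match the number of subjects")
  }
  if (is.null(grid)) grid <- frame_mid(tacs[[1]])
  curves <- purrr::map(seq_along(tacs), function(i) {
    v <- tac_interp(tacs[[i]], grid)
    if (normalise == "dose_per_weight") {
      v / (doses_MBq[i] / weights_kg[i])
    } else {
      auc <- sum(diff(grid) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
      v / auc
    }
  })
  avg <- purrr::reduce(curves, `+`) / length(curves)
  out <- input_function(grid, avg)
  attr(out, "normalisation") <- normalise
  out
}

#' Hybrid input function for the dual-time-window protocol
#'
#' Assembles a full 0-60 min input function from the measured IDIF segments
#' of the two scan windows and a population curve bridging the gap:
#' C_p(t) = C_image(t) on \[0, t1) and \[t2, 60\], and
#' mu * exp(-gamma (t - t1)) * C_p0(t) on the gap, where C_p0 is the
#' PB-IDIF. The scaling factors are chosen to make the curve continuous at
#' both junctions: mu = C_image / C_p0 at the last measured early sample,
#' and gamma the exponential rate that matches the same ratio at the first
#' late sample. When the population curve equals the subject's own IDIF the
#' bridge is the identity (mu = 1, gamma = 0), and a rescaled population
#' curve changes only mu.
#'
#' @param idif_early `pet_tac` covering \[0, t1\].
#' @param idif_late `pet_tac` covering \[t2, 60\].
#' @param pbidif `pet_if` population curve, positive at t1 and t2.
#' @param t1,t2 Window edges in minutes, 0 < t1 < t2 <= 60.
#' @param bridge_step Node spacing (minutes) used to sample the bridge.
#' @return A list with `input_fn` (`pet_if`) and `params` (tibble with
#'   `mu`, `gamma`, `t1`, `t2`).
#' @export
hybrid_if_dtw <- function(idif_early, idif_late, pbidif, t1, t2,
                          bridge_step = 0.25) {
  if (!(t1 < t2)) stop("t1 must be < t2")
  if (nrow(idif_early) == 0 || nrow(idif_late) == 0) {
    stop("both window segments must be nonempty")
  }
  early_mid <- frame_mid(idif_early)
  late_mid <- frame_mid(idif_late)
  ## junction anchors: the last measured sample of the early window and the
  ## first of the late window (the frame midpoints adjacent to t1 and t2)
  a <- max(early_mid[early_mid <= t1])
  b <- min(late_mid[late_mid >= t2])
  c_img_a <- idif_early$value[which.max(early_mid == a)]
  c_img_b <- idif_late$value[which.max(late_mid == b)]
  cp0_a <- if_value(pbidif, a)
  cp0_b <- if_value(pbidif, b)
  if (cp0_a <= 0 || cp0_b <= 0) stop("PB-IDIF must be positive at the junctions")
  if (c_img_b <= 0) stop("measured IDIF must be positive at the late junction")
  mu <- c_img_a / cp0_a
  gamma <- log(mu * cp0_b / c_img_b) / (b - a)

  keep_e <- early_mid < a
  keep_l <- late_mid > b
  tb <- seq(a, b, by = bridge_step)
  if (tb[length(tb)] < b) tb <- c(tb, b)
  bridge <- mu * exp(-gamma * (tb - a)) * if_value(pbidif, tb)
  tt <- c(early_mid[keep_e], tb, late_mid[keep_l])
  vv <- c(idif_early$value[keep_e], bridge, idif_late$value[keep_l])
  end_t <- max(60, max(tt))
  if (max(tt) < end_t) {
    tt <- c(tt, end_t); vv <- c(vv, vv[length(vv)])
  }
  list(input_fn = input_function(tt, pmax(vv, 0)),
       params = tibble::tibble(mu = mu, gamma = gamma, t1 = t1, t2 = t2))
}

#' Statically scaled population input function (for FUR / Patlak)
#'
#' When only a single late static scan (50-60 min by default) is available,
#' the population curve is scaled by the ratio of late areas under the
#' curve: alpha = AUC_image(window) / AUC_pb(window). The result is
#' alpha * C_p0(t) before the window and the measured data inside it.
#'
#' @param idif_late `pet_tac` covering the late window.
#' @param pbidif `pet_if` population curve.
#' @param window Late window in minutes (default `c(50, 60)`).
#' @return A list with `input_fn` (`pet_if`) and `params` (tibble with
#'   `alpha` and the window).
#' @export
scale_pbif_static <- function(idif_late, pbidif, window = c(50, 60)) {
  lo <- window[1]; hi <- window[2]
  mids <- frame_mid(idif_late)
  if (min(mids) > lo + 1e-9 && min(idif_late$start) > lo + 1e-9) {
    stop("late TAC must cover the scaling window")
  }
  tt <- sort(unique(c(lo, hi, mids[mids >= lo & mids <= hi])))
  vv <- tac_interp(idif_late, tt)
  auc_img <- sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
  auc_pb <- if_auc(pbidif, lo, hi)
  if (auc_pb <= 0) stop("PB-IDIF AUC over the window is zero")
  alpha <- auc_img / auc_pb

  g <- if_nodes(pbidif)
  pre <- g$t < lo
  late_keep <- mids > lo
  tt_out <- c(g$t[pre], lo, mids[late_keep])
  vv_out <- c(alpha * g$v[pre], alpha * if_value(pbidif, lo),
              idif_late$value[late_keep])
  o <- order(tt_out)
  dup <- duplicated(round(tt_out[o], 9))
  list(input_fn = input_function(tt_out[o][!dup], pmax(vv_out[o][!dup], 0)),
       params = tibble::tibble(alpha = alpha, window_lo = lo, window_hi = hi))
}

#' Delay correction by input-function shifting
#'
#' Grid-searches a time shift of the input function in
#' \[-range_s, +range_s\] seconds; for each shift the 2T3k model is fitted
#' to the TAC and the shift with the lowest weighted residual sum of squares
#' is selected.
#'
#' @param tac A `pet_tac`.
#' @param input_fn A `pet_if`.
#' @param range_s Half-width of the search range in seconds (default 60).
#' @param step_s Grid step in seconds (default 1); must divide the range.
#' @param ... Passed to [fit_2t3k()] (e.g. `n_starts`, `sampling`).
#' @return A `delay_result`: list with `delay_s`, `grid` (tibble of
#'   `shift_s`, `weighted_rss`), and `fit` (the best `fit_2t3k`).
#' @export
correct_delay <- function(tac, input_fn, range_s = 60, step_s = 1, ...) {
  if (range_s %% step_s != 0) stop("step must divide the range")
  shifts <- seq(-range_s, range_s, by = step_s)
  fits <- purrr::map(shifts, function(d) fit_2t3k(tac, input_fn, delay_s = d, ...))
  rss <- purrr::map_dbl(fits, "weighted_rss")
  best <- which.min(rss)
  structure(list(delay_s = shifts[best],
                 grid = tibble::tibble(shift_s = shifts, weighted_rss = rss),
                 fit = fits[[best]]),
            class = "delay_result")
}

#' @export
print.delay_result <- function(x, ...) {
  cat(sprintf("delay correction: best shift %+g s (weighted RSS %.4g)\n",
              x$delay_s, x$fit$weighted_rss))
  invisible(x)
}
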