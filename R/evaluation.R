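#' Correlation and regression between paired quantifications
#'
#' Ordinary least squares of `y` on `x` with the squared Pearson
#' correlation and the two-sided p-value for the zero-slope null -- the
#' standard "y = a x + b, R^2, p" comparison of a surrogate measure
#' against a reference.
#'
#' @param x,y Paired numeric vectors, n >= 3, finite.
#' @return One-row tibble: `r_squared`, `slope`, `intercept`, `p_value`,
#'   `n`.
#' @export
correlation_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs")
  if (stats::sd(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))   # "perfect fit" warning on exact data
  tibble::tibble(r_squared = s$r.squared,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 p_value = unname(s$coefficients["x", "Pr(>|t|)"]),
                 n = length(x))
}

#' Bland-Altman agreement statistics
#'
#' Differences `y - x` against pair means, with the mean difference and
#' 95% limits of agreement (mean +/- 1.96 SD).
#'
#' @param x,y Paired numeric vectors, n >= 2.
#' @return A `bland_altman` tibble (one row): `mean_diff`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `n`; the per-pair values are in
#'   `attr(, "pairs")`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) stop("need paired data, n >= 2")
  d <- y - x
  m <- (x + y) / 2
  sd_d <- stats::sd(d)
  out <- tibble::tibble(mean_diff = mean(d), sd_diff = sd_d,
                        loa_lower = mean(d) - 1.96 * sd_d,
                        loa_upper = mean(d) + 1.96 * sd_d,
                        n = length(d))
  attr(out, "pairs") <- tibble::tibble(mean = m, diff = d)
  class(out) <- c("bland_altman", class(out))
  out
}

#' Quantify one subject with every method
#'
#' Runs the full quantification battery on one virtual (or measured)
#' subject: reference Ki from the full-scan 2T3k fit with the measured
#' IDIF; DTW Ki/K1 for each window configuration (gap completion by the
#' rational model, hybrid input function, 2T3k refit); Patlak Ki
#' (t* to 60 min) and FUR with the statically scaled population input;
#' and SUV. Returns one row per tissue and method.
#'
#' @param subject A `pet_subject` (see [simulate_subject()]), or a list
#'   with the same elements built from measured data.
#' @param pbidif A `pet_if` population input curve (normalised); rescaled
#'   per subject by dose/weight inside the hybrid assemblies.
#' @param windows List of `c(t1, t2)` DTW configurations (default all
#'   three studied: (10,55), (10,50), (10,40)).
#' @param t_star Patlak equilibrium time (default 30 min).
#' @param sampling,n_starts Passed to [fit_2t3k()]; cohort-scale callers
#'   typically use `"midpoint"` sampling and 2 starts for speed.
#' @return A tibble: `tissue`, `method`, `Ki`, `K1`, plus reference and
#'   truth columns.
#' @export
quantify_subject <- function(subject, pbidif,
                             windows = list(c(10, 55), c(10, 50), c(10, 40)),
                             t_star = 30,
                             sampling = "average", n_starts = 4) {
  schedule <- subject$idif_tac[c("start", "end")]
  idif_if <- input_function(frame_mid(subject$idif_tac),
                            pmax(subject$idif_tac$value, 0))
  static_if <- scale_pbif_static(subject$idif_tac, pbidif)$input_fn

  purrr::map_dfr(names(subject$tacs), function(tis) {
    tt <- subject$tacs[[tis]]
    truth_row <- subject$truth[subject$truth$tissue == tis, ]
    ref_fit <- fit_2t3k(tt, idif_if, sampling = sampling, n_starts = n_starts)

    rows <- tibble::tibble(tissue = tis, method = "reference",
                           Ki = ref_fit$params$Ki, K1 = ref_fit$params$K1)
    for (w in windows) {
      dtw <- quantify_dtw(tt, subject$idif_tac, pbidif, w,
                          sampling = sampling, n_starts = n_starts)
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        tissue = tis,
        method = sprintf("DTW (%g+%g min)", w[1], 60 - w[2]),
        Ki = dtw$fit$params$Ki, K1 = dtw$fit$params$K1))
    }
    pk <- patlak(tt, static_if, t_star = t_star)
    fr <- fur(tt, static_if)
    sv <- suv(tt, subject$meta$dose_MBq, subject$meta$weight_kg)
    rows <- dplyr::bind_rows(
      rows,
      tibble::tibble(tissue = tis, method = "Patlak", Ki = pk$ki, K1 = NA_real_),
      tibble::tibble(tissue = tis, method = "FUR", Ki = fr$value, K1 = NA_real_),
      tibble::tibble(tissue = tis, method = "SUV", Ki = sv$value, K1 = NA_real_))
    rows$truth_Ki <- truth_row$Ki
    rows$truth_K1 <- truth_row$K1
    rows
  })
}

#' Run the dual-time-window pipeline on one TAC
#'
#' Truncates the TAC and the blood TAC to the DTW windows, completes the
#' tissue TAC with the rational model, assembles the hybrid input function,
#' and refits the 2T3k model.
#'
#' @param tt Full-schedule tissue `pet_tac`.
#' @param idif_tac Full-schedule blood-pool `pet_tac`.
#' @param pbidif Population `pet_if`.
#' @param w `c(t1, t2)` window edges in minutes.
#' @param delay_s Input delay passed to the fit (default 0; see
#'   [correct_delay()] to estimate one).
#' @inheritParams quantify_subject
#' @return List with `fit` (`fit_2t3k`), `completed` (`pet_tac`),
#'   `rational` (`rational_fit`), `hybrid` (list from [hybrid_if_dtw()]).
#' @export
quantify_dtw <- function(tt, idif_tac, pbidif, w, sampling = "average",
                         n_starts = 4, delay_s = 0) {
  full_schedule <- new_frame_schedule(tt[c("start", "end")])
  gapped <- truncate_to_dtw(tt, w)
  rfit <- fit_rational3(gapped)
  completed <- complete_tac(gapped, rfit, full_schedule)
  blood_gapped <- truncate_to_dtw(idif_tac, w)
  mid <- frame_mid(blood_gapped)
  early <- new_tac(blood_gapped[mid < w[1], ])
  late <- new_tac(blood_gapped[mid > w[2], ])
  hybrid <- hybrid_if_dtw(early, late, pbidif, w[1], w[2])
  fit <- fit_2t3k(completed, hybrid$input_fn, sampling = sampling,
                  n_starts = n_starts, delay_s = delay_s)
  list(fit = fit, completed = completed, rational = rfit, hybrid = hybrid)
}

#' Compare quantification methods over a cohort
#'
#' The cohort-level analysis: quantifies every subject with every method,
#' then, per tissue and method, regresses the surrogate against the
#' reference full-scan Ki (correlation, slope, intercept, p), computes
#' Bland-Altman agreement and the percent-bias distribution. `pooled`
#' rows aggregate all tissues.
#'
#' @param cohort List of `pet_subject`s (see [simulate_cohort()]).
#' @param pbidif Optional population `pet_if`; by default built from the
#'   first `min(15, n)` subjects' measured blood TACs.
#' @param ... Passed to [quantify_subject()] (e.g. `windows`, `sampling`,
#'   `n_starts`).
#' @return A `comparison_study`: list with `per_subject` (long tibble) and
#'   `report` (per tissue x method statistics).
#' @export
run_comparison_study <- function(cohort, pbidif = NULL, ...) {
  if (length(cohort) == 0) stop("empty cohort")
  if (is.null(pbidif)) {
    k <- seq_len(min(15, length(cohort)))
    if (length(k) >= 2) {
      pbidif <- build_pb_idif(purrr::map(cohort[k], "idif_tac"),
                              purrr::map_dbl(cohort[k], ~ .x$meta$dose_MBq),
                              purrr::map_dbl(cohort[k], ~ .x$meta$weight_kg))
    } else {
      s1 <- cohort[[1]]
      pbidif <- input_function(
        frame_mid(s1$idif_tac),
        s1$idif_tac$value / (s1$meta$dose_MBq / s1$meta$weight_kg))
    }
  }
  per_subject <- purrr::imap_dfr(cohort, function(s, i) {
    dplyr::mutate(quantify_subject(s, pbidif, ...), subject = i,
                  .before = 1)
  })
  ref <- dplyr::select(
    dplyr::filter(per_subject, .data$method == "reference"),
    "subject", "tissue", ref_Ki = "Ki")
  long <- dplyr::left_join(
    dplyr::filter(per_subject, .data$method != "reference"),
    ref, by = c("subject", "tissue"))

  report <- dplyr::group_modify(
    dplyr::group_by(long, .data$tissue, .data$method),
    function(d, key) method_stats(d$ref_Ki, d$Ki))
  pooled <- dplyr::group_modify(
    dplyr::group_by(long, .data$method),
    function(d, key) method_stats(d$ref_Ki, d$Ki))
  pooled$tissue <- "pooled"
  report <- dplyr::bind_rows(dplyr::ungroup(report), pooled)

  structure(list(per_subject = per_subject, report = report,
                 pbidif = pbidif),
            class = "comparison_study")
}

method_stats <- function(ref, est) {
  out <- if (length(ref) >= 3 && stats::sd(ref) > 0) {
    correlation_regression(ref, est)
  } else {
    tibble::tibble(r_squared = NA_real_, slope = NA_real_,
                   intercept = NA_real_, p_value = NA_real_, n = length(ref))
  }
  ba <- if (length(ref) >= 2) bland_altman(ref, est) else
    tibble::tibble(mean_diff = NA_real_, sd_diff = NA_real_,
                   loa_lower = NA_real_, loa_upper = NA_real_, n = length(ref))
  bias <- tryCatch(percent_bias(ref, est), error = function(e) NA_real_)
  dplyr::bind_cols(out,
                   dplyr::rename_with(tibble::as_tibble(ba[1, 1:4]),
                                      ~ paste0("ba_", .x)),
                   tibble::tibble(bias_mean_pct = mean(bias),
                                  bias_sd_pct = stats::sd(bias)))
}

#' @export
print.comparison_study <- function(x, ...) {
  cat("comparison_study:", dplyr::n_distinct(x$per_subject$subject),
      "subjects,", dplyr::n_distinct(x$per_subject$tissue), "tissues\n")
  print(x$report)
  invisible(x)
}

#' Tidy a comparison study
#'
#' @param x A `comparison_study`.
#' @param ... Unused.
#' @return `tidy()`: the per-tissue/method report tibble; `glance()`: one
#'   row per method pooled over tissues.
#' @export
tidy.comparison_study <- function(x, ...) {
  x$report
}

#' @rdname tidy.comparison_study
#' @export
glance.comparison_study <- function(x, ...) {
  dplyr::filter(x$report, .data$tissue == "pooled")
}

#' Write a comparison report to JSON
#'
#' Deterministic serialisation (fixed digit count, no environment-dependent
#' fields) so a fixed-seed study produces a byte-identical file.
#'
#' @param x A `comparison_study`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(
    list(report = x$report, per_subject = x$per_subject),
    path, digits = 10, na = "null", auto_unbox = TRUE)
  invisible(path)
}
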