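#' Build a frame schedule from a framing specification
#'
#' A dynamic PET acquisition is reconstructed into contiguous time frames.
#' The schedule is described compactly as blocks of `count` frames of a common
#' `duration_s`, e.g. the 66-frame total-body protocol
#' 24 x 5 s, 6 x 10 s, 6 x 30 s, 6 x 60 s, 24 x 120 s.
#'
#' @param spec A data frame with columns `count` and `duration_s`, or a list of
#'   `c(count, duration_s)` pairs. Counts must be >= 1 and durations > 0.
#' @return A `frame_schedule` tibble with columns `start` and `end` in minutes,
#'   contiguous from t = 0.
#' @examples
#' frame_schedule_66()
#' frame_schedule(list(c(4, 30), c(2, 60)))
#' @export
frame_schedule <- function(spec) {
  if (is.list(spec) && !is.data.frame(spec)) {
    spec <- tibble::tibble(
      count = vapply(spec, `[`, numeric(1), 1),
      duration_s = vapply(spec, `[`, numeric(1), 2)
    )
  }
  if (!is.data.frame(spec) || nrow(spec) == 0) {
    stop("`spec` must be a non-empty data frame or list of (count, duration) pairs")
  }
  stopifnot(all(c("count", "duration_s") %in% names(spec)))
  if (any(spec$count < 1) || any(spec$duration_s <= 0)) {
    stop("counts must be >= 1 and durations > 0")
  }
  dur_s <- rep(spec$duration_s, times = spec$count)
  end <- cumsum(dur_s) / 60
  start <- c(0, end[-length(end)])
  new_frame_schedule(tibble::tibble(start = start, end = end))
}

new_frame_schedule <- function(df) {
  structure(df, class = c("frame_schedule", class(tibble::as_tibble(df))))
}

#' The 66-frame total-body acquisition schedule
#'
#' The standard 60-minute dynamic framing used throughout:
#' 24 x 5 s, 6 x 10 s, 6 x 30 s, 6 x 60 s, 24 x 120 s.
#'
#' @return A `frame_schedule` tibble (66 rows, minutes).
#' @export
frame_schedule_66 <- function() {
  frame_schedule(list(c(24, 5), c(6, 10), c(6, 30), c(6, 60), c(24, 120)))
}

#' Frame midpoints and durations
#'
#' @param schedule A `frame_schedule` (or any data frame with `start`/`end`
#'   columns in minutes).
#' @return Numeric vector of frame midpoints (`frame_mid`) or durations
#'   (`frame_dur`), in minutes.
#' @export
frame_mid <- function(schedule) (schedule$start + schedule$end) / 2

#' @rdname frame_mid
#' @export
frame_dur <- function(schedule) schedule$end - schedule$start

validate_schedule <- function(schedule) {
  stopifnot(all(c("start", "end") %in% names(schedule)))
  if (any(schedule$end <= schedule$start)) stop("frames must have end > start")
  if (is.unsorted(schedule$start)) stop("frames must be sorted by start time")
  if (any(schedule$start < 0)) stop("frame times must be >= 0")
  if (nrow(schedule) > 1 &&
      any(schedule$start[-1] < schedule$end[-nrow(schedule)] - 1e-9)) {
    stop("frames must not overlap")
  }
  invisible(schedule)
}
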