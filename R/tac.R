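#' Time-activity curves
#'
#' A time-activity curve (TAC) records the mean activity concentration
#' (kBq/mL) in a region or voxel for each acquisition frame. It is stored as a
#' tibble with columns `start`, `end` (minutes) and `value` (kBq/mL), so it
#' pipes through dplyr verbs; subsetting rows (e.g. to simulate a gapped
#' dual-time-window acquisition) keeps it a valid TAC.
#'
#' Measured data may contain small negative values (noise in low-count
#' frames); these are preserved but flagged with a warning on construction.
#'
#' @param schedule A `frame_schedule` (columns `start`, `end` in minutes).
#' @param values Numeric vector of per-frame activity concentrations, same
#'   length as the schedule.
#' @return A `pet_tac` tibble with columns `start`, `end`, `value`.
#' @export
tac <- function(schedule, values) {
  validate_schedule(schedule)
  if (length(values) != nrow(schedule)) {
    stop("`values` must have one entry per frame")
  }
  if (any(!is.finite(values))) stop("TAC values must be finite")
  if (any(values < 0)) {
    warning("TAC contains negative values; preserved as measured")
  }
  new_tac(tibble::tibble(start = schedule$start, end = schedule$end,
                         value = as.numeric(values)))
}

new_tac <- function(df) {
  structure(tibble::as_tibble(df), class = c("pet_tac", class(tibble::tibble())))
}

#' Coerce a data frame to a TAC
#'
#' Accepts either minute columns (`start`, `end`, `value`) or the CSV
#' interchange columns (`frame_start_s`, `frame_end_s`,
#' `activity_kBq_per_mL`), converting seconds to minutes.
#'
#' @param df A data frame in either layout.
#' @return A `pet_tac` tibble.
#' @export
as_tac <- function(df) {
  if (all(c("frame_start_s", "frame_end_s", "activity_kBq_per_mL") %in% names(df))) {
    df <- tibble::tibble(start = df$frame_start_s / 60, end = df$frame_end_s / 60,
                         value = df$activity_kBq_per_mL)
  }
  tac(df[c("start", "end")], df$value)
}

#' Read / write a TAC in the CSV interchange format
#'
#' Columns: `frame_start_s`, `frame_end_s`, `activity_kBq_per_mL`.
#'
#' @param path File path.
#' @param x A `pet_tac`.
#' @return `read_tac_csv()` returns a `pet_tac`; `write_tac_csv()` returns
#'   `x` invisibly.
#' @export
read_tac_csv <- function(path) {
  as_tac(utils::read.csv(path))
}

#' @rdname read_tac_csv
#' @export
write_tac_csv <- function(x, path) {
  utils::write.csv(
    data.frame(frame_start_s = x$start * 60, frame_end_s = x$end * 60,
               activity_kBq_per_mL = x$value),
    path, row.names = FALSE)
  invisible(x)
}

#' Read frame timing from a BIDS-PET style JSON sidecar
#'
#' Reads `FrameTimesStart` and `FrameDuration` arrays (seconds) and returns
#' the schedule in minutes.
#'
#' @param path Path to a JSON sidecar.
#' @return A `frame_schedule` tibble.
#' @export
read_frame_timing_json <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(meta$FrameTimesStart) || is.null(meta$FrameDuration)) {
    stop("sidecar must contain FrameTimesStart and FrameDuration")
  }
  start <- as.numeric(meta$FrameTimesStart) / 60
  end <- start + as.numeric(meta$FrameDuration) / 60
  validate_schedule(new_frame_schedule(tibble::tibble(start = start, end = end)))
}

# TAC value interpolated at arbitrary times from frame-midpoint samples;
# constant extrapolation beyond the first/last midpoint.
tac_interp <- function(x, t) {
  stats::approx(frame_mid(x), x$value, xout = t, rule = 2)$y
}
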