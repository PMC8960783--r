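#' Convert clock time of death to Zeitgeber time
#'
#' Zeitgeber time (ZT) anchors the circadian day at sunrise on the date of
#' death: ZT0 is sunrise and negative values are hours immediately before
#' sunrise. The representative is chosen in the half-open interval
#' \eqn{[-6, 18)}, the scale conventionally used for plotting postmortem
#' TOD data.
#'
#' Under the default convention the mapping is a pure sunrise-anchored
#' offset: \code{(tod_clock - sunrise)} wrapped into \eqn{[-6, 18)}; sunset
#' is validated (a degenerate photoperiod with \code{sunrise == sunset} is
#' rejected) but does not change the result. With
#' \code{photoperiod_scale = TRUE}, daylight hours are linearly rescaled to
#' a 12 h day (ZT0--ZT12) and night hours to a 12 h night, so that ZT12
#' always corresponds to sunset regardless of season.
#'
#' @param tod_clock clock time of death, decimal hours in \eqn{[0, 24)}.
#' @param sunrise sunrise on the date of death, decimal hours in \eqn{[0, 24)}.
#' @param sunset sunset on the date of death, decimal hours in \eqn{[0, 24)}.
#' @param photoperiod_scale logical; rescale day/night to 12 h halves.
#' @return Zeitgeber time, decimal hours in \eqn{[-6, 18)}. Vectorized over
#'   all three time arguments.
#' @examples
#' to_zeitgeber(6, sunrise = 6, sunset = 18)    # death at sunrise -> ZT 0
#' to_zeitgeber(4, sunrise = 6, sunset = 18)    # 2 h before sunrise -> ZT -2
#' to_zeitgeber(0.5, sunrise = 7, sunset = 19)  # wraps to ZT 17.5
#' @export
to_zeitgeber <- function(tod_clock, sunrise, sunset, photoperiod_scale = FALSE) {
  check_hours(tod_clock, "tod_clock")
  check_hours(sunrise, "sunrise")
  check_hours(sunset, "sunset")
  n <- max(length(tod_clock), length(sunrise), length(sunset))
  tod_clock <- rep_len(tod_clock, n)
  sunrise <- rep_len(sunrise, n)
  sunset <- rep_len(sunset, n)
  if (any(sunrise == sunset)) {
    td_stop("degenerate_photoperiod_error",
            "sunrise equals sunset: photoperiod is degenerate")
  }
  if (!photoperiod_scale) {
    zt <- ((tod_clock - sunrise + 6) %% 24) - 6
  } else {
    day_len <- (sunset - sunrise) %% 24
    since_rise <- (tod_clock - sunrise) %% 24
    in_day <- since_rise < day_len
    zt_raw <- ifelse(in_day,
                     12 * since_rise / day_len,
                     12 + 12 * (since_rise - day_len) / (24 - day_len))
    zt <- ((zt_raw + 6) %% 24) - 6
  }
  zt
}

#' Attach Zeitgeber time to a subject metadata table
#'
#' Populates a `zt` column from `tod_clock`, `sunrise` and `sunset` via
#' [to_zeitgeber()], preserving row order.
#'
#' @param metadata data.frame with columns `subject_id`, `group`,
#'   `tod_clock`, `sunrise`, `sunset`.
#' @param photoperiod_scale passed to [to_zeitgeber()].
#' @return the same data.frame with a `zt` column appended (decimal hours
#'   in \eqn{[-6, 18)}).
#' @export
attach_zt <- function(metadata, photoperiod_scale = FALSE) {
  required <- c("subject_id", "group", "tod_clock", "sunrise", "sunset")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    td_stop("schema_error", "metadata is missing column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(metadata$subject_id)) {
    td_stop("schema_error", "duplicate subject_id: %s",
            paste(unique(metadata$subject_id[duplicated(metadata$subject_id)]),
                  collapse = ", "))
  }
  metadata$zt <- to_zeitgeber(metadata$tod_clock, metadata$sunrise,
                              metadata$sunset,
                              photoperiod_scale = photoperiod_scale)
  metadata
}
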