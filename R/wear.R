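#' Remove night-time epochs
#'
#' Drops every epoch whose start time falls in the night window, 00:00 to
#' 06:00 by default (half-open: an epoch starting exactly at 06:00:00 is
#' retained, one at 05:59:57 is not). Night removal is applied before
#' non-wear detection, so wear statistics always refer to the remaining
#' 06:00-24:00 span.
#'
#' @param epochs an `epoch_series`.
#' @param night_start,night_end night window bounds in hours of the day.
#' @return The `epoch_series` without night epochs.
#' @export
remove_night <- function(epochs, night_start = 0, night_end = 6) {
  hr <- as.numeric(format(epochs$epoch_start, "%H")) +
    as.numeric(format(epochs$epoch_start, "%M")) / 60 +
    as.numeric(format(epochs$epoch_start, "%S")) / 3600
  keep <- !(hr >= night_start & hr < night_end)
  epoch_subset(epochs, keep)
}

#' Detect non-wear periods from the AG-filtered epoch series
#'
#' A non-wear period is a run of at least `min_duration_min` minutes of zero
#' epochs, with an allowance of up to `allowance_min` minutes (cumulative,
#' anywhere in the window, edges included) of output strictly between zero
#' and the sedentary threshold. An epoch at or above the sedentary threshold
#' terminates the window. "Zero" means at most `zero_tol` mg, since exact
#' zeros are measure-zero after band-pass filtering. Candidate windows never
#' span gaps in the epoch timeline (e.g. the removed night), so detection is
#' invariant to concatenation of disjoint days.
#'
#' Non-wear classification is defined on the AG-filtered output; the returned
#' mask is intended to be applied unchanged to the wide-filtered series of
#' the same subject-day (same epoch grid).
#'
#' @param ag_epochs the AG-filtered `epoch_series` (night already removed).
#' @param sedentary_threshold mg value separating sedentary output from
#'   activity (default 19.1, the 1.5 MET cut-point of the AG arm).
#' @param min_duration_min minimum window length in minutes (default 60).
#' @param allowance_min maximum cumulative sub-threshold minutes tolerated
#'   inside a window (default 2).
#' @param zero_tol epoch values at or below this (mg) count as zero.
#' @return Logical vector, `TRUE` = wear, aligned to `ag_epochs`, with
#'   attribute `provenance = "ag_reference"`.
#' @export
detect_non_wear <- function(ag_epochs, sedentary_threshold = 19.1,
                            min_duration_min = 60, allowance_min = 2,
                            zero_tol = 1e-6) {
  v <- ag_epochs$value_mg
  n <- length(v)
  el <- epoch_len(ag_epochs)
  wear <- rep(TRUE, n)
  if (n == 0L) return(structure(wear, provenance = "ag_reference"))

  # segment on timeline discontinuities: windows may not bridge gaps
  tdiff <- diff(as.numeric(ag_epochs$epoch_start))
  seg_id <- cumsum(c(1L, as.integer(abs(tdiff - el) > 0.5)))

  allow_ep <- floor(allowance_min * 60 / el)      # max sub-threshold epochs
  min_ep <- ceiling(min_duration_min * 60 / el)   # min window length in epochs
  is_zero <- v <= zero_tol
  is_allow <- !is_zero & v < sedentary_threshold

  for (seg in split(seq_len(n), seg_id)) {
    l <- 1L
    n_allow <- 0L
    for (r in seq_along(seg)) {
      i <- seg[r]
      if (!is_zero[i] && !is_allow[i]) {        # active epoch terminates
        l <- r + 1L
        n_allow <- 0L
        next
      }
      if (is_allow[i]) n_allow <- n_allow + 1L
      while (n_allow > allow_ep) {              # shrink from the left
        if (is_allow[seg[l]]) n_allow <- n_allow - 1L
        l <- l + 1L
      }
      if (r - l + 1L >= min_ep) wear[seg[l:r]] <- FALSE
    }
  }
  structure(wear, provenance = "ag_reference")
}

#' Per-day wear time and validity
#'
#' Wear time per calendar date is the count of wear epochs times the epoch
#' length. A day is valid when wear time reaches `min_wear_hours` (default 8,
#' strict: 7.99 h is invalid).
#'
#' @param epochs an `epoch_series` (night removed).
#' @param mask logical wear mask from [detect_non_wear()], aligned to
#'   `epochs`.
#' @param min_wear_hours validity threshold in hours.
#' @return A data.frame with columns `date`, `wear_hours`, `valid`.
#' @export
wear_time_by_day <- function(epochs, mask, min_wear_hours = 8) {
  stopifnot(length(mask) == nrow(epochs))
  el <- epoch_len(epochs)
  date <- as.Date(epochs$epoch_start, tz = "UTC")
  wear_sec <- tapply(as.numeric(mask) * el, date, sum)
  out <- data.frame(date = as.Date(names(wear_sec)),
                    wear_hours = as.numeric(wear_sec) / 3600)
  out$valid <- out$wear_hours >= min_wear_hours
  rownames(out) <- NULL
  out
}

#' Is a multi-day measurement valid?
#'
#' A measurement is valid when it contains at least `min_valid_days` valid
#' days (default 4).
#'
#' @param days data.frame from [wear_time_by_day()] (needs a `valid` column),
#'   possibly empty.
#' @param min_valid_days required number of valid days.
#' @return Single logical.
#' @export
is_valid_measurement <- function(days, min_valid_days = 4) {
  if (is.null(days) || nrow(days) == 0L) return(FALSE)
  sum(days$valid) >= min_valid_days
}
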