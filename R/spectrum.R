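#' Intensity bin scheme for an epoch output arm
#'
#' Bins cover the epoch output range with half-open intervals. The first two
#' bins are half width so that low intensities are resolved in relation to
#' the sedentary and light cut-points: AG edges run 0, 10, 20, 40, 60, ... in
#' 20 mg steps; wide-filter edges run 0, 40, 80, 160, 240, ... in 80 mg steps
#' (the wide output is roughly four times the AG output at high intensity).
#' The last bin is open-ended to infinity, so no epoch is ever discarded.
#'
#' @param filter_kind `"ag"` or `"wide"`.
#' @param n_bins number of bins (default 22, at least 3).
#' @return An object of class `bin_scheme`: list with `filter_kind`, `edges`
#'   (the `n_bins` lower edges, starting at 0), `n_bins`, `final_bin_open`,
#'   `labels`.
#' @export
#' @examples
#' make_bin_scheme("ag", 5)$edges    # 0 10 20 40 60
#' make_bin_scheme("wide", 5)$edges  # 0 40 80 160 240
make_bin_scheme <- function(filter_kind = c("ag", "wide"), n_bins = 22) {
  filter_kind <- match.arg(tolower(filter_kind), c("ag", "wide"))
  if (n_bins < 3) stop("`n_bins` must be at least 3")
  step <- switch(filter_kind, ag = 20, wide = 80)
  edges <- c(0, step / 2, step * seq_len(n_bins - 2L))
  labels <- c(sprintf("[%g,%g)", edges[-n_bins], edges[-1L]),
              sprintf("[%g,Inf)", edges[n_bins]))
  structure(list(filter_kind = filter_kind, edges = edges, n_bins = as.integer(n_bins),
                 final_bin_open = TRUE, labels = labels),
            class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("<bin_scheme> %s, %d bins: %s ... %s\n", toupper(x$filter_kind),
              x$n_bins, paste(head(x$edges, 4), collapse = ", "), tail(x$labels, 1)))
  invisible(x)
}

#' MET-anchored intensity cut-points for an arm
#'
#' Epoch output values (mg) equivalent to 1.5, 3, 6 and 9 METs, delimiting
#' sedentary (SED), light (LPA), moderate (MPA), vigorous (VPA) and very
#' vigorous (VVPA) activity. AG arm: 19.1, 63.0, 171.0, 300.2 mg; wide arm:
#' 38.9, 167.2, 582.3, 994.1 mg.
#'
#' @param filter_kind `"ag"` or `"wide"`.
#' @return Named numeric vector `c(lpa=, mpa=, vpa=, vvpa=)` of lower bounds.
#' @export
met_cutpoints <- function(filter_kind = c("ag", "wide")) {
  filter_kind <- match.arg(tolower(filter_kind), c("ag", "wide"))
  switch(filter_kind,
         ag   = c(lpa = 19.1, mpa = 63.0, vpa = 171.0, vvpa = 300.2),
         wide = c(lpa = 38.9, mpa = 167.2, vpa = 582.3, vvpa = 994.1))
}

met_class_names <- c("SED", "LPA", "MPA", "VPA", "VVPA")

# assign epoch values to bins (1..n_bins); half-open [low, high), open last bin
bin_index <- function(values, scheme) {
  idx <- findInterval(values, scheme$edges)
  pmin(pmax(idx, 1L), scheme$n_bins)
}

#' Time-in-bin intensity spectrum for one subject
#'
#' Wear epochs on valid days are assigned to bins by value (half-open
#' intervals, boundary values join the upper bin); per-bin time is summed and
#' divided by the number of valid days, giving minutes per day. By
#' construction the bin minutes sum exactly to the average daily wear time.
#'
#' @param epochs an `epoch_series` (night removed).
#' @param mask logical wear mask aligned to `epochs`.
#' @param scheme a `bin_scheme`; its `filter_kind` should match the series.
#' @param days data.frame from [wear_time_by_day()]; only dates with
#'   `valid = TRUE` contribute.
#' @return An object of class `intensity_spectrum`: list with
#'   `minutes_per_day` (named by bin label), `scheme`, `n_valid_days`,
#'   `wear_minutes_per_day`.
#' @export
time_in_bins <- function(epochs, mask, scheme, days) {
  stopifnot(inherits(scheme, "bin_scheme"), length(mask) == nrow(epochs))
  valid_dates <- days$date[days$valid]
  if (length(valid_dates) == 0L) stop("no valid days")
  el <- epoch_len(epochs)
  on_valid <- as.Date(epochs$epoch_start, tz = "UTC") %in% valid_dates
  use <- mask & on_valid
  idx <- bin_index(epochs$value_mg[use], scheme)
  counts <- tabulate(idx, nbins = scheme$n_bins)
  minutes <- counts * el / 60 / length(valid_dates)
  names(minutes) <- scheme$labels
  structure(list(minutes_per_day = minutes, scheme = scheme,
                 n_valid_days = length(valid_dates),
                 wear_minutes_per_day = sum(minutes)),
            class = "intensity_spectrum")
}

#' @export
print.intensity_spectrum <- function(x, ...) {
  cat(sprintf("<intensity_spectrum> %s, %d bins, %.1f wear min/day over %d valid days\n",
              toupper(x$scheme$filter_kind), x$scheme$n_bins,
              x$wear_minutes_per_day, x$n_valid_days))
  invisible(x)
}

#' Minutes per day in the five MET-anchored intensity classes
#'
#' Epochs below the 1.5 MET cut-point are sedentary; each class is half-open
#' (a value exactly at a cut-point joins the class above it). Classes are a
#' coarsening of the full spectrum: their minutes sum to the same daily wear
#' time.
#'
#' @inheritParams time_in_bins
#' @param cutpoints named vector from [met_cutpoints()].
#' @return Named numeric vector of minutes/day for SED, LPA, MPA, VPA, VVPA.
#' @export
met_class_minutes <- function(epochs, mask, cutpoints, days) {
  stopifnot(length(mask) == nrow(epochs))
  valid_dates <- days$date[days$valid]
  if (length(valid_dates) == 0L) stop("no valid days")
  el <- epoch_len(epochs)
  on_valid <- as.Date(epochs$epoch_start, tz = "UTC") %in% valid_dates
  use <- mask & on_valid
  cls <- findInterval(epochs$value_mg[use], cutpoints) + 1L
  counts <- tabulate(cls, nbins = 5L)
  stats::setNames(counts * el / 60 / length(valid_dates), met_class_names)
}

#' Proportion of subjects with any time in each bin
#'
#' For each bin of a shared scheme, the fraction of subjects whose spectrum
#' has strictly positive minutes in that bin — the participation profile
#' across the intensity range.
#'
#' @param spectra a list of `intensity_spectrum` objects sharing one scheme,
#'   or a numeric matrix (rows = subjects, columns = bins).
#' @return Numeric vector of proportions in `[0, 1]`, one per bin.
#' @export
participation_proportion <- function(spectra) {
  M <- spectrum_matrix(spectra)
  if (nrow(M) == 0L) stop("empty cohort")
  colMeans(M > 0)
}

#' Assemble a cohort spectrum matrix
#'
#' @param spectra list of `intensity_spectrum` objects sharing one scheme, or
#'   an already-assembled numeric matrix (returned unchanged).
#' @return Numeric matrix, rows = subjects, columns = bins (labelled).
#' @export
spectrum_matrix <- function(spectra) {
  if (is.matrix(spectra)) return(spectra)
  stopifnot(is.list(spectra), length(spectra) > 0L)
  schemes <- unique(vapply(spectra, function(s) paste(s$scheme$filter_kind, s$scheme$n_bins), ""))
  if (length(schemes) != 1L) stop("all spectra must share one bin scheme")
  do.call(rbind, lapply(spectra, function(s) s$minutes_per_day))
}
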