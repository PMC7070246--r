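#' Construct a raw tri-axial acceleration record
#'
#' Container for a raw accelerometer recording: an n x 3 matrix of
#' accelerations in g at a nominal sample rate, with a start timestamp.
#' Samples are clipped to the device range of +/- 6 g on ingest.
#'
#' @param samples numeric n x 3 matrix (columns x, y, z) in g.
#' @param sample_rate sampling frequency in Hz (nominal 30).
#' @param start_time start timestamp (`POSIXct`, or anything
#'   [as.POSIXct()] accepts).
#' @param range_g device measurement range in g; samples are clipped to
#'   `[-range_g, range_g]`.
#' @return An object of class `raw_accel`: a list with elements `samples`,
#'   `sample_rate`, `start_time`.
#' @export
raw_accel <- function(samples, sample_rate = 30, start_time = as.POSIXct("2020-01-06 06:00:00", tz = "UTC"),
                      range_g = 6) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stop("`samples` must have three columns (x, y, z)")
  if (!all(is.finite(samples))) stop("`samples` must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number")
  samples <- pmin(pmax(samples, -range_g), range_g)
  structure(
    list(samples = samples, sample_rate = sample_rate,
         start_time = as.POSIXct(start_time, tz = "UTC")),
    class = "raw_accel"
  )
}

#' @export
print.raw_accel <- function(x, ...) {
  cat(sprintf("<raw_accel> %d samples at %g Hz (%.1f min) starting %s\n",
              nrow(x$samples), x$sample_rate,
              nrow(x$samples) / x$sample_rate / 60,
              format(x$start_time, "%Y-%m-%d %H:%M:%S")))
  invisible(x)
}

#' Design the band-pass filter for one processing arm
#'
#' Returns the band-pass specification used to emulate either the narrow
#' ActiGraph frequency band (`"ag"`, low-pass corner 1.6 Hz) or the wide band
#' (`"wide"`, low-pass corner 10 Hz). Both share a low-frequency
#' (gravity-removal) corner, 0.29 Hz by default. The filter is a Butterworth
#' band-pass (4th order, i.e. two poles per band edge), so each stated corner
#' is the half-power (-3 dB) point of the single-pass response. Filtering is
#' applied forward-backward (zero phase), which squares the amplitude
#' response; [filter_gain()] reports the effective zero-phase gain.
#'
#' @param kind `"ag"` or `"wide"` (case-insensitive).
#' @param sample_rate sampling frequency in Hz; must be at least 30 and the
#'   low-pass corner must lie below the Nyquist frequency.
#' @param high_pass_corner gravity-removal corner in Hz.
#' @param order filter order of the band-pass (even; `order/2` poles per edge).
#' @return An object of class `filter_spec`: list with `kind`,
#'   `high_pass_corner`, `low_pass_corner`, `order`, `design_name`,
#'   `sample_rate`, and the digital filter coefficients `b`, `a`.
#' @export
#' @examples
#' design_filter("ag", 30)$low_pass_corner    # 1.6
#' design_filter("wide", 30)$low_pass_corner  # 10
design_filter <- function(kind = c("ag", "wide"), sample_rate = 30,
                          high_pass_corner = 0.29, order = 4) {
  kind <- match.arg(tolower(kind), c("ag", "wide"))
  if (sample_rate < 30) stop("`sample_rate` must be at least 30 Hz")
  low_pass_corner <- switch(kind, ag = 1.6, wide = 10)
  nyq <- sample_rate / 2
  if (low_pass_corner >= nyq) stop("low-pass corner must be below the Nyquist frequency")
  if (high_pass_corner <= 0 || high_pass_corner >= low_pass_corner)
    stop("`high_pass_corner` must lie in (0, low_pass_corner)")
  if (order %% 2 != 0 || order < 2) stop("`order` must be a positive even integer")
  bf <- signal::butter(order / 2, c(high_pass_corner, low_pass_corner) / nyq,
                       type = "pass")
  structure(
    list(kind = kind, high_pass_corner = high_pass_corner,
         low_pass_corner = low_pass_corner, order = order,
         design_name = sprintf("butterworth band-pass %g-%g Hz, order %d, zero-phase",
                               high_pass_corner, low_pass_corner, order),
         sample_rate = sample_rate, b = bf$b, a = bf$a),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s: %s (design rate %g Hz)\n",
              toupper(x$kind), x$design_name, x$sample_rate))
  invisible(x)
}

#' Effective zero-phase amplitude gain of a filter at given frequencies
#'
#' Evaluates the designed transfer function at `freq_hz` and returns the
#' amplitude gain of the forward-backward application (the squared magnitude
#' of the single-pass response), i.e. the factor by which a pure sinusoid at
#' that frequency is scaled by [filter_signal()].
#'
#' @param spec a `filter_spec` from [design_filter()].
#' @param freq_hz vector of frequencies in Hz.
#' @return Numeric vector of gains in `[0, 1]`.
#' @export
#' @examples
#' filter_gain(design_filter("ag", 30), c(0.7, 3, 5))
filter_gain <- function(spec, freq_hz) {
  stopifnot(inherits(spec, "filter_spec"))
  w <- 2 * pi * freq_hz / spec$sample_rate
  h <- vapply(w, function(wi) {
    z <- exp(-1i * wi * (seq_along(spec$b) - 1L))
    Mod(sum(spec$b * z) / sum(spec$a * z))
  }, numeric(1))
  h^2
}

#' Band-pass filter a raw tri-axial signal
#'
#' Applies the band-pass filter to each axis independently, forward and
#' backward (zero phase), using odd end extensions so that boundary
#' transients do not leak into the signal. Gravity (the DC component) is
#' removed by the high-pass edge; content above the low-pass corner is
#' attenuated.
#'
#' @param raw a `raw_accel` object (or an n x 3 numeric matrix in g).
#' @param spec a `filter_spec`; its design rate must match the signal's
#'   sample rate.
#' @return An n x 3 matrix of filtered accelerations in g.
#' @export
filter_signal <- function(raw, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  X <- if (inherits(raw, "raw_accel")) raw$samples else as.matrix(raw)
  if (inherits(raw, "raw_accel") && !isTRUE(all.equal(raw$sample_rate, spec$sample_rate)))
    stop("sample rate of the signal does not match the filter design rate")
  if (nrow(X) == 0L) stop("empty signal")
  # forward-backward filtering with odd (reflect-and-invert) end extensions,
  # long enough for the slow gravity-removal pole to settle (~10 s)
  n_pad <- min(nrow(X) - 1L, as.integer(10 * spec$sample_rate))
  if (n_pad < 3L * (length(spec$a) - 1L))
    stop("signal shorter than the filter warm-up length")
  apply(X, 2L, function(col) {
    n <- length(col)
    head_ext <- 2 * col[1L] - col[(n_pad + 1L):2L]
    tail_ext <- 2 * col[n] - col[(n - 1L):(n - n_pad)]
    ext <- c(head_ext, col, tail_ext)
    out <- rev(signal::filter(spec$b, spec$a, rev(signal::filter(spec$b, spec$a, ext))))
    out[(n_pad + 1L):(n_pad + n)]
  })
}

#' Aggregate a filtered signal into fixed epochs of mean amplitude (mg)
#'
#' Per epoch, the mean over samples of the Euclidean norm of the three
#' filtered axes, expressed in mg (g x 10^-3). A trailing partial epoch is
#' dropped, never padded.
#'
#' @param filtered n x 3 matrix of filtered accelerations in g.
#' @param sample_rate sampling frequency in Hz.
#' @param epoch_length epoch duration in seconds (default 3); must contain an
#'   integer number of samples.
#' @param start_time timestamp of the first sample; epoch start times are
#'   derived from it.
#' @param filter_kind tag recorded on the output (`"ag"` or `"wide"`).
#' @return An `epoch_series`: a data.frame with columns `epoch_start`
#'   (POSIXct) and `value_mg`, with attributes `filter_kind`, `epoch_length`.
#' @export
epoch_aggregate <- function(filtered, sample_rate = 30, epoch_length = 3,
                            start_time = as.POSIXct("2020-01-06 06:00:00", tz = "UTC"),
                            filter_kind = NA_character_) {
  X <- as.matrix(filtered)
  if (nrow(X) == 0L) stop("empty input")
  n_per <- epoch_length * sample_rate
  if (abs(n_per - round(n_per)) > 1e-9)
    stop("`epoch_length` must contain an integer number of samples")
  n_per <- as.integer(round(n_per))
  n_ep <- nrow(X) %/% n_per
  if (n_ep == 0L) stop("input shorter than one epoch")
  amp <- sqrt(rowSums(X[seq_len(n_ep * n_per), , drop = FALSE]^2))
  vals <- colMeans(matrix(amp, nrow = n_per, ncol = n_ep)) * 1000
  epoch_series(
    epoch_start = as.POSIXct(start_time, tz = "UTC") + (seq_len(n_ep) - 1L) * epoch_length,
    value_mg = vals, filter_kind = filter_kind, epoch_length = epoch_length
  )
}

#' Construct an epoch series
#'
#' @param epoch_start POSIXct vector of epoch start times.
#' @param value_mg non-negative epoch values in mg.
#' @param filter_kind `"ag"`, `"wide"` or `NA`.
#' @param epoch_length epoch duration in seconds.
#' @return A data.frame of class `epoch_series`.
#' @export
epoch_series <- function(epoch_start, value_mg, filter_kind = NA_character_,
                         epoch_length = 3) {
  stopifnot(length(epoch_start) == length(value_mg), all(value_mg >= 0))
  structure(
    data.frame(epoch_start = as.POSIXct(epoch_start, tz = "UTC"),
               value_mg = as.numeric(value_mg)),
    filter_kind = filter_kind, epoch_length = epoch_length,
    class = c("epoch_series", "data.frame")
  )
}

epoch_len <- function(epochs) attr(epochs, "epoch_length") %||% 3

# subset an epoch_series keeping its attributes
epoch_subset <- function(epochs, keep) {
  epoch_series(epochs$epoch_start[keep], epochs$value_mg[keep],
               filter_kind = attr(epochs, "filter_kind"),
               epoch_length = epoch_len(epochs))
}

#' Process a raw recording to an epoch series in one call
#'
#' Convenience wrapper: [design_filter()], [filter_signal()],
#' [epoch_aggregate()].
#'
#' @inheritParams design_filter
#' @param raw a `raw_accel` object.
#' @param epoch_length epoch duration in seconds.
#' @return An `epoch_series`.
#' @export
process_raw <- function(raw, kind = c("ag", "wide"), epoch_length = 3,
                        high_pass_corner = 0.29) {
  kind <- match.arg(tolower(kind), c("ag", "wide"))
  spec <- design_filter(kind, raw$sample_rate, high_pass_corner = high_pass_corner)
  filt <- filter_signal(raw, spec)
  epoch_aggregate(filt, raw$sample_rate, epoch_length,
                  start_time = raw$start_time, filter_kind = kind)
}

#' Read a raw acceleration CSV
#'
#' Expected layout: header lines `subject_id,<id>`, `start_time,<ISO-8601>`,
#' `sample_rate,<Hz>` followed by a `x,y,z` column header and one row per
#' sample in g. A headerless file can be read by supplying `start_time` and
#' `sample_rate` directly.
#'
#' @param path file path.
#' @param start_time,sample_rate overrides for headerless files.
#' @return A `raw_accel` object with attribute `subject_id` when present.
#' @export
read_raw_csv <- function(path, start_time = NULL, sample_rate = NULL) {
  first <- readLines(path, n = 4L)
  has_header <- grepl("^subject_id,", first[1L])
  subject_id <- NA_character_
  skip <- 0L
  if (has_header) {
    kv <- strsplit(first[1:3], ",")
    hdr <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    subject_id <- hdr[["subject_id"]]
    start_time <- start_time %||% as.POSIXct(hdr[["start_time"]], tz = "UTC")
    sample_rate <- sample_rate %||% as.numeric(hdr[["sample_rate"]])
    skip <- 4L   # three key-value lines plus the x,y,z header
  }
  if (is.null(start_time) || is.null(sample_rate))
    stop("headerless raw CSV requires `start_time` and `sample_rate`")
  d <- read.csv(path, header = FALSE, skip = skip,
                col.names = c("x", "y", "z"))
  out <- raw_accel(as.matrix(d), sample_rate = sample_rate, start_time = start_time)
  attr(out, "subject_id") <- subject_id
  out
}

#' Write / read an epoch series CSV
#'
#' Columns: `epoch_start` (ISO-8601, UTC), `value_mg`, `filter_kind`, and
#' `wear` when a wear mask is supplied.
#'
#' @param epochs an `epoch_series`.
#' @param path file path.
#' @param mask optional logical wear mask aligned to `epochs`.
#' @return `write_epoch_csv` returns `path` invisibly; `read_epoch_csv`
#'   returns an `epoch_series` (with attribute `wear` if the column exists).
#' @export
write_epoch_csv <- function(epochs, path, mask = NULL) {
  d <- data.frame(
    epoch_start = format(epochs$epoch_start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    value_mg = epochs$value_mg,
    filter_kind = attr(epochs, "filter_kind") %||% NA_character_
  )
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(epochs))
    d$wear <- mask
  }
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epoch_csv
#' @export
read_epoch_csv <- function(path) {
  d <- read.csv(path)
  out <- epoch_series(as.POSIXct(d$epoch_start, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                      d$value_mg, filter_kind = d$filter_kind[1L])
  if ("wear" %in% names(d)) attr(out, "wear") <- as.logical(d$wear)
  out
}
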