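# epoch-series builders used across test files

# epochs from a vector of mg values, 3 s apart, starting at a given clock time
make_epochs <- function(values, start = "2020-01-06 06:00:00", kind = "ag") {
  epoch_series(as.POSIXct(start, tz = "UTC") + 3 * (seq_along(values) - 1L),
               values, filter_kind = kind)
}

# n minutes of a constant mg value, as 3-s epochs (20 per minute)
minutes_of <- function(min, value) rep(value, min * 20L)

# a pure sine of amplitude `amp` (g) at `freq` Hz on the z axis, with gravity,
# long enough for `n_epochs` 3-s epochs at 30 Hz plus settling time
sine_raw <- function(freq, amp, n_epochs = 40, sample_rate = 30) {
  n <- n_epochs * 3 * sample_rate
  t <- seq_len(n) / sample_rate
  raw_accel(cbind(0, 0, 1 + amp * sin(2 * pi * freq * t)),
            sample_rate = sample_rate)
}

# steady-state epoch value (mg) for a sine processed under one arm: the mean
# over central epochs, away from filter edge effects
sine_epoch_value <- function(freq, amp, kind, n_epochs = 40) {
  raw <- sine_raw(freq, amp, n_epochs)
  eps <- process_raw(raw, kind)
  mean(eps$value_mg[10:(n_epochs - 10)])
}

# small random regression instance with optional planted column
random_instance <- function(n, p, seed, planted = NULL, noise = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- if (is.null(planted)) rnorm(n) else X[, planted] + rnorm(n, 0, noise)
  list(X = X, y = y)
}

# complete six-marker panel at given latent values (length n each)
flat_panel <- function(n = 4, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = paste0("S", seq_len(n)),
             sbp = rnorm(n, 123, 16), triglycerides = rlnorm(n, 0.1, 0.4),
             chol_hdl_ratio = rnorm(n, 3.6, 1), glucose = rnorm(n, 5.5, 0.5),
             insulin = rlnorm(n, 3.7, 0.5), waist_height = rnorm(n, 0.54, 0.06),
             fitness = rnorm(n, 33, 7))
}
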