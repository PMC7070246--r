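test_that("filter designs carry the stated corners and reject bad input", {
  ag <- design_filter("ag", 30)
  wide <- design_filter("wide", 30)
  expect_equal(ag$low_pass_corner, 1.6)
  expect_equal(wide$low_pass_corner, 10)
  expect_equal(ag$high_pass_corner, wide$high_pass_corner)
  expect_error(design_filter("counts", 30))
  expect_error(design_filter("ag", 20), "30 Hz")
  expect_error(design_filter("ag", 30, high_pass_corner = 2))
})

test_that("zero-phase gain: half-power at corners, narrow band rejects 5 Hz", {
  ag <- design_filter("ag", 30)
  wide <- design_filter("wide", 30)
  # Butterworth corner is the half-power point; squared for zero-phase
  expect_equal(filter_gain(ag, 1.6), 0.5, tolerance = 1e-6)
  expect_equal(filter_gain(wide, 10), 0.5, tolerance = 1e-6)
  expect_lt(filter_gain(ag, 5), 0.1)
  expect_gt(filter_gain(wide, 5), 0.9)
})

test_that("filtering removes gravity and scales sines by the designed gain", {
  for (kind in c("ag", "wide")) {
    spec <- design_filter(kind, 30)
    const <- matrix(rep(c(0, 0, 1), each = 3000), ncol = 3)
    out <- filter_signal(const, spec)
    expect_equal(dim(out), dim(const))
    expect_lt(max(abs(out)), 1e-5)
    # pure sines: steady-state RMS equals the gain oracle times A/sqrt(2)
    n <- 3600; t <- seq_len(n) / 30
    for (f in c(0.7, 5)) {
      filt <- filter_signal(cbind(0, 0, 1 + 0.1 * sin(2 * pi * f * t)), spec)
      rms <- sqrt(mean(filt[1000:2600, 3]^2))
      expect_equal(rms, 0.1 * filter_gain(spec, f) / sqrt(2),
                   tolerance = 0.01)
    }
  }
  expect_error(filter_signal(matrix(0, 5, 3), design_filter("ag", 30)),
               "warm-up")
})

test_that("a 5 Hz sine is attenuated by the narrow arm but kept by the wide arm", {
  rms_out <- function(kind) {
    n <- 3600; t <- seq_len(n) / 30
    filt <- filter_signal(cbind(0, 0, 1 + 0.1 * sin(2 * pi * 5 * t)),
                          design_filter(kind, 30))
    sqrt(mean(filt[1000:2600, 3]^2))
  }
  ideal <- 0.1 / sqrt(2)
  expect_lt(rms_out("ag"), 0.1 * ideal)
  expect_gt(rms_out("wide"), 0.9 * ideal)
})

test_that("epoch aggregation: means of the vector norm in mg, partials dropped", {
  z <- matrix(0, 90, 3)
  e1 <- epoch_aggregate(z, 30, 3)
  expect_equal(nrow(e1), 1L)
  expect_equal(e1$value_mg, 0)
  expect_equal(nrow(epoch_aggregate(matrix(0, 180, 3), 30, 3)), 2L)
  expect_equal(nrow(epoch_aggregate(matrix(0, 100, 3), 30, 3)), 1L)
  expect_error(epoch_aggregate(matrix(0, 0, 3), 30, 3))
  # |A sin| averaged over whole cycles is 2A/pi: 0.1 g -> 63.66 mg
  t <- seq_len(90) / 30
  s <- cbind(0.1 * sin(2 * pi * t), 0, 0)   # 1 Hz, 3 whole cycles
  expect_equal(epoch_aggregate(s, 30, 3)$value_mg, 200 / pi, tolerance = 0.01)
  # axis permutation invariance
  set.seed(42)
  X <- matrix(rnorm(270), 90, 3)
  expect_equal(epoch_aggregate(X, 30, 3)$value_mg,
               epoch_aggregate(X[, c(3, 1, 2)], 30, 3)$value_mg)
})

test_that("the whole raw chain is homogeneous of degree one", {
  set.seed(7)
  n <- 30 * 60
  raw <- raw_accel(cbind(rnorm(n, 0, 0.05), rnorm(n, 0, 0.05),
                         1 + rnorm(n, 0, 0.05)))
  for (kind in c("ag", "wide")) {
    e1 <- process_raw(raw, kind)
    e3 <- process_raw(raw_accel(raw$samples * 3), kind)
    expect_equal(e3$value_mg, 3 * e1$value_mg, tolerance = 1e-8)
  }
})

test_that("rising step frequency at fixed amplitude: wide keeps, narrow loses", {
  freqs <- seq(1, 3.5, by = 0.5)
  n <- 3600; t <- seq_len(n) / 30
  amp_out <- function(f, kind) {
    filt <- filter_signal(cbind(0, 0, 1 + 0.2 * sin(2 * pi * f * t)),
                          design_filter(kind, 30))
    sqrt(2 * mean(filt[1000:2600, 3]^2))
  }
  ag <- vapply(freqs, amp_out, 0, kind = "ag")
  wide <- vapply(freqs, amp_out, 0, kind = "wide")
  expect_true(all(diff(wide) > -0.005 * wide[1]))  # non-decreasing (flat passband)
  beyond <- freqs >= 2                             # beyond the 1.6 Hz corner
  expect_true(all(diff(ag[beyond]) < 0))           # strictly decreasing
})

test_that("raw and epoch CSV round-trips preserve the data", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,S001", "start_time,2020-01-06 06:00:00",
               "sample_rate,30", "x,y,z",
               apply(matrix(round(rnorm(30), 4), 10, 3), 1, paste, collapse = ",")),
             tmp)
  raw <- read_raw_csv(tmp)
  expect_s3_class(raw, "raw_accel")
  expect_equal(attr(raw, "subject_id"), "S001")
  expect_equal(raw$sample_rate, 30)
  expect_equal(nrow(raw$samples), 10L)

  eps <- make_epochs(c(0, 12.5, 250), kind = "wide")
  tmp2 <- tempfile(fileext = ".csv")
  write_epoch_csv(eps, tmp2, mask = c(TRUE, TRUE, FALSE))
  back <- read_epoch_csv(tmp2)
  expect_equal(back$value_mg, eps$value_mg)
  expect_equal(back$epoch_start, eps$epoch_start)
  expect_equal(attr(back, "filter_kind"), "wide")
  expect_equal(attr(back, "wear"), c(TRUE, TRUE, FALSE))
})

test_that("samples are clipped to the device range on ingest", {
  r <- raw_accel(matrix(c(10, -8, 2), 1, 3))
  expect_equal(as.numeric(r$samples), c(6, -6, 2))
})
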