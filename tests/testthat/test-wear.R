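test_that("night removal drops [00:00, 06:00) by epoch start, half-open", {
  eps <- make_epochs(rep(50, 3), start = "2020-01-06 05:59:54")
  # starts at 05:59:54, 05:59:57, 06:00:00
  out <- remove_night(eps)
  expect_equal(nrow(out), 1L)
  expect_equal(format(out$epoch_start, "%H:%M:%S"), "06:00:00")
  late <- make_epochs(rep(50, 2), start = "2020-01-06 23:59:57")
  # 23:59:57 retained, 00:00:00 removed
  expect_equal(nrow(remove_night(late)), 1L)
  mid <- make_epochs(50, start = "2020-01-06 03:00:00")
  expect_equal(nrow(remove_night(mid)), 0L)
})

test_that("60-min zero runs are non-wear; 59-min runs are not", {
  active <- minutes_of(5, 100)
  m61 <- make_epochs(c(active, minutes_of(61, 0), active))
  w61 <- detect_non_wear(m61)
  expect_false(any(w61[101:(100 + 61 * 20)]))
  expect_true(all(w61[1:100]))
  m59 <- make_epochs(c(active, minutes_of(59, 0), active))
  expect_true(all(detect_non_wear(m59)))
})

test_that("sub-threshold allowance: 2 min tolerated, 3 min breaks the window", {
  ok <- make_epochs(c(minutes_of(30, 0), minutes_of(2, 10), minutes_of(30, 0)))
  expect_false(any(detect_non_wear(ok)))        # whole 62-min span non-wear
  bad <- make_epochs(c(minutes_of(30, 0), minutes_of(3, 10), minutes_of(30, 0)))
  expect_true(all(detect_non_wear(bad)))        # no qualifying 60-min window
  # an epoch at the sedentary threshold terminates the window outright
  stopper <- make_epochs(c(minutes_of(30, 0), 19.1, minutes_of(30, 0)))
  expect_true(all(detect_non_wear(stopper)))
})

test_that("detection is idempotent and invariant to day concatenation", {
  d1 <- c(minutes_of(70, 0), minutes_of(30, 80))
  d2 <- c(minutes_of(20, 60), minutes_of(45, 0))
  e1 <- make_epochs(d1, start = "2020-01-06 08:00:00")
  e2 <- make_epochs(d2, start = "2020-01-07 08:00:00")
  joint <- epoch_series(c(e1$epoch_start, e2$epoch_start),
                        c(e1$value_mg, e2$value_mg))
  w_joint <- detect_non_wear(joint)
  expect_equal(w_joint, c(detect_non_wear(e1), detect_non_wear(e2)),
               ignore_attr = TRUE)
  # the 45-min zero tail of day 2 must not merge with day 1's zeros
  expect_true(all(tail(w_joint, 45 * 20)))
})

test_that("day validity: 8 h of wear epochs exactly meets the bar", {
  eps <- make_epochs(rep(30, 9600), start = "2020-01-06 06:00:00")
  d <- wear_time_by_day(eps, rep(TRUE, 9600))
  expect_equal(d$wear_hours, 8)
  expect_true(d$valid)
  d2 <- wear_time_by_day(eps, c(rep(TRUE, 9599), FALSE))
  expect_false(d2$valid)
  # empty day: all non-wear
  d3 <- wear_time_by_day(eps, rep(FALSE, 9600))
  expect_equal(d3$wear_hours, 0)
  expect_false(d3$valid)
})

test_that("a measurement needs at least four valid days", {
  mk <- function(valid) data.frame(date = as.Date("2020-01-06") + seq_along(valid),
                                   wear_hours = ifelse(valid, 9, 2), valid = valid)
  expect_true(is_valid_measurement(mk(rep(TRUE, 4))))
  expect_false(is_valid_measurement(mk(c(rep(TRUE, 3), rep(FALSE, 10)))))
  expect_false(is_valid_measurement(mk(logical(0))))
})

test_that("the AG mask applied to the wide series yields identical wear time", {
  ag <- make_epochs(c(minutes_of(65, 0), minutes_of(400, 40),
                      minutes_of(80, 0), minutes_of(100, 25)))
  wide <- make_epochs(c(minutes_of(65, 2), minutes_of(400, 160),
                        minutes_of(80, 1), minutes_of(100, 95)), kind = "wide")
  mask <- detect_non_wear(ag)
  expect_identical(attr(mask, "provenance"), "ag_reference")
  expect_equal(wear_time_by_day(ag, mask)$wear_hours,
               wear_time_by_day(wide, mask)$wear_hours)
})
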