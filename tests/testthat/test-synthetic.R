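test_that("a sedentary day stays below the sedentary threshold almost always", {
  prof <- activity_profile(60, "sedentary")
  eps <- process_raw(simulate_raw_day(prof, seed = 2), "ag")
  expect_gt(mean(eps$value_mg < 19.1), 0.99)
  expect_true(all(eps$value_mg > 0))     # fidgeting, not non-wear
})

test_that("running at 3 Hz step frequency: wide output far exceeds narrow", {
  speed <- (3 - 1.2) / 0.14              # speed whose step frequency is 3 Hz
  prof <- activity_profile(6, "run", speed = speed)
  raw <- simulate_raw_day(prof, seed = 4)
  ag <- median(process_raw(raw, "ag")$value_mg)
  wide <- median(process_raw(raw, "wide")$value_mg)
  expect_gt(wide / ag, 2)
})

test_that("a simulated 61-min non-wear gap is detected by the standard rule", {
  prof <- activity_profile(c(30, 61, 30), c("sedentary", "nonwear", "sedentary"))
  raw <- simulate_raw_day(prof, seed = 6)
  eps <- process_raw(raw, "ag")
  mask <- detect_non_wear(eps)
  inner <- 700:1750                      # well inside the 61-min gap
  expect_true(all(!mask[inner]))
  expect_true(all(mask[1:500]))
})

test_that("the raw generator and cohort generator are seed-deterministic", {
  prof <- activity_profile(c(5, 5), c("sedentary", "walk"), speed = c(0, 5))
  expect_identical(simulate_raw_day(prof, seed = 3)$samples,
                   simulate_raw_day(prof, seed = 3)$samples)
  sch <- make_bin_scheme("wide", 22)
  a <- simulate_cohort(cohort_truth(50, seed = 9), sch)
  b <- simulate_cohort(cohort_truth(50, seed = 9), sch)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$markers, b$markers)
  expect_identical(simulate_cohort_paired(30, seed = 2, n_bins = 10),
                   simulate_cohort_paired(30, seed = 2, n_bins = 10))
})

test_that("scheduled activity minutes survive the raw-to-spectrum pipeline", {
  prof <- activity_profile(c(100, 30, 10, 60),
                           c("sedentary", "walk", "run", "sedentary"),
                           speed = c(0, 5, 10, 0))
  raw <- simulate_raw_day(prof, seed = 8)
  eps <- process_raw(raw, "wide")
  # under the wide arm the classes map to well-separated value ranges:
  # sedentary ~5 mg, walking at 5 km/h ~165 mg, running at 10 km/h ~540 mg
  sed <- sum(eps$value_mg < 38.9) * 3 / 60
  walk <- sum(eps$value_mg >= 80 & eps$value_mg < 300) * 3 / 60
  run <- sum(eps$value_mg >= 400) * 3 / 60
  expect_equal(sed, 160, tolerance = 0.05)
  expect_equal(walk, 30, tolerance = 0.05)
  expect_equal(run, 10, tolerance = 0.05)
})

test_that("across running speeds the narrow arm reverses while the wide arm rises", {
  co <- simulate_cohort_paired(20, seed = 1)
  run <- co$speeds >= 8
  wide_vals <- co$speed_mg[run, "wide"]
  ag_vals <- co$speed_mg[run, "ag"]
  expect_true(all(diff(wide_vals) > 0))
  expect_true(all(diff(ag_vals) < 0))    # beyond the corner: reversed
  # and the wide arm's walking range stays monotone too
  expect_true(all(diff(co$speed_mg[, "wide"]) > 0))
})

test_that("the planted effect size is exact and markers recover the latent score", {
  sch <- make_bin_scheme("ag", 22)
  co <- simulate_cohort(cohort_truth(725, 15:18, 0.15, seed = 1), sch)
  expect_equal(cor(co$h, co$signal)^2, 0.15, tolerance = 1e-10)
  cs <- composite_score(co$markers)$cs
  expect_gt(cor(cs, co$h), 0.9)
  # effect_size 0: latent score uncorrelated with the planted minutes
  co0 <- simulate_cohort(cohort_truth(725, 15:18, 0, seed = 1), sch)
  expect_lt(abs(cor(co0$h, co0$signal)), 1e-10)
})

test_that("cohort spectra have declining participation and realistic wear", {
  sch <- make_bin_scheme("ag", 22)
  co <- simulate_cohort(cohort_truth(725, seed = 4), sch)
  pp <- participation_proportion(co$spectra)
  expect_true(all(pp[1:10] > 0.95))
  expect_true(all(diff(pp[12:22]) <= 0))
  expect_lt(pp[22], 0.15)
  wear_h <- rowSums(co$spectra) / 60
  expect_equal(mean(wear_h), 14.1, tolerance = 0.05)
  expect_true(all(co$spectra >= 0))
})

test_that("profile construction validates durations and classes", {
  expect_error(activity_profile(-5, "walk"))
  expect_error(activity_profile(5, "swim"))
})
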