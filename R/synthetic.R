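#' Locomotion maps: step frequency and movement amplitude versus speed
#'
#' The synthetic gait model represents each locomotion speed by a single
#' dominant sinusoid. Step frequency rises roughly linearly with speed
#' (about 1.4 Hz at slow walking to 3.4 Hz at fast running), which is the
#' mechanism that makes the narrow AG band plateau at running speeds while
#' the wide band keeps discriminating. Movement amplitude grows as a power
#' of speed, calibrated so that brisk walking lands near the moderate
#' cut-point of the wide arm and fast running near the top of its range.
#'
#' @param speed locomotion speed in km/h (0 = stationary).
#' @return `step_frequency()`: dominant frequency in Hz;
#'   `gait_amplitude()`: sinusoid amplitude in g.
#' @export
step_frequency <- function(speed) pmin(3.5, pmax(0.8, 1.2 + 0.14 * speed))

#' @rdname step_frequency
#' @export
gait_amplitude <- function(speed) 0.0166 * speed^1.71

#' Activity schedule for one simulated day
#'
#' A profile is a sequence of segments, each with a duration, an activity
#' class and (for locomotion) a speed. Classes: `"nonwear"` (device
#' off-body: constant gravity, zero dynamic signal), `"sedentary"` (small
#' incidental movement), `"walk"` and `"run"` (sinusoidal gait at the
#' class's step frequency and amplitude).
#'
#' @param duration_min segment durations in minutes (positive).
#' @param class segment classes, from the set above.
#' @param speed locomotion speed in km/h (ignored for nonwear/sedentary).
#' @return An object of class `activity_profile` (a data.frame).
#' @export
activity_profile <- function(duration_min, class, speed = 0) {
  class <- match.arg(class, c("nonwear", "sedentary", "walk", "run"),
                     several.ok = TRUE)
  d <- data.frame(duration_min = duration_min, class = class, speed = speed)
  if (any(d$duration_min <= 0)) stop("durations must be positive")
  structure(d, class = c("activity_profile", "data.frame"))
}

#' Simulate one day of raw tri-axial acceleration
#'
#' Generates a 30 Hz signal following an [activity_profile()]: gravity (1 g)
#' on the vertical axis plus, per segment, a sinusoid at the segment class's
#' step frequency and amplitude plus white noise. Non-wear segments carry
#' the constant gravity component only (exact zero dynamic signal), so the
#' standard non-wear detector finds them.
#'
#' @param profile an [activity_profile()].
#' @param seed integer seed.
#' @param sample_rate Hz (default 30).
#' @param noise_sd white-noise SD in g per axis (default 0.003 g = 3 mg);
#'   not applied to non-wear segments.
#' @param start_time timestamp of the first sample.
#' @return A `raw_accel` object.
#' @export
simulate_raw_day <- function(profile, seed = 1, sample_rate = 30,
                             noise_sd = 0.003,
                             start_time = as.POSIXct("2020-01-06 06:00:00", tz = "UTC")) {
  stopifnot(inherits(profile, "activity_profile"))
  set.seed(derive_seed(seed, 11L))
  segs <- lapply(seq_len(nrow(profile)), function(i) {
    n <- as.integer(round(profile$duration_min[i] * 60 * sample_rate))
    cls <- profile$class[i]
    if (cls == "nonwear")
      return(cbind(x = numeric(n), y = numeric(n), z = rep(1, n)))
    tim <- seq_len(n) / sample_rate
    if (cls == "sedentary") {
      amp <- 0.008; f <- 0.9       # fidgeting: ~5 mg at sub-gait frequency
    } else {
      amp <- gait_amplitude(profile$speed[i])
      f <- step_frequency(profile$speed[i])
    }
    ph <- runif(1, 0, 2 * pi)
    cbind(x = rnorm(n, 0, noise_sd),
          y = rnorm(n, 0, noise_sd),
          z = 1 + amp * sin(2 * pi * f * tim + ph) + rnorm(n, 0, noise_sd))
  })
  raw_accel(do.call(rbind, segs), sample_rate = sample_rate,
            start_time = start_time)
}

#' Ground truth for a simulated cohort
#'
#' @param n_subjects cohort size.
#' @param planted_bins integer indices of the bins carrying the planted
#'   health effect.
#' @param effect_size fraction of the latent health score's variance
#'   explained by minutes in the planted bins, in `[0, 1)`; made exact
#'   in-sample by orthogonalizing the noise against the signal.
#' @param seed master seed; all randomness in [simulate_cohort()] derives
#'   from it.
#' @param marker_cor target correlation of each generated marker with the
#'   latent health score (default 0.72, giving a composite-score correlation
#'   of about 0.93).
#' @param max_bin optional hard activity ceiling: no subject gets time in
#'   bins above this index.
#' @return An object of class `cohort_truth`.
#' @export
cohort_truth <- function(n_subjects = 725, planted_bins = 15:18,
                         effect_size = 0.15, seed = 1, marker_cor = 0.72,
                         max_bin = NULL) {
  if (effect_size < 0 || effect_size >= 1) stop("`effect_size` must be in [0, 1)")
  if (n_subjects < 10) stop("need at least 10 subjects")
  structure(list(n_subjects = as.integer(n_subjects),
                 planted_bins = as.integer(planted_bins),
                 effect_size = effect_size, seed = seed,
                 marker_cor = marker_cor, max_bin = max_bin),
            class = "cohort_truth")
}

# latent health score with exact in-sample planted effect size:
# h = sqrt(es) z(signal) + sqrt(1-es) z(noise orthogonal to signal)
plant_effect <- function(signal, effect_size, seed) {
  n <- length(signal)
  set.seed(derive_seed(seed, 23L))
  eps <- rnorm(n)
  if (sd(signal) == 0) return(as.numeric(scale(eps)))
  zs <- as.numeric(scale(signal))
  e_perp <- stats::residuals(stats::lm(eps ~ zs))
  ze <- as.numeric(scale(e_perp))
  sqrt(effect_size) * zs + sqrt(1 - effect_size) * ze
}

# six-marker panel as noisy affine transforms of the latent health score h
# (risk markers of -h, fitness of +h), on realistic clinical scales for a
# middle-aged adult cohort; glucose is drawn independently and insulin is
# back-computed so that the HOMA index carries the planted signal.
simulate_markers <- function(h, seed, rho = 0.72) {
  n <- length(h)
  set.seed(derive_seed(seed, 31L))
  u <- -as.numeric(scale(h))                 # standardized risk direction
  mk <- function(mean, sd, lo, direction = u)
    pmax(lo, mean + sd * (rho * direction + sqrt(1 - rho^2) * rnorm(n)))
  sbp <- mk(123.2, 16.6, 80)
  trig <- mk(1.20, 0.79, 0.3)
  chol <- mk(3.59, 1.16, 1.2)
  homa_t <- mk(2.11, 2.75, 0.2)
  waist <- mk(0.54, 0.06, 0.33)
  fitness <- mk(33.5, 7.4, 12, direction = -u)
  glucose <- pmax(3.5, rnorm(n, 5.5, 0.5))
  insulin <- homa_t * 22.5 / glucose
  data.frame(subject_id = sprintf("S%04d", seq_len(n)),
             sbp = sbp, triglycerides = trig, chol_hdl_ratio = chol,
             glucose = glucose, insulin = insulin,
             waist_height = waist, fitness = fitness)
}

#' Simulate a cohort of intensity spectra and marker panels
#'
#' Generates per-subject minutes-per-day spectra with the collinear,
#' right-skewed, zero-inflated structure of real time-in-bin data, and a
#' marker panel carrying a linear health effect confined to the chosen bins.
#'
#' The spectrum model: daily wear time is drawn around 14.1 h (SD 1.3 h);
#' active bins (3 and up) get log-normal minutes with geometrically decaying
#' means, a subject-level frailty, and a heavy-tailed per-subject activity
#' ceiling that zeroes high bins for most subjects, so that participation
#' (the fraction of subjects with any time in a bin) declines across the
#' vigorous range — about half the cohort reaches the lower very-vigorous
#' bins and under a tenth the last bin. Sedentary time fills bins 1-2 with
#' the remainder of wear time, so sedentary minutes trade off against active
#' minutes. The latent health score is
#' `h = sqrt(es) z(planted minutes) + sqrt(1-es) z(noise)` with the noise
#' orthogonalized so the in-sample planted effect size is exact; the six
#' markers are noisy affine transforms of `-h` (fitness of `+h`), so
#' [composite_score()] recovers approximately `h`.
#'
#' @param truth a [cohort_truth()].
#' @param scheme a [make_bin_scheme()].
#' @return List with `spectra` (n x n_bins minutes/day matrix), `markers`
#'   (data.frame for [composite_score()]), `h` (latent health score),
#'   `signal` (standardized planted minutes), `truth`, `scheme`.
#' @export
simulate_cohort <- function(truth, scheme) {
  stopifnot(inherits(truth, "cohort_truth"), inherits(scheme, "bin_scheme"))
  n <- truth$n_subjects
  K <- scheme$n_bins
  if (max(truth$planted_bins) > K) stop("planted bins outside the scheme")

  set.seed(derive_seed(truth$seed, 17L))
  wear <- pmin(1080, pmax(600, rnorm(n, 846, 78)))      # min/day, ~14.1 h
  frailty <- rlnorm(n, 0, 0.35)
  ceiling_bin <- pmin(K, 12L + floor(rexp(n, rate = 0.28)))
  if (!is.null(truth$max_bin)) ceiling_bin <- pmin(ceiling_bin, truth$max_bin)
  # subjects who ever reach vigorous bins are overall more active, so their
  # sedentary remainder shrinks: total volume scales with the ceiling
  volume <- frailty * exp(0.045 * (ceiling_bin - 12L))

  active_bins <- 3:K
  m <- 45 * 0.78^(active_bins - 3L)                     # mean minutes per bin
  noise <- matrix(rlnorm(n * length(active_bins), -0.45^2 / 2, 0.45),
                  n, length(active_bins))
  A <- (volume * noise) * rep(m, each = n)
  reach <- outer(ceiling_bin, active_bins, ">=")
  A <- A * reach

  spectra <- matrix(0, n, K, dimnames = list(NULL, scheme$labels))
  spectra[, active_bins] <- A
  active_total <- rowSums(A)
  sed <- pmax(60, wear - active_total)
  share1 <- runif(n, 0.68, 0.82)
  spectra[, 1L] <- sed * share1
  spectra[, 2L] <- sed * (1 - share1)

  signal <- rowSums(spectra[, truth$planted_bins, drop = FALSE])
  h <- plant_effect(signal, truth$effect_size, truth$seed)
  markers <- simulate_markers(h, truth$seed, truth$marker_cor)

  list(spectra = spectra, markers = markers, h = h,
       signal = if (sd(signal) > 0) as.numeric(scale(signal)) else signal,
       truth = truth, scheme = scheme)
}

#' Simulate a paired-arm cohort through the filter mechanism
#'
#' Generates a cohort at the level of time spent at each locomotion speed,
#' then maps every speed to the epoch output (mg) it would produce under
#' each processing arm, using the actual designed filters: output =
#' mean rectified sinusoid (2A/pi, in mg) times the arm's zero-phase gain at
#' the speed's step frequency. Because the narrow AG band attenuates high
#' step frequencies, fast running maps to modest AG values but large wide
#' values — the same physical activity lands at different relative positions
#' in the two arms' spectra, which is the mechanism under study. A health
#' effect is planted on minutes at or above `min_effect_speed`, and markers
#' are generated as in [simulate_cohort()].
#'
#' @param n_subjects cohort size.
#' @param effect_size planted effect size in `[0, 1)`.
#' @param seed master seed.
#' @param n_bins bins per arm scheme.
#' @param min_effect_speed speed (km/h) from which minutes count towards the
#'   latent health score (default 8, the walk-run transition).
#' @param marker_cor see [cohort_truth()].
#' @return List with `ag` and `wide` (each: `spectra`, `scheme`,
#'   `cutpoints`), `markers`, `h`, `speeds`, `speed_mg` (per-speed mg under
#'   each arm), `minutes_by_speed` (n x speeds matrix), `seed`.
#' @export
simulate_cohort_paired <- function(n_subjects = 100, effect_size = 0.15,
                                   seed = 1, n_bins = 22,
                                   min_effect_speed = 8, marker_cor = 0.72) {
  if (effect_size < 0 || effect_size >= 1) stop("`effect_size` must be in [0, 1)")
  if (n_subjects < 10) stop("need at least 10 subjects")
  speeds <- c(0, 1.5, 2.5, 3.5, 4.5, 5.5, 6.5, 8, 9.5, 11, 12.5, 14, 16)
  mean_min <- c(NA, 40, 50, 55, 45, 25, 12, 4, 2.5, 1.5, 0.8, 0.4, 0.2)
  run_idx <- which(speeds >= 8)

  spec_ag <- design_filter("ag", 30)
  spec_wide <- design_filter("wide", 30)
  amp <- gait_amplitude(speeds)
  fstep <- step_frequency(speeds)
  mg <- function(spec) (2 / pi) * 1000 * amp * filter_gain(spec, fstep)
  speed_mg <- cbind(ag = mg(spec_ag), wide = mg(spec_wide))
  speed_mg[1L, ] <- c(5, 15)        # stationary: incidental movement only

  n <- n_subjects
  set.seed(derive_seed(seed, 41L))
  wear <- pmin(1080, pmax(600, rnorm(n, 846, 78)))
  frailty <- rlnorm(n, 0, 0.25)
  # heavy-tailed top-speed ceiling: most walk, some jog, few run fast
  ceiling_idx <- pmin(length(speeds), 7L + floor(rexp(n, rate = 0.5)))
  minutes <- matrix(0, n, length(speeds))
  for (j in 2:length(speeds)) {
    lam <- frailty * mean_min[j] * rlnorm(n, -0.32, 0.8)
    minutes[, j] <- lam * (ceiling_idx >= j)
  }
  minutes[, 1L] <- pmax(60, wear - rowSums(minutes[, -1L]))

  signal <- rowSums(minutes[, run_idx[speeds[run_idx] >= min_effect_speed],
                            drop = FALSE])
  h <- plant_effect(signal, effect_size, seed)
  markers <- simulate_markers(h, seed, marker_cor)

  set.seed(derive_seed(seed, 43L))
  jitter <- matrix(rlnorm(n * length(speeds), 0, 0.12), n, length(speeds))

  arm <- function(kind) {
    scheme <- make_bin_scheme(kind, n_bins)
    vals <- sweep(jitter, 2L, speed_mg[, kind], "*")
    spectra <- matrix(0, n, n_bins, dimnames = list(NULL, scheme$labels))
    for (i in seq_len(n)) {
      idx <- bin_index(vals[i, ], scheme)
      for (j in seq_along(idx))
        spectra[i, idx[j]] <- spectra[i, idx[j]] + minutes[i, j]
    }
    list(spectra = spectra, scheme = scheme, cutpoints = met_cutpoints(kind))
  }

  list(ag = arm("ag"), wide = arm("wide"), markers = markers, h = h,
       speeds = speeds, speed_mg = speed_mg, minutes_by_speed = minutes,
       seed = seed)
}
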