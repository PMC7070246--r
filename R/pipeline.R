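#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis with its default, so a
#' whole run is reproducible from one object. Defaults are the package's
#' standard analysis conditions: 3-s epochs, 22 bins, the 19.1 mg sedentary
#' threshold, 60-min non-wear window with 2-min allowance, 8-h valid days,
#' 4 valid days per measurement, 100 Monte Carlo half-splits.
#'
#' @param filters which processing arms to run.
#' @param epoch_length epoch duration, seconds.
#' @param n_bins bins per intensity spectrum.
#' @param sedentary_threshold mg; also the non-wear allowance ceiling.
#' @param nonwear_min minimum non-wear window, minutes.
#' @param allowance_min sub-threshold allowance inside a window, minutes.
#' @param zero_tol mg value at or below which an epoch counts as zero.
#' @param min_wear_hours hours of wear for a valid day.
#' @param min_valid_days valid days for a valid measurement.
#' @param max_components,reps,seed PLS/Monte Carlo settings (see [sr_pls()]).
#' @param high_pass_corner gravity-removal corner, Hz.
#' @return A list of class `accel_config`.
#' @export
accel_config <- function(filters = c("ag", "wide"), epoch_length = 3,
                         n_bins = 22, sedentary_threshold = 19.1,
                         nonwear_min = 60, allowance_min = 2,
                         zero_tol = 1e-6, min_wear_hours = 8,
                         min_valid_days = 4, max_components = 10,
                         reps = 100, seed = 1, high_pass_corner = 0.29) {
  filters <- match.arg(filters, c("ag", "wide"), several.ok = TRUE)
  stopifnot(epoch_length > 0, n_bins >= 3, sedentary_threshold > 0,
            nonwear_min > 0, allowance_min >= 0, zero_tol >= 0,
            min_wear_hours > 0, min_valid_days >= 1,
            max_components >= 1, reps >= 2)
  structure(as.list(environment()), class = "accel_config")
}

#' @export
print.accel_config <- function(x, ...) {
  cat("<accel_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

#' Process one subject's raw days through both arms
#'
#' Runs the per-subject chain: filter each day's raw signal under the AG and
#' wide arms, aggregate to epochs, remove night time, detect non-wear on the
#' AG series (the reference arm), apply that one mask to both arms, check
#' day/measurement validity, and build the per-arm intensity spectra and
#' MET-class minutes.
#'
#' @param raw_days list of `raw_accel` objects, one per day.
#' @param config an [accel_config()].
#' @return List with `valid` (logical), `days` (per-day summary), and per
#'   requested arm a list with `spectrum` ([time_in_bins()] result),
#'   `met_minutes`, `epochs`, `mask`. Invalid measurements return
#'   `valid = FALSE` with `days` only.
#' @export
process_subject <- function(raw_days, config = accel_config()) {
  stopifnot(length(raw_days) >= 1L)
  one_arm <- function(kind) {
    eps <- lapply(raw_days, process_raw, kind = kind,
                  epoch_length = config$epoch_length,
                  high_pass_corner = config$high_pass_corner)
    all <- do.call(rbind, eps)
    remove_night(epoch_series(all$epoch_start, all$value_mg,
                              filter_kind = kind,
                              epoch_length = config$epoch_length))
  }
  ag <- one_arm("ag")
  mask <- detect_non_wear(ag, config$sedentary_threshold, config$nonwear_min,
                          config$allowance_min, config$zero_tol)
  days <- wear_time_by_day(ag, mask, config$min_wear_hours)
  if (!is_valid_measurement(days, config$min_valid_days))
    return(list(valid = FALSE, days = days))
  out <- list(valid = TRUE, days = days)
  for (kind in config$filters) {
    eps <- if (kind == "ag") ag else one_arm(kind)
    if (nrow(eps) != length(mask))
      stop("arm series misaligned with the AG wear mask")
    scheme <- make_bin_scheme(kind, config$n_bins)
    out[[kind]] <- list(
      spectrum = time_in_bins(eps, mask, scheme, days),
      met_minutes = met_class_minutes(eps, mask, met_cutpoints(kind), days),
      epochs = eps, mask = mask
    )
  }
  out
}

#' MET-class minutes from an already-binned spectrum
#'
#' Coarsens a time-in-bin spectrum to the five intensity classes by
#' assigning every bin to the class of its lower edge. Because bin edges
#' only approximately align with the cut-points this is an approximation of
#' epoch-level classification, but it conserves total minutes exactly.
#'
#' @param spectra n x n_bins minutes matrix (or one spectrum vector).
#' @param scheme the [make_bin_scheme()] the spectra were built with.
#' @param cutpoints [met_cutpoints()] for the same arm.
#' @return n x 5 matrix of minutes/day in SED, LPA, MPA, VPA, VVPA.
#' @export
spectrum_met_minutes <- function(spectra, scheme, cutpoints) {
  M <- if (is.matrix(spectra)) spectra else matrix(spectra, nrow = 1L)
  cls <- findInterval(scheme$edges, cutpoints) + 1L
  out <- sapply(1:5, function(k) rowSums(M[, cls == k, drop = FALSE]))
  out <- matrix(out, nrow = nrow(M), dimnames = list(NULL, met_class_names))
  out
}

#' Run the full spectrum-health analysis
#'
#' Orchestrates the cohort-level analysis for each processing arm: assemble
#' the spectrum matrix, compute the cardiometabolic composite score
#' (complete-case), fit the PLS / target-projection / selectivity-ratio
#' model with Monte Carlo component selection and confidence intervals,
#' compute participation proportions and cohort descriptives, and optionally
#' write selectivity-ratio plots and a results JSON.
#'
#' @param cohort either a paired cohort from [simulate_cohort_paired()], or
#'   a list with element `markers` plus one element per arm named `"ag"` /
#'   `"wide"`, each a list with `spectra` (matrix or list of
#'   `intensity_spectrum`) and `scheme`. `NULL` simulates a paired cohort of
#'   `n_subjects` with the configured seed.
#' @param config an [accel_config()].
#' @param out_dir optional directory; when given, per-arm selectivity-ratio
#'   plots (`sr_<arm>.png`) and `results.json` are written there.
#' @param n_subjects cohort size when simulating (`cohort = NULL`).
#' @param effect_size planted effect size when simulating.
#' @param quiet suppress progress messages.
#' @return A list of class `pipeline_result`: per arm, the `sr_pls` fit,
#'   participation proportions, scheme and peak position on the MET scale;
#'   plus `scores` (markers with composite score), `descriptives`,
#'   `n_excluded`, `config`.
#' @export
run_pipeline <- function(cohort = NULL, config = accel_config(),
                         out_dir = NULL, n_subjects = 100,
                         effect_size = 0.15, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(cohort)) {
    say("simulating paired cohort: n = %d, effect size %.2f, seed %d",
        n_subjects, effect_size, config$seed)
    cohort <- simulate_cohort_paired(n_subjects, effect_size,
                                     seed = config$seed,
                                     n_bins = config$n_bins)
  }
  arms <- intersect(config$filters, names(cohort))
  if (length(arms) == 0L) stop("cohort contains none of the configured arms")

  scored <- composite_score(cohort$markers)
  n_excluded <- attr(scored, "n_excluded")
  keep <- match(scored$subject_id, cohort$markers$subject_id)
  if (n_excluded > 0)
    say("excluded %d subject(s) with incomplete markers", n_excluded)
  if (nrow(scored) < 10L) stop("fewer than 10 subjects with complete data")

  out <- list(config = config, scores = scored, n_excluded = n_excluded)
  met_tabs <- list()
  for (kind in arms) {
    a <- cohort[[kind]]
    M <- spectrum_matrix(a$spectra)[keep, , drop = FALSE]
    scheme <- a$scheme
    cp <- met_cutpoints(kind)
    fit <- sr_pls(M, scored$cs, max_components = config$max_components,
                  reps = config$reps, seed = config$seed,
                  cutpoints = cp, bin_values = scheme$edges)
    peak <- which.max(abs(fit$sr))
    out[[kind]] <- list(
      fit = fit, scheme = scheme, cutpoints = cp,
      participation = participation_proportion(M),
      peak_bin = peak,
      peak_met_position = met_position(scheme$edges[peak], cp)
    )
    met_tabs[[kind]] <- spectrum_met_minutes(M, scheme, cp)
    say("%s arm: %d component(s), R2 = %.1f%%, peak |SR| at bin %d (%s)",
        toupper(kind), fit$ncomp, 100 * fit$r_squared, peak,
        scheme$labels[peak])
  }
  out$descriptives <- describe_cohort(scored, met_tabs)
  class(out) <- "pipeline_result"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (kind in arms) {
      png(file.path(out_dir, sprintf("sr_%s.png", kind)),
          width = 1000, height = 600)
      plot(out[[kind]]$fit,
           main = sprintf("Selectivity ratios, %s arm", toupper(kind)))
      dev.off()
    }
    res <- lapply(arms, function(kind) {
      a <- out[[kind]]
      list(ncomp = a$fit$ncomp, r_squared = a$fit$r_squared,
           r_squared_ci = as.numeric(a$fit$r_squared_ci),
           sr = as.list(a$fit$sr), sr_ci_low = as.numeric(a$fit$sr_ci[1L, ]),
           sr_ci_high = as.numeric(a$fit$sr_ci[2L, ]),
           bin_edges = a$scheme$edges, cutpoints = as.list(a$cutpoints),
           participation = as.numeric(a$participation),
           peak_bin = a$peak_bin, peak_met_position = a$peak_met_position)
    })
    names(res) <- arms
    jsonlite::write_json(res, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA)
    say("wrote plots and results.json to %s", out_dir)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat(sprintf("  subjects analyzed: %d (excluded: %d)\n",
              nrow(x$scores), x$n_excluded))
  for (kind in intersect(c("ag", "wide"), names(x))) {
    a <- x[[kind]]
    cat(sprintf("  %-4s: %d comp, R2 %.1f%% (CI %.1f-%.1f%%), peak |SR| bin %d, MET position %.2f\n",
                toupper(kind), a$fit$ncomp, 100 * a$fit$r_squared,
                100 * a$fit$r_squared_ci[1], 100 * a$fit$r_squared_ci[2],
                a$peak_bin, a$peak_met_position))
  }
  invisible(x)
}

#' Cohort descriptive summary
#'
#' Mean and SD for each cardiometabolic marker (plus the HOMA index and
#' composite score) and, when supplied, the per-arm MET-class minutes and
#' wear statistics. With a single subject the SD is reported as `NA`.
#'
#' @param scored marker data.frame, ideally from [composite_score()] (so
#'   `homa` and `cs` are included).
#' @param met_minutes optional named list of n x 5 MET-minute matrices, one
#'   per arm (see [spectrum_met_minutes()]).
#' @param days optional data.frame with per-subject `valid_days` and
#'   `wear_hours`.
#' @return data.frame with columns `variable`, `mean`, `sd`.
#' @export
describe_cohort <- function(scored, met_minutes = NULL, days = NULL) {
  stopifnot(nrow(scored) >= 1L)
  num <- scored[vapply(scored, is.numeric, TRUE)]
  rows <- data.frame(variable = names(num),
                     mean = vapply(num, mean, 0),
                     sd = if (nrow(scored) > 1L) vapply(num, sd, 0) else NA_real_)
  if (!is.null(days)) {
    for (v in intersect(c("valid_days", "wear_hours"), names(days)))
      rows <- rbind(rows, data.frame(variable = v, mean = mean(days[[v]]),
                                     sd = if (nrow(days) > 1L) sd(days[[v]]) else NA_real_))
  }
  if (!is.null(met_minutes)) {
    for (kind in names(met_minutes)) {
      M <- met_minutes[[kind]]
      rows <- rbind(rows, data.frame(
        variable = paste0(kind, "_", tolower(colnames(M))),
        mean = colMeans(M),
        sd = if (nrow(M) > 1L) apply(M, 2L, sd) else NA_real_))
    }
  }
  rownames(rows) <- NULL
  rows
}
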