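#' Fit the spectrum-health association model
#'
#' The package's central model: a partial least squares regression of a
#' response (typically the cardiometabolic composite score) on a collinear
#' predictor matrix (typically the time-in-bin intensity spectrum), collapsed
#' to one predictive component by target projection and summarized as signed
#' per-bin selectivity ratios. The number of PLS components is chosen by
#' Monte Carlo resampling: `reps` random half-splits, the count minimizing
#' the median held-out RMSE wins. The same draws give 95% percentile
#' confidence intervals for the selectivity ratios and for the explained
#' variance R-squared. All predictors and the response are standardized
#' before fitting (the full-data fit uses full-data statistics; each
#' resampling fit recomputes them on its own training half).
#'
#' @param x numeric n x p predictor matrix (e.g. from [spectrum_matrix()]),
#'   raw scale.
#' @param y numeric length-n response, raw scale.
#' @param max_components largest component count considered (default 10,
#'   capped at `min(n/2 - 1, p)`).
#' @param reps Monte Carlo repetitions (default 100).
#' @param seed integer seed governing all half-splits.
#' @param ci_level confidence level for percentile intervals.
#' @param cutpoints optional [met_cutpoints()] vector, stored for plotting.
#' @param bin_values optional numeric vector of bin lower edges (mg), stored
#'   for plotting and peak location.
#' @return An object of class `sr_pls`: list with elements `ncomp`,
#'   `sr` (signed selectivity ratios), `sr_ci` (2 x p), `r_squared`,
#'   `r_squared_ci`, `coefficients` (standardized scale), `pls`, `tp`,
#'   `mccv`, `center`/`scale`/`y_center`/`y_scale`, `fitted.values`,
#'   `residuals`, `call`.
#' @seealso [plot.sr_pls()], [summary.sr_pls()], [mccv_select()]
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rlnorm(200 * 8), 200, 8)
#' y <- scale(X[, 3])[, 1] + rnorm(200)
#' fit <- sr_pls(X, y, max_components = 4, reps = 25, seed = 1)
#' which.max(abs(fit$sr))   # 3
sr_pls <- function(x, y, max_components = 10, reps = 100, seed = 1,
                   ci_level = 0.95, cutpoints = NULL, bin_values = NULL) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  stopifnot(length(y) == n)
  if (n < 10L) stop("need at least 10 subjects")
  if (is.null(colnames(x))) colnames(x) <- paste0("bin", seq_len(ncol(x)))
  max_components <- min(max_components, n %/% 2L - 1L, ncol(x))

  sx <- standardize_columns(x)
  y_center <- mean(y); y_scale <- sd(y)
  if (!is.finite(y_scale) || y_scale == 0) stop("response has zero variance")
  yz <- (y - y_center) / y_scale

  full0 <- pls_nipals(sx$Z, yz, max_components)
  if (full0$ncomp == 0L) stop("response is orthogonal to all predictors; null model")
  align <- full0$b / sqrt(sum(full0$b^2))

  mc <- mccv_select(x, y, max_components, reps = reps, seed = seed,
                    align_to = align)

  fit <- pls_nipals(sx$Z, yz, mc$ncomp)
  tp <- target_projection(fit, sx$Z, yz)
  sr <- selectivity_ratio(tp, sx$Z)
  names(sr) <- colnames(x)
  fitted_z <- fit$fitted
  r2 <- 1 - sum((yz - fitted_z)^2) / sum((yz - mean(yz))^2)

  structure(list(
    ncomp = mc$ncomp,
    sr = sr,
    sr_ci = percentile_ci(mc$sr_draws, ci_level),
    r_squared = r2,
    r_squared_ci = percentile_ci(mc$r2_train_draws, ci_level),
    coefficients = stats::setNames(fit$b, colnames(x)),
    pls = fit, tp = tp, mccv = mc,
    center = sx$center, scale = sx$scale,
    y_center = y_center, y_scale = y_scale,
    fitted.values = y_center + y_scale * fitted_z,
    residuals = y - (y_center + y_scale * fitted_z),
    y = y, ci_level = ci_level,
    cutpoints = cutpoints, bin_values = bin_values,
    call = match.call()
  ), class = "sr_pls")
}

#' @export
print.sr_pls <- function(x, ...) {
  cat("Spectrum PLS with target projection and selectivity ratios\n")
  cat(sprintf("  %d predictor(s), n = %d, %d PLS component(s) (Monte Carlo, %d half-splits)\n",
              length(x$sr), length(x$y), x$ncomp, x$mccv$reps))
  cat(sprintf("  R-squared: %.1f%% (%.0f%% CI %.1f-%.1f%%)\n",
              100 * x$r_squared, 100 * x$ci_level,
              100 * x$r_squared_ci[1], 100 * x$r_squared_ci[2]))
  pk <- which.max(abs(x$sr))
  cat(sprintf("  Peak |selectivity ratio|: %s (SR = %.3f)\n",
              names(x$sr)[pk], x$sr[pk]))
  invisible(x)
}

#' Summarize a fitted spectrum PLS model
#'
#' @param object an `sr_pls` fit.
#' @param ... unused.
#' @return An object of class `summary.sr_pls` with a per-bin table of
#'   signed selectivity ratios and confidence bounds.
#' @export
summary.sr_pls <- function(object, ...) {
  tab <- data.frame(
    bin = names(object$sr),
    sr = unname(object$sr),
    ci_low = object$sr_ci[1L, ],
    ci_high = object$sr_ci[2L, ],
    coefficient = unname(object$coefficients),
    row.names = NULL
  )
  structure(list(table = tab, ncomp = object$ncomp,
                 r_squared = object$r_squared,
                 r_squared_ci = object$r_squared_ci,
                 ci_level = object$ci_level, n = length(object$y)),
            class = "summary.sr_pls")
}

#' @export
print.summary.sr_pls <- function(x, digits = 3, ...) {
  cat(sprintf("Spectrum PLS: %d component(s), n = %d\n", x$ncomp, x$n))
  cat(sprintf("R-squared %.1f%% (%.0f%% CI %.1f-%.1f%%)\n\n",
              100 * x$r_squared, 100 * x$ci_level,
              100 * x$r_squared_ci[1], 100 * x$r_squared_ci[2]))
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Coefficients of a spectrum PLS fit
#'
#' @param object an `sr_pls` fit.
#' @param standardized if `TRUE`, coefficients on the standardized scale on
#'   which the model was fitted; otherwise (default) on the original scales,
#'   with an `(Intercept)` term.
#' @param ... unused.
#' @return Named numeric vector.
#' @export
coef.sr_pls <- function(object, standardized = FALSE, ...) {
  if (standardized) return(object$coefficients)
  sc <- ifelse(object$scale > 0, object$scale, 1)
  b <- object$y_scale * object$coefficients / sc
  c("(Intercept)" = object$y_center - sum(b * object$center), b)
}

#' Predict from a spectrum PLS fit
#'
#' @param object an `sr_pls` fit.
#' @param newdata numeric matrix with the same columns as the training
#'   spectrum (raw scale); omitted means the training data.
#' @param ... unused.
#' @return Numeric vector of predictions on the response's original scale.
#' @export
predict.sr_pls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  Z <- standardize_columns(as.matrix(newdata), object$center, object$scale)$Z
  as.numeric(object$y_center + object$y_scale * (Z %*% object$coefficients))
}

#' @export
fitted.sr_pls <- function(object, ...) object$fitted.values

#' @export
residuals.sr_pls <- function(object, ...) object$residuals

#' Simulate responses from a spectrum PLS fit
#'
#' Draws `nsim` response vectors as fitted values plus Gaussian noise with
#' the residual standard deviation.
#'
#' @param object an `sr_pls` fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns.
#' @export
simulate.sr_pls <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- sd(object$residuals)
  n <- length(object$fitted.values)
  out <- as.data.frame(replicate(nsim, object$fitted.values + rnorm(n, 0, s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Selectivity-ratio plot
#'
#' Bar plot of the signed selectivity ratio per intensity bin with
#' confidence-interval whiskers, annotated with the MET-anchored intensity
#' classes when cut-points are available (stored in the fit or passed here).
#' Positive bars: more time at that intensity is associated with a higher
#' response (better health when the response is the composite score).
#'
#' @param x an `sr_pls` fit.
#' @param cutpoints optional [met_cutpoints()] vector (overrides the stored
#'   one).
#' @param bin_values optional bin lower edges in mg (overrides stored).
#' @param main plot title.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.sr_pls <- function(x, cutpoints = NULL, bin_values = NULL,
                        main = "Selectivity ratio by intensity bin", ...) {
  sr <- x$sr
  ci <- x$sr_ci
  cutpoints <- cutpoints %||% x$cutpoints
  bin_values <- bin_values %||% x$bin_values
  ylim <- range(0, sr, ci, finite = TRUE) * 1.15
  mids <- barplot(sr, ylim = ylim, las = 2, main = main,
                  ylab = "selectivity ratio (signed)",
                  col = ifelse(sr >= 0, "grey35", "grey75"),
                  border = NA, cex.names = 0.6, ...)
  ok <- is.finite(ci[1L, ]) & is.finite(ci[2L, ]) & (ci[2L, ] > ci[1L, ])
  if (any(ok))
    arrows(mids[ok], ci[1L, ok], mids[ok], ci[2L, ok],
           angle = 90, code = 3, length = 0.02, col = "grey10")
  abline(h = 0)
  if (!is.null(cutpoints) && !is.null(bin_values)) {
    # first bin at or above each cut-point marks a class boundary
    for (k in seq_along(cutpoints)) {
      j <- which(bin_values >= cutpoints[k])[1L]
      if (!is.na(j)) abline(v = mids[j] - (mids[2] - mids[1]) / 2,
                            lty = 3, col = "grey40")
    }
    lab_pos <- c(0, vapply(cutpoints, function(cp) {
      j <- which(bin_values >= cp)[1L]
      if (is.na(j)) NA_real_ else mids[j]
    }, numeric(1)))
    cls <- c("SED", "LPA", "MPA", "VPA", "VVPA")
    usable <- !is.na(lab_pos)
    mtext(cls[usable], side = 3, at = lab_pos[usable], cex = 0.7, line = 0.2)
  }
  invisible(mids)
}
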