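#' Monte Carlo cross-validation for PLS component selection
#'
#' Repeatedly splits the sample in random halves (without replacement), fits
#' PLS models with 1..`max_components` components on one half and evaluates
#' the root mean squared prediction error on the held-out half. The number
#' of components with the lowest median RMSE across repetitions is selected.
#' Standardization statistics are recomputed inside each training half, so
#' no information leaks from the held-out half. The same splits then provide
#' per-repetition draws of the selectivity-ratio vector and of R-squared at
#' the selected component count, from which percentile confidence intervals
#' are built (see [sr_pls()]).
#'
#' Columns that are constant within a training half stay in the model as
#' all-zero standardized columns; their selectivity ratio is recorded as 0
#' for that draw.
#'
#' @param X numeric n x p matrix of predictors (raw scale).
#' @param y numeric response (raw scale).
#' @param max_components largest component count to try.
#' @param reps number of random half-splits (default 100).
#' @param seed integer seed; the full set of splits is a deterministic
#'   function of it.
#' @param align_to optional unit vector; each draw's selectivity-ratio signs
#'   are flipped when its target-projection weight points away from it
#'   (guards against component sign indeterminacy across draws).
#' @return List with `ncomp` (selected), `rmse` (reps x max_components),
#'   `median_rmse` (per component count), `sr_draws` (reps x p, signed, at
#'   the selected count), `r2_train_draws`, `r2_holdout_draws` (length
#'   `reps`, at the selected count), `reps`, `seed`.
#' @export
mccv_select <- function(X, y, max_components, reps = 100, seed = 1,
                        align_to = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 10L) stop("need at least 10 samples for half-split resampling")
  if (reps < 2L) stop("`reps` must be at least 2")
  n_train <- n %/% 2L
  max_components <- min(max_components, n_train - 1L, p)

  set.seed(derive_seed(seed, 101L))
  splits <- lapply(seq_len(reps), function(r) sample.int(n, n_train))

  rmse <- matrix(NA_real_, reps, max_components)
  fits <- vector("list", reps)
  for (r in seq_len(reps)) {
    tr <- splits[[r]]
    sx <- standardize_columns(X[tr, , drop = FALSE])
    ym <- mean(y[tr]); ys <- sd(y[tr])
    yz <- (y[tr] - ym) / ys
    fit <- pls_nipals(sx$Z, yz, max_components)
    Zte <- standardize_columns(X[-tr, , drop = FALSE], sx$center, sx$scale)$Z
    pred <- ym + ys * (Zte %*% fit$B)        # one column per component count
    rmse[r, ] <- sqrt(colMeans((y[-tr] - pred)^2))
    fits[[r]] <- list(fit = fit, sx = sx, yz = yz, ym = ym, ys = ys, tr = tr)
  }
  med <- apply(rmse, 2L, median)
  ncomp <- which.min(med)

  sr_draws <- matrix(0, reps, p, dimnames = list(NULL, colnames(X)))
  r2_train <- numeric(reps); r2_hold <- numeric(reps)
  for (r in seq_len(reps)) {
    f <- fits[[r]]
    b <- f$fit$B[, ncomp]
    if (sum(b^2) > 1e-20) {
      sub <- f$fit; sub$b <- b
      tp <- target_projection(sub, f$sx$Z, f$yz)
      if (!is.null(align_to) && sum(tp$tp_weight * align_to) < 0) {
        tp$tp_weight <- -tp$tp_weight; tp$t_tp <- -tp$t_tp; tp$p_tp <- -tp$p_tp
      }
      sr_draws[r, ] <- selectivity_ratio(tp, f$sx$Z)
    }
    yhat_tr <- f$sx$Z %*% b
    r2_train[r] <- 1 - sum((f$yz - yhat_tr)^2) / sum(f$yz^2)
    Zte <- standardize_columns(X[-f$tr, , drop = FALSE], f$sx$center, f$sx$scale)$Z
    pred <- f$ym + f$ys * (Zte %*% b)
    yte <- y[-f$tr]
    r2_hold[r] <- 1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
  }
  list(ncomp = ncomp, rmse = rmse, median_rmse = med, sr_draws = sr_draws,
       r2_train_draws = r2_train, r2_holdout_draws = r2_hold,
       reps = reps, seed = seed)
}

#' Percentile confidence interval from resampling draws
#'
#' Central interval at level `level` using linear interpolation between order
#' statistics ([stats::quantile()] type 7). Identical draws give a zero-width
#' interval at the common value.
#'
#' @param draws numeric vector (or matrix; columns summarized separately).
#' @param level coverage (default 0.95).
#' @return For a vector, `c(lower, upper)`; for a matrix, a 2-row matrix.
#' @export
percentile_ci <- function(draws, level = 0.95) {
  a <- (1 - level) / 2
  if (is.matrix(draws)) {
    apply(draws, 2L, quantile, probs = c(a, 1 - a), names = FALSE, type = 7)
  } else {
    quantile(draws, probs = c(a, 1 - a), names = FALSE, type = 7)
  }
}
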