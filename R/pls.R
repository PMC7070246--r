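#' NIPALS partial least squares for a univariate response
#'
#' Fits PLS components on a standardized predictor matrix and response by the
#' NIPALS algorithm. Per component: `w = X'y / ||X'y||`, `t = Xw`,
#' `p = X't/(t't)`, `q = y't/(t't)`, then `X <- X - t p'`. The regression
#' vector over the standardized predictors is assembled as
#' `b = W (P'W)^-1 q`. Each component maximizes covariance of its score with
#' the response among directions orthogonal (in score space) to earlier
#' components, which is what makes the fit stable under the strong
#' collinearity of time-in-bin spectra. If the residual covariance `X'y`
#' vanishes (response orthogonal to all columns), extraction stops early and
#' the remaining coefficients are zero (`ncomp` is reduced; with no usable
#' component the null model `b = 0` is returned).
#'
#' @param X numeric n x p matrix, columns standardized (zero-variance columns
#'   may be present as all-zero columns and get zero coefficients).
#' @param y numeric length-n standardized response.
#' @param ncomp number of components A, `1 <= A <= min(n-1, p)`.
#' @return An object of class `pls_fit`: list with `W`, `P`, `Tm` (scores),
#'   `q`, `b` (at `ncomp`), `B` (p x A matrix of coefficient vectors for
#'   models with 1..A components), `ncomp`, `fitted` (standardized scale).
#' @export
pls_nipals <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n > 1L, p >= 1L)
  if (ncomp < 1 || ncomp > min(n - 1L, p))
    stop("`ncomp` must lie in [1, min(n-1, p)]")
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  Xd <- X
  A <- 0L
  for (a in seq_len(ncomp)) {
    wv <- crossprod(Xd, y)
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) break                     # no covariance left
    wv <- wv / nw
    tv <- Xd %*% wv
    tt <- sum(tv^2)
    if (tt < 1e-12) break
    pv <- crossprod(Xd, tv) / tt
    W[, a] <- wv; P[, a] <- pv; Tm[, a] <- tv
    q[a] <- sum(y * tv) / tt
    Xd <- Xd - tcrossprod(tv, pv)
    A <- a
  }
  B <- matrix(0, p, ncomp)
  if (A > 0L) {
    for (a in seq_len(A)) {
      Wa <- W[, seq_len(a), drop = FALSE]
      Pa <- P[, seq_len(a), drop = FALSE]
      B[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
    }
    if (A < ncomp) for (a in (A + 1L):ncomp) B[, a] <- B[, A]
  }
  b <- B[, ncomp]
  structure(list(W = W[, seq_len(max(A, 1L)), drop = FALSE],
                 P = P[, seq_len(max(A, 1L)), drop = FALSE],
                 Tm = Tm[, seq_len(max(A, 1L)), drop = FALSE],
                 q = q[seq_len(max(A, 1L))],
                 b = b, B = B, ncomp = A,
                 fitted = as.numeric(X %*% b)),
            class = "pls_fit")
}

#' Target projection of a fitted PLS model
#'
#' Collapses an A-component PLS model onto the single predictive direction
#' given by its regression vector: `tp_weight = b / ||b||`,
#' `t_tp = X tp_weight`, `p_tp = X' t_tp / (t_tp' t_tp)`,
#' `q_tp = y' t_tp / (t_tp' t_tp)`. Predictions from the target-projected
#' component (`t_tp q_tp`) reproduce the model predictions exactly; the
#' projection only re-expresses the model so that per-variable explained
#' variance can be read off one component.
#'
#' @param fit a `pls_fit`.
#' @param X the standardized predictor matrix the model was fitted on.
#' @param y optional standardized response (needed only for `q_tp`).
#' @return An object of class `target_projection`: list with `tp_weight`
#'   (unit norm), `t_tp`, `p_tp`, `q_tp` (or `NA`).
#' @export
target_projection <- function(fit, X, y = NULL) {
  stopifnot(inherits(fit, "pls_fit"))
  nb <- sqrt(sum(fit$b^2))
  if (nb < 1e-12) stop("regression vector is zero; target projection undefined")
  w <- fit$b / nb
  t_tp <- as.numeric(as.matrix(X) %*% w)
  tt <- sum(t_tp^2)
  p_tp <- as.numeric(crossprod(as.matrix(X), t_tp)) / tt
  q_tp <- if (is.null(y)) NA_real_ else sum(y * t_tp) / tt
  structure(list(tp_weight = as.numeric(w), t_tp = t_tp, p_tp = p_tp, q_tp = q_tp),
            class = "target_projection")
}

#' Signed selectivity ratios on the target-projected component
#'
#' For each predictor `j`, the variance of column `j` explained by the
#' target-projected component is `||t_tp||^2 p_tp_j^2`; the selectivity
#' ratio is explained variance over residual variance
#' (`||x_j||^2 - explained`), a variance-independent measure of how
#' selectively that variable carries the predictive direction. The sign is
#' taken from the target-projection loading `p_tp_j`, so positive means more
#' time at that intensity goes with a higher response. A column perfectly
#' explained by the component gets `Inf` (signed); an all-zero column gets 0.
#'
#' @param tp a `target_projection`.
#' @param X the standardized predictor matrix.
#' @return Numeric vector of signed selectivity ratios, one per column.
#' @export
selectivity_ratio <- function(tp, X) {
  stopifnot(inherits(tp, "target_projection"))
  X <- as.matrix(X)
  tt <- sum(tp$t_tp^2)
  if (tt < 1e-12) stop("target-projected score is zero")
  expl <- tt * tp$p_tp^2
  tot <- colSums(X^2)
  resid <- tot - expl
  sr <- numeric(ncol(X))
  zero_col <- tot < 1e-12
  perfect <- !zero_col & resid <= 1e-10 * pmax(tot, 1)
  ok <- !zero_col & !perfect
  sr[ok] <- expl[ok] / resid[ok]
  sr[perfect] <- Inf
  sign(tp$p_tp) * sr
}

#' Continuous position of an epoch value on the MET cut-point scale
#'
#' Maps an epoch output value (mg) to a unitless position on the intensity
#' class scale of its arm: 0-1 within SED, 1-2 within LPA, 2-3 MPA, 3-4 VPA,
#' and 4-5 across VVPA (the open top class is compressed by its own lower
#' bound). Because each arm is scored against its own cut-points, positions
#' are comparable across arms; used to compare where selectivity-ratio
#' profiles peak.
#'
#' @param value_mg epoch output value(s) in mg.
#' @param cutpoints named vector from [met_cutpoints()].
#' @return Numeric position(s) in `[0, 5]`.
#' @export
met_position <- function(value_mg, cutpoints) {
  bounds <- c(0, unname(cutpoints))
  vapply(value_mg, function(v) {
    k <- findInterval(v, bounds)             # 1..5
    if (k >= 5L) 4 + min(1, (v - bounds[5L]) / bounds[5L])
    else (k - 1) + (v - bounds[k]) / (bounds[k + 1L] - bounds[k])
  }, numeric(1))
}
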