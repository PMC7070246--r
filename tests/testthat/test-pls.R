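std <- function(M) scale(M, TRUE, apply(as.matrix(M), 2, sd))

test_that("one predictor: PLS is simple least squares", {
  d <- random_instance(40, 1, seed = 1, planted = 1, noise = 0.5)
  Z <- std(d$X); yz <- as.numeric(std(d$y))
  fit <- pls_nipals(Z, yz, 1)
  ols <- solve(crossprod(Z), crossprod(Z, yz))
  expect_equal(fit$b, as.numeric(ols), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("at full rank PLS reproduces the least-squares fit", {
  for (seed in 1:5) {
    d <- random_instance(50, 5, seed = seed, planted = 2)
    Z <- std(d$X); yz <- as.numeric(std(d$y))
    fit <- pls_nipals(Z, yz, 5)
    # independent oracle: normal equations
    beta <- solve(crossprod(Z), crossprod(Z, yz))
    expect_lt(max(abs(fit$fitted - Z %*% beta)), 1e-8)
  }
})

test_that("scores are orthogonal and nested coefficient paths are returned", {
  d <- random_instance(60, 6, seed = 3, planted = 1)
  Z <- std(d$X); yz <- as.numeric(std(d$y))
  fit <- pls_nipals(Z, yz, 4)
  G <- crossprod(fit$Tm)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_equal(fit$B[, 4], fit$b)
  # one-component coefficients match a one-component fit
  expect_equal(fit$B[, 1], pls_nipals(Z, yz, 1)$b)
})

test_that("a response orthogonal to all predictors yields the null model", {
  d <- random_instance(50, 4, seed = 8)
  Z <- std(d$X)
  # project y orthogonal to every column, exactly
  y <- residuals(lm(d$y ~ Z))
  fit <- pls_nipals(std(cbind(Z)), as.numeric(std(y)), 3)
  expect_equal(fit$ncomp, 0L)
  expect_equal(fit$b, rep(0, 4), ignore_attr = TRUE)
})

test_that("target projection re-expresses the model without changing it", {
  # one component: the TP score is the score itself up to sign and scale
  d <- random_instance(50, 5, seed = 4, planted = 3)
  Z <- std(d$X); yz <- as.numeric(std(d$y))
  f1 <- pls_nipals(Z, yz, 1)
  tp1 <- target_projection(f1, Z, yz)
  al <- cor(tp1$t_tp, f1$Tm[, 1])
  expect_equal(abs(al), 1, tolerance = 1e-10)
  # any A: TP predictions equal model predictions
  for (A in 2:4) {
    fit <- pls_nipals(Z, yz, A)
    tp <- target_projection(fit, Z, yz)
    expect_equal(sqrt(sum(tp$tp_weight^2)), 1, tolerance = 1e-12)
    expect_lt(max(abs(tp$t_tp * tp$q_tp - fit$fitted)), 1e-8)
  }
})

test_that("selectivity ratios separate planted, noise and orthogonal columns", {
  set.seed(21)
  n <- 1000
  y <- rnorm(n)
  X <- cbind(sig = y + rnorm(n, 0, 0.3), matrix(rnorm(n * 4), n, 4))
  Z <- std(X); yz <- as.numeric(std(y))
  fit <- pls_nipals(Z, yz, 2)
  tp <- target_projection(fit, Z, yz)
  sr <- selectivity_ratio(tp, Z)
  expect_equal(which.max(abs(sr)), 1L)
  expect_true(all(abs(sr[-1]) < 0.05))
  expect_gt(sr[1], 1)                      # strongly selective and positive
  # a column exactly orthogonal to the TP score has SR 0
  ortho <- as.numeric(std(residuals(lm(rnorm(n) ~ tp$t_tp))))
  Zo <- cbind(Z, ortho = ortho)
  fit_pad <- fit; fit_pad$b <- c(fit$b, 0)   # same model, inert extra column
  tp_pad <- target_projection(fit_pad, Zo, yz)
  expect_lt(abs(selectivity_ratio(tp_pad, Zo)[6]), 1e-10)
})

test_that("a perfectly explained column reports the infinite sentinel", {
  set.seed(5)
  y <- rnorm(80)
  Z <- std(cbind(y))
  fit <- pls_nipals(Z, as.numeric(std(y)), 1)
  tp <- target_projection(fit, Z)
  expect_identical(selectivity_ratio(tp, Z), Inf)
})

test_that("met_position maps values onto the class scale of each arm", {
  cp <- met_cutpoints("ag")
  expect_equal(met_position(0, cp), 0)
  expect_equal(met_position(19.1, cp), 1)
  expect_equal(met_position(63, cp), 2)
  expect_equal(met_position((19.1 + 63) / 2, cp), 1.5)
  expect_equal(met_position(300.2, cp), 4)
  expect_equal(met_position(1e6, cp), 5)   # open class is capped
  # same physical class lands at the same position under either arm
  expect_equal(met_position(171, met_cutpoints("ag")),
               met_position(582.3, met_cutpoints("wide")))
})
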