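test_that("signed-max statistic follows the formula, ties give zero", {
  expect_equal(signedMaxStatistic(c(3, 0, 1), c(1, 2, 1)), c(3, -2, 0))
  expect_equal(signedMaxStatistic(c(2, 2), c(2, 2)), c(0, 0))
  # swapping an entry flips the sign and preserves the magnitude
  Z <- c(4, 1, 0.5); Zt <- c(1, 3, 0.5)
  W <- signedMaxStatistic(Z, Zt)
  Wsw <- signedMaxStatistic(Zt, Z)
  expect_equal(Wsw, -W)
  expect_error(signedMaxStatistic(c(-1, 2), c(0, 1)), "nonnegative")
  expect_error(signedMaxStatistic(1:3, 1:2), "equal length")
})

test_that("lasso entry values: no signal means no entries", {
  X <- withr::with_seed(1, matrix(rnorm(100), 20, 5))
  Xt <- withr::with_seed(2, matrix(rnorm(100), 20, 5))
  et <- lassoEntryTimes(X, Xt, rep(0, 20))
  expect_equal(et$Z, rep(0, 5))
  expect_equal(et$Ztilde, rep(0, 5))
})

test_that("first lasso entry equals the max inner product", {
  # one signal column, orthogonalized knockoff: the first path breakpoint
  # is lambda_max = max_j |A_j' y| and belongs to the signal column
  n <- 50
  u <- withr::with_seed(5, rnorm(n)); u <- u / sqrt(sum(u^2))
  v <- withr::with_seed(6, rnorm(n))
  v <- v - u * sum(u * v); v <- v / sqrt(sum(v^2))
  y <- 5 * u
  et <- lassoEntryTimes(cbind(X1 = u), cbind(v), y)
  yc <- y - mean(y)
  expect_equal(et$Z[1], abs(sum(u * yc)), tolerance = 1e-8)
  expect_lt(et$Ztilde[1], et$Z[1])
})

test_that("exact path entries agree with a fine-grid lasso fit", {
  inst <- makeLinearInstance(n = 80, p = 10, nSignal = 3, seed = 21)
  mine <- lassoEntryTimes(inst$X, inst$Xtilde, inst$y)
  ref <- glmnetEntryTimes(inst$X, inst$Xtilde, inst$y)
  all_mine <- c(mine$Z, mine$Ztilde)
  all_ref <- c(ref$Z, ref$Ztilde)
  # one log-grid step of the 2000-point reference grid is ~0.46%
  expect_true(all(abs(all_mine - all_ref) / pmax(all_ref, 1) < 0.01))
  # and the exact entries can only exceed the downward-quantized grid ones
  expect_true(all(all_mine >= all_ref - 1e-6))
})

test_that("entry values are equivariant under variable permutation", {
  inst <- makeLinearInstance(n = 60, p = 6, nSignal = 2, seed = 31)
  perm <- c(3, 1, 6, 2, 5, 4)
  et <- lassoEntryTimes(inst$X, inst$Xtilde, inst$y)
  etp <- lassoEntryTimes(inst$X[, perm], inst$Xtilde[, perm], inst$y)
  expect_equal(etp$Z, et$Z[perm], tolerance = 1e-7)
  expect_equal(etp$Ztilde, et$Ztilde[perm], tolerance = 1e-7)
})

test_that("logistic grid starts at the all-zero solution", {
  sim <- generateLogistic(150, 8, 0.5, 2, 5, seed = 41)
  model <- knockoffModel(ar1Covariance(8, 0.5))
  Xt <- sampleKnockoffs(sim$X, model, seed = 42)
  et <- logisticEntryTimes(sim$X, Xt, sim$y, nlambda = 50)
  # no variable may be active at the first grid point
  expect_true(all(c(et$Z, et$Ztilde) < et$lambda[1] - 1e-12))
  expect_error(logisticEntryTimes(sim$X, Xt, rep(1, 150)), "single class")
  expect_error(logisticEntryTimes(sim$X, Xt, sim$y * 2), "binary")
})

test_that("a strong logistic effect enters before its knockoff", {
  wins <- 0L
  nrep <- 20L
  model <- knockoffModel(diag(6))
  for (s in seq_len(nrep)) {
    X <- withr::with_seed(100 + s, matrix(rnorm(300 * 6), 300, 6))
    eta <- X[, 1] * 1.0
    y <- withr::with_seed(200 + s, rbinom(300, 1, plogis(eta)))
    Xt <- sampleKnockoffs(X, model, seed = 300 + s)
    st <- knockoffStatistics(X, Xt, y, family = "logistic", nlambda = 50)
    if (wStatistic(st)[1] > 0) wins <- wins + 1L
  }
  expect_gt(wins, nrep / 2)
})

test_that("null variables give sign-symmetric W", {
  # pure-noise outcome: positive and negative W should be balanced, and
  # pooled original/knockoff entry values indistinguishable
  pos <- 0L; tot <- 0L; zs <- c(); zts <- c()
  model <- knockoffModel(ar1Covariance(20, 0.5))
  for (s in 1:10) {
    X <- withr::with_seed(500 + s,
                          matrix(rnorm(80 * 20), 80, 20) %*%
                            chol(ar1Covariance(20, 0.5)))
    y <- withr::with_seed(600 + s, rnorm(80))
    Xt <- sampleKnockoffs(X, model, seed = 700 + s)
    st <- knockoffStatistics(X, Xt, y)
    W <- wStatistic(st)
    pos <- pos + sum(W > 0); tot <- tot + sum(W != 0)
    ev <- entryValues(st)
    zs <- c(zs, ev[, "Z"]); zts <- c(zts, ev[, "Ztilde"])
  }
  # binomial(tot, 1/2) within ~4 SD
  expect_lt(abs(pos - tot / 2), 4 * sqrt(tot / 4) + 1)
  expect_gt(suppressWarnings(wilcox.test(zs, zts)$p.value), 0.01)
})

test_that("doubling the logistic grid moves entries less than a grid step", {
  sim <- generateLogistic(200, 10, 0.5, 3, 5, seed = 51)
  model <- knockoffModel(ar1Covariance(10, 0.5))
  Xt <- sampleKnockoffs(sim$X, model, seed = 52)
  e1 <- logisticEntryTimes(sim$X, Xt, sim$y, nlambda = 50)
  e2 <- logisticEntryTimes(sim$X, Xt, sim$y, nlambda = 100)
  step <- exp(log(1e3) / 49)   # coarse-grid ratio between adjacent points
  z1 <- c(e1$Z, e1$Ztilde); z2 <- c(e2$Z, e2$Ztilde)
  both <- z1 > 0 & z2 > 0
  expect_true(all(z2[both] / z1[both] < step + 1e-8 &
                  z1[both] / z2[both] < step + 1e-8))
})

test_that("statistics constructor wires Z, Ztilde and W together", {
  inst <- makeLinearInstance(seed = 61)
  st <- knockoffStatistics(inst$X, inst$Xtilde, inst$y)
  ev <- entryValues(st)
  expect_equal(wStatistic(st),
               signedMaxStatistic(ev[, "Z"], ev[, "Ztilde"]))
  expect_error(knockoffStatistics(inst$X, inst$Xtilde[, -1], inst$y),
               "identical dimensions")
})
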