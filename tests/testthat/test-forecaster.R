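test_that("olsFit recovers exact lines and matches the normal-equations oracle", {
  x <- matrix(1:5, ncol = 1, dimnames = list(NULL, "x"))
  b <- olsFit(x, 3 * (1:5) + 1)
  expect_equal(unname(b), c(1, 3), tolerance = 1e-10)

  bc <- olsFit(x, rep(4.5, 5))
  expect_equal(unname(bc), c(4.5, 0), tolerance = 1e-10)

  set.seed(33)
  for (i in 1:10) {
    X <- matrix(rnorm(30), nrow = 10, ncol = 3)
    y <- rnorm(10)
    Xd <- cbind(1, X)
    oracle <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
    expect_equal(unname(olsFit(X, y)), as.vector(oracle), tolerance = 1e-8)
  }
  expect_error(olsFit(matrix(1, 1, 1), 2), "at least 2 rows")
})

test_that("olsFit on rank-deficient designs still reproduces fitted values", {
  set.seed(4)
  X <- cbind(a = rnorm(12), b = 0, c = 0)
  X[, "b"] <- 2 * X[, "a"]  # exactly collinear
  y <- 1 + 3 * X[, "a"] + rnorm(12, 0, 0.1)
  beta <- olsFit(X, y)
  fitted <- cbind(1, X) %*% beta
  ref <- lm(y ~ a, data.frame(a = X[, "a"], y = y))
  expect_equal(as.vector(fitted), unname(fitted(ref)), tolerance = 1e-8)
})

test_that("chain length matches the schedule contract", {
  co <- makeAdditiveCohort(n = 24)
  m44 <- fitChain(co, 44)
  expect_equal(m44$targetWeeks, 48L)
  expect_length(m44$coefs, 1L)
  m6 <- fitChain(co, 6)
  expect_equal(length(m6$coefs), 13L)
  expect_error(fitChain(co, 48), "final schedule week")
  expect_error(fitChain(co, 7), "not in the schedule")
  expect_error(fitChain(co[, 1:8], 6), "too few records")
})

test_that("noiseless additive dynamics are recovered exactly along the chain", {
  co <- makeAdditiveCohort(n = 24, step = 2)
  model <- fitChain(co, 6)
  pred <- predictChain(model, "F", 0L, c("6" = 20))
  sched <- defaultSchedule()
  expect_equal(unname(pred), 20 + 2 * (seq_along(sched[-1])),
               tolerance = 1e-6)

  # constant-weight training data predicts that constant at every horizon
  flat <- makeCohort(matrix(20, 20, 14) + 0 * rnorm(20),
                     genotype = rep(c(0L, 1L), 10))
  mflat <- fitChain(flat, 6)
  pflat <- predictChain(mflat, "M", 1L, c("6" = 20))
  expect_equal(unname(pflat), rep(20, 13), tolerance = 1e-8)

  expect_error(predictChain(model, "F", 0L, c("8" = 22)),
               "missing observed predecessor")
})

test_that("chain predictions are invariant to training-row order", {
  co <- makeAdditiveCohort(n = 30)
  set.seed(2)
  w <- weightMatrix(co) + matrix(rnorm(length(weightMatrix(co)), 0, 0.3),
                                 nrow = 14)
  co <- BWCohort(w, mouseLine(co), mouseSex(co), mouseGenotype(co),
                 mouseIds = mouseIds(co))
  perm <- sample(ncol(co))
  m1 <- fitChain(co, 16)
  m2 <- fitChain(co[, perm], 16)
  obs <- setNames(w[1:6, 1], as.character(defaultSchedule()[1:6]))
  p1 <- predictChain(m1, mouseSex(co)[1], mouseGenotype(co)[1], obs)
  p2 <- predictChain(m2, mouseSex(co)[1], mouseGenotype(co)[1], obs)
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("with one target the chain equals a direct OLS of week 48", {
  co <- makeAdditiveCohort(n = 30)
  set.seed(6)
  w <- weightMatrix(co) + matrix(rnorm(14 * 30, 0, 0.5), nrow = 14)
  co <- BWCohort(w, mouseLine(co), mouseSex(co), mouseGenotype(co),
                 mouseIds = mouseIds(co))
  model <- fitChain(co, 44)
  X <- cbind(sex = as.numeric(mouseSex(co) == "M"),
             genotype = mouseGenotype(co), t(w[1:13, ]))
  direct <- olsFit(X, w["wk48", ])
  expect_equal(unname(model$coefs$wk48), unname(direct), tolerance = 1e-10)
})

test_that("pooled out-of-fold R2 is exact on noiseless data and 0 at the mean", {
  co <- makeAdditiveCohort(n = 25)
  for (lw in c(6, 16, 44)) {
    ev <- evaluateChain(co, "IL72", lw, folds = 5, seed = 1L)
    expect_equal(ev$pooledR2, 1, tolerance = 1e-9)
  }
  # definitional check: predicting the pooled mean gives R2 = 0
  actual <- c(1, 2, 3, 4)
  expect_equal(ccweight:::pooledR2(actual, rep(mean(actual), 4)), 0)
  expect_error(ccweight:::pooledR2(rep(2, 4), rep(2, 4)),
               class = "ccweight_invalid_data")
})

test_that("structureless small-n lines can score negative pooled R2", {
  set.seed(88)
  sched <- c(6L, 8L, 10L, 12L)
  w <- matrix(runif(10 * 4, 18, 45), nrow = 10)  # no temporal structure
  co <- makeCohort(w, genotype = rep(c(0L, 1L), 5), schedule = sched)
  ev <- evaluateChain(co, "IL72", 8, folds = 5, seed = 88L)
  expect_lt(ev$pooledR2, 0)
  expect_lte(ev$pooledR2, 1)
})

test_that("evaluateChain is invariant to mouse relabeling and checks size", {
  co <- makeAdditiveCohort(n = 25)
  set.seed(10)
  w <- weightMatrix(co) + matrix(rnorm(14 * 25, 0, 0.4), nrow = 14)
  mk <- function(ids) BWCohort(w, mouseLine(co), mouseSex(co),
                               mouseGenotype(co), mouseIds = ids)
  e1 <- evaluateChain(mk(sprintf("m%02d", 1:25)), "IL72", 16, seed = 4L)
  e2 <- evaluateChain(mk(sprintf("zz%02d", 1:25)), "IL72", 16, seed = 4L)
  expect_equal(e1$pooledR2, e2$pooledR2, tolerance = 1e-12)

  expect_error(evaluateChain(co[, 1:4], "IL72", 16, folds = 5),
               class = "ccweight_not_evaluable")
})

test_that("forecastTable covers lines x last-observed weeks", {
  co <- makeAdditiveCohort(n = 24)
  tab <- forecastTable(co, lastWeeks = c(6, 16), folds = 4, seed = 2L)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$lastObservedWeek, c(6, 16))
  expect_true(all(tab$pooledR2 <= 1))
})
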