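test_that("pooled t from summaries reproduces raw-data t exactly", {
  set.seed(4)
  x <- rnorm(15, 1.2, 0.08); y <- rnorm(45, 1.25, 0.07)
  fromRaw <- tTestPooled(x, y)
  fromSummary <- tTestFromSummary(groupSummary(length(x), mean(x), sd(x)),
                                  groupSummary(length(y), mean(y), sd(y)))
  expect_equal(fromRaw$t, fromSummary$t, tolerance = 1e-12)
  # independent oracle: base t.test with pooled variance
  ht <- t.test(y, x, var.equal = TRUE)
  expect_equal(fromRaw$t, unname(ht$statistic), tolerance = 1e-12)
  expect_equal(fromRaw$p, ht$p.value, tolerance = 1e-12)
  expect_identical(fromRaw$df, 58L)
})

test_that("pooled t handles identical and degenerate groups", {
  same <- tTestFromSummary(groupSummary(10, 5, 1), groupSummary(20, 5, 1))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  zero <- tTestFromSummary(groupSummary(5, 3, 0), groupSummary(5, 3, 0))
  expect_identical(zero$t, 0)
  expect_error(tTestFromSummary(groupSummary(5, 3, 0), groupSummary(5, 4, 0)),
               "undefined")
  expect_error(groupSummary(1, 0, 1), "n must be >= 2")
  expect_error(groupSummary(5, 0, -1), "sd")
})

test_that("chi-square of independence matches hand computation and keeps margins", {
  flat <- chiSquareIndependence(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)

  diag2 <- chiSquareIndependence(rbind(c(5, 0), c(0, 5)))
  expect_equal(diag2$chi2, 10)       # E = 2.5 in every cell
  expect_identical(diag2$df, 1L)
  expect_true(all(diag2$expected == 2.5))

  obs <- rbind(c(12, 3, 0), c(34, 9, 2))
  res <- chiSquareIndependence(obs)
  # hand formula: E_ij = row_i col_j / N
  E <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  expect_equal(res$chi2, sum((obs - E)^2 / E), tolerance = 1e-12)
  expect_equal(rowSums(res$expected), rowSums(obs))
  expect_equal(colSums(res$expected), colSums(obs))
  # invariant under row/column permutation
  perm <- chiSquareIndependence(obs[2:1, c(3, 1, 2)])
  expect_equal(perm$chi2, res$chi2, tolerance = 1e-12)

  expect_warning(z <- chiSquareIndependence(rbind(c(5, 0, 3), c(4, 0, 6))),
                 "empty")
  expect_identical(dim(z$observed), c(2L, 2L))
  expect_error(chiSquareIndependence(matrix(0, 2, 2)), "empty")
})

test_that("effect size follows the rms-SD convention with a pooled alternative", {
  d <- cohensD(c(15, 1.162, 0.076), c(45, 1.253, 0.067))
  expect_equal(d, 0.091 / sqrt((0.076^2 + 0.067^2) / 2), tolerance = 1e-12)
  expect_equal(d, 1.27, tolerance = 0.005)
  expect_identical(cohensD(c(10, 5, 1), c(10, 5, 2)), 0)
  # one rms SD apart -> d = 1
  s <- sqrt((1^2 + 2^2) / 2)
  expect_equal(cohensD(c(10, 0, 1), c(10, s, 2)), 1, tolerance = 1e-12)
  expect_error(cohensD(c(10, 1, 0), c(10, 2, 0)), "undefined")
})

test_that("post hoc power equals alpha at d = 0 and grows with the effect", {
  p0 <- posthocPowerT(0, 15, 45, alpha = 0.05)
  expect_equal(p0$power, 0.05, tolerance = 1e-6)
  expect_lt(posthocPowerT(0.5, 20, 20)$power, posthocPowerT(1.0, 20, 20)$power)
  ladder <- sapply(seq(0, 2, by = 0.25), function(d) posthocPowerT(d, 15, 45)$power)
  expect_true(all(diff(ladder) > 0))
  expect_error(posthocPowerT(-0.1, 10, 10), "d must be")
  expect_error(posthocPowerT(0.5, 10, 10, alpha = 1.2), "alpha")
})

test_that("ICC recovers designed reliabilities", {
  # perfect agreement
  set.seed(8)
  v <- rnorm(30)
  perfect <- iccReliability(cbind(v, v))
  expect_equal(perfect$icc, 1)
  expect_equal(cronbachAlpha(cbind(v, v)), 1)

  # independent raters: ICC near zero
  set.seed(81)
  indep <- iccReliability(cbind(rnorm(200), rnorm(200)),
                          model = "twoWayMixedConsistency")
  expect_lt(abs(indep$icc), 0.15)
  expect_lt(abs(cronbachAlpha(cbind(rnorm(200), rnorm(200)))), 0.2)

  # noise variance equal to truth variance -> consistency ICC ~ 0.5
  set.seed(82)
  truth <- rnorm(500)
  ratings <- cbind(truth + rnorm(500), truth + rnorm(500))
  half <- iccReliability(ratings, model = "twoWayMixedConsistency")
  expect_lt(abs(half$icc - 0.5), 0.1)
  expect_true(half$lower < half$icc && half$icc < half$upper)

  # agreement model penalizes a systematic rater offset, consistency does not
  set.seed(83)
  t2 <- rnorm(300)
  shifted <- cbind(t2, t2 + 2)
  expect_equal(iccReliability(shifted, model = "twoWayMixedConsistency")$icc, 1)
  expect_lt(iccReliability(shifted, model = "twoWayRandomAbsolute")$icc, 0.8)

  expect_error(iccReliability(matrix(1:5, 5, 1)), "2 raters")
  expect_error(iccReliability(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("Cronbach's alpha matches its closed form for correlated columns", {
  # columns with correlation rho: alpha -> 2 rho / (1 + rho)
  rho <- 0.6
  set.seed(9)
  n <- 20000
  z <- rnorm(n)
  x <- cbind(sqrt(rho) * z + sqrt(1 - rho) * rnorm(n),
             sqrt(rho) * z + sqrt(1 - rho) * rnorm(n))
  expect_equal(cronbachAlpha(x), 2 * rho / (1 + rho), tolerance = 0.02)
  expect_error(cronbachAlpha(cbind(rep(1, 5), rep(2, 5))), "variance")
})

test_that("Mann-Whitney handles separation, identity and orientation", {
  same <- mannWhitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p, 1)
  sep <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(unname(sep$U), 9)
  expect_identical(unname(mannWhitney(c(4, 5, 6), c(1, 2, 3))$U), 0)
  expect_true(sep$exact)
  big <- mannWhitney(rnorm(30), rnorm(30))
  expect_false(big$exact)
  expect_error(mannWhitney(numeric(0), 1:3), "non-empty")
})

test_that("type-I error of t and Mann-Whitney is calibrated at alpha", {
  set.seed(314)
  nrep <- 10000
  # pooled t under the null, n = 15 vs 45 (vectorized)
  X <- matrix(rnorm(15 * nrep), 15)
  Y <- matrix(rnorm(45 * nrep), 45)
  mx <- colMeans(X); my <- colMeans(Y)
  vx <- colSums((X - rep(mx, each = 15))^2) / 14
  vy <- colSums((Y - rep(my, each = 45))^2) / 44
  sp <- sqrt((14 * vx + 44 * vy) / 58)
  tstat <- (my - mx) / (sp * sqrt(1 / 15 + 1 / 45))
  rejT <- mean(2 * pt(-abs(tstat), 58) < 0.05)
  expect_lt(abs(rejT - 0.05), 0.01)

  rejMW <- mean(vapply(seq_len(nrep), function(i) {
    mannWhitney(rnorm(25), rnorm(25))$p < 0.05
  }, logical(1)))
  expect_lt(abs(rejMW - 0.05), 0.01)
})

test_that("two-factor ANOVA isolates effects with Type II sums of squares", {
  # identical cell means with symmetric within-cell spread: all F exactly 0
  g <- expand.grid(A = c("a", "b"), B = c("u", "v"), rep = 1:2)
  vals <- ifelse(g$rep == 1, 9, 11)
  res <- twoWayAnova(vals, g$A, g$B)
  eff <- res[res$term != "Residuals", ]
  expect_equal(eff$F, rep(0, 3))
  expect_equal(eff$p, rep(1, 3))

  # a pure 2-SD factor-A shift is detected; B and interaction stay null-like
  set.seed(12)
  n <- 20
  g2 <- expand.grid(A = c("a", "b"), B = c("u", "v"), rep = seq_len(n))
  vals2 <- rnorm(nrow(g2)) + 2 * (g2$A == "b")
  res2 <- twoWayAnova(vals2, g2$A, g2$B)
  expect_lt(res2$p[res2$term == "factorA"], 1e-6)
  expect_gt(res2$p[res2$term == "factorA:factorB"], 0.01)

  # unbalanced data: Type II is invariant to factor order
  keep <- c(rep(TRUE, 50), rep(c(TRUE, FALSE), 15))
  v3 <- vals2[keep]
  r1 <- twoWayAnova(v3, g2$A[keep], g2$B[keep])
  r2 <- twoWayAnova(v3, g2$B[keep], g2$A[keep])
  expect_equal(sort(r1$F), sort(r2$F), tolerance = 1e-10)

  one <- expand.grid(A = c("a", "b"), B = c("u", "v"))
  expect_error(twoWayAnova(rnorm(4), one$A, one$B), "residual")
  expect_error(twoWayAnova(rnorm(4), rep("a", 4), c("u", "v", "u", "v")),
               "2 levels")
})
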