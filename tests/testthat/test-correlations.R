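test_that("thresholds are inverse-normal quantiles of cumulative margins", {
  expect_equal(estimateThresholds(c(0, 0, 1, 1)), 0)
  th <- estimateThresholds(rep(0:3, times = c(25, 25, 25, 25)))
  expect_equal(th, qnorm(c(0.25, 0.5, 0.75)))
  expect_equal(th, c(-0.6744898, 0, 0.6744898), tolerance = 1e-6)
  expect_error(estimateThresholds(rep(2, 10)), "degenerate")
})

test_that("thresholds are invariant to monotone relabeling", {
  set.seed(1)
  for (i in 1:10) {
    x <- sample(0:3, 100, replace = TRUE)
    relab <- c(10, 20, 35, 99)[x + 1]  # strictly increasing relabeling
    expect_equal(estimateThresholds(x), estimateThresholds(relab))
  }
})

test_that("nearestPD repairs indefinite matrices and respects PD input", {
  expect_equal(nearestPD(diag(3)), diag(3))
  m <- matrix(c(1, 1.2, 1.2, 1), 2)
  r <- nearestPD(m)
  expect_equal(diag(r), c(1, 1))
  expect_lt(abs(r[1, 2]), 1)
  expect_gte(min(eigen(r, symmetric = TRUE)$values), 1e-6 - 1e-12)
  expect_error(nearestPD(matrix(1:4, 2)), "symmetric")
  set.seed(2)
  for (i in 1:5) {
    A <- matrix(rnorm(25), 5)
    m <- (A + t(A)) / 2
    diag(m) <- 1
    r <- nearestPD(m)
    expect_gte(min(eigen(r, symmetric = TRUE)$values), 1e-6 - 1e-12)
    expect_equal(diag(r), rep(1, 5))
  }
})

test_that("identical ordinal columns give a boundary correlation", {
  set.seed(3)
  x <- sample(0:3, 200, replace = TRUE)
  d <- ordinalDataset(cbind(a = x, b = x))
  # without the continuity constant the MLE sits at the clamp
  raw <- netstab:::.cppPolychoricPair(d$codes[, 1], d$codes[, 2],
                                      FALSE, 0.999)
  expect_equal(raw$rho, 0.999, tolerance = 1e-3)
  est <- estimateCorrelations(d)
  expect_gt(est$matrix[1, 2], 0.95)
})

test_that("polychoric recovers the latent correlation (two-step ML)", {
  set.seed(4)
  th <- c(-0.6745, 0, 0.6745)
  for (rho in c(-0.6, 0, 0.6)) {
    errs <- replicate(5, {
      X <- MASS::mvrnorm(5000, c(0, 0), matrix(c(1, rho, rho, 1), 2))
      d <- ordinalDataset(apply(X, 2, findInterval, vec = th))
      est <- estimateCorrelations(d)
      est$matrix[1, 2] - rho
    })
    expect_true(all(abs(errs) < 0.05))
  }
})

test_that("continuous columns fall back to product-moment correlations", {
  set.seed(5)
  X <- MASS::mvrnorm(300, c(0, 0, 0), diag(3) * 0.5 + 0.5)
  d <- ordinalDataset(X)
  expect_true(all(d$level == "continuous"))
  est <- estimateCorrelations(d)
  expect_equal(est$method, "pearson")
  expect_equal(unname(est$matrix), unname(cor(X)), tolerance = 1e-10)
})

test_that("mixed ordinal/continuous data dispatch to polyserial", {
  set.seed(6)
  rho <- 0.5
  X <- MASS::mvrnorm(4000, c(0, 0), matrix(c(1, rho, rho, 1), 2))
  xo <- findInterval(X[, 1], c(-0.5, 0.5))
  d <- ordinalDataset(cbind(o = xo, c = X[, 2]))
  expect_equal(d$level, c("ordinal", "continuous"))
  est <- estimateCorrelations(d)
  expect_equal(est$method, "mixed")
  expect_equal(est$matrix[1, 2], rho, tolerance = 0.06)
})

test_that("polychoric matrices are symmetric, unit-diagonal and PD", {
  set.seed(7)
  net <- chainNetwork(6, 0.3, 0.5)
  d <- simulateDataset(net, 150, levels = 4)
  est <- estimateCorrelations(d)
  expect_equal(est$matrix, t(est$matrix))
  expect_equal(unname(diag(est$matrix)), rep(1, 6))
  expect_gte(min(eigen(est$matrix, symmetric = TRUE)$values), 1e-6 - 1e-12)
  expect_equal(est$method, "polychoric")
  expect_equal(est$n, 150)
  expect_length(est$thresholds[[1]], 3)
})

test_that("missing data are handled pairwise or listwise", {
  set.seed(8)
  net <- chainNetwork(4, 0.25, 0)
  d <- simulateDataset(net, 300, levels = 4)
  v <- d$values
  v[sample(length(v), 30)] <- NA
  d2 <- ordinalDataset(v)
  ep <- estimateCorrelations(d2)
  el <- estimateCorrelations(d2, missing = "listwise")
  expect_lt(el$n, ep$n)
  expect_equal(ep$n, 300)
  expect_false(anyNA(ep$matrix))
})

test_that("correlation matrices round-trip through CSV", {
  set.seed(9)
  d <- smallOrdinalData()
  est <- estimateCorrelations(d)
  f <- tempfile(fileext = ".csv")
  writeCorrelations(est, f)
  back <- readCorrelations(f, n = est$n)
  expect_equal(back$matrix, est$matrix, tolerance = 1e-6)
  expect_equal(back$n, est$n)
})

test_that("ordinal auto-detection uses the integer/<=10-level rule", {
  set.seed(10)
  x <- cbind(a = sample(0:3, 60, TRUE), b = rnorm(60),
             c = sample(1:15, 60, TRUE))
  d <- ordinalDataset(x)
  expect_equal(d$level, c("ordinal", "continuous", "continuous"))
  d2 <- ordinalDataset(x, level = c("ordinal", "continuous", "ordinal"))
  expect_equal(d2$level[3], "ordinal")
  expect_error(ordinalDataset(cbind(a = rep(1, 10), b = 1:10)), "constant")
})

test_that("bivariate normal CDF matches mvtnorm over a wide grid", {
  hs <- c(-3, -1.2, 0, 0.8, 2.5)
  rs <- c(-0.999, -0.95, -0.6, 0, 0.4, 0.9, 0.95, 0.999)
  for (h in hs) for (k in hs) for (r in rs) {
    ours <- netstab:::.cppPbvn(h, k, r)
    ref <- mvtnorm::pmvnorm(upper = c(h, k),
                            corr = matrix(c(1, r, r, 1), 2))[1]
    expect_equal(ours, ref, tolerance = 1e-6)
  }
})
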