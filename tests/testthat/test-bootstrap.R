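test_that("type-6 quantiles follow the (n+1)p plotting position", {
  expect_equal(quantileType6(1:10, 0.5), 5.5)
  expect_equal(quantileType6(1:10, 1 / 11), 1)
  expect_equal(quantileType6(10:1, 10 / 11), 10)
  expect_equal(quantileType6(rep(3.2, 7), runif(1)), 3.2)
  expect_error(quantileType6(numeric(0), 0.5), "non-empty")
  expect_error(quantileType6(c(1, NA), 0.5), "finite")
  # cross-check against the reference implementation on random cases
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(sample(5:50, 1))
    pr <- runif(4)
    expect_equal(quantileType6(x, pr),
                 unname(quantile(x, pr, type = 6)), tolerance = 1e-12)
  }
})

test_that("type-6 bootstrap CIs have near-nominal normal-theory width", {
  set.seed(32)
  lo <- replicate(50, quantileType6(rnorm(200), 0.025))
  hi <- replicate(50, quantileType6(rnorm(200), 0.975))
  expect_lt(abs(mean(lo) - (-1.96)), 0.15)
  expect_lt(abs(mean(hi) - 1.96), 0.15)
})

test_that("minimum alpha is 2 over the replicate count", {
  expect_equal(minAlpha(1000), 0.002)
  expect_equal(minAlpha(2), 1)
  expect_equal(minAlpha(2500), 0.0008)
  expect_error(minAlpha(1), "at least 2")
})

test_that("analytic test-count utilities match closed forms", {
  expect_equal(edgeDiffCount(20), 17955)
  expect_equal(edgeDiffCount(10), choose(45, 2))
  expect_equal(round(bonferroniAlpha(0.05, edgeDiffCount(20)), 6), 3e-06)
})

test_that("a constant estimator yields zero-width CIs", {
  set.seed(33)
  W <- ringWeights(4, 0.3)
  d <- smallOrdinalData(n = 60)
  bt <- nonparametricBoot(d, estimator = constantEstimator(W),
                          nBoots = 25, seed = 1)
  ci <- edgeCITable(bt, alpha = 0.1)
  expect_equal(ci$lower, ci$upper)
  expect_equal(ci$lower, ci$sample)
})

test_that("bootstrap results are deterministic given the seed", {
  set.seed(34)
  d <- smallOrdinalData(n = 120)
  b1 <- nonparametricBoot(d, nBoots = 12, seed = 99)
  b2 <- nonparametricBoot(d, nBoots = 12, seed = 99)
  expect_identical(b1, b2)
  net <- estimateGGM(d)
  p1 <- parametricBoot(net, n = 120, nBoots = 8, seed = 7)
  p2 <- parametricBoot(net, n = 120, nBoots = 8, seed = 7)
  expect_identical(p1, p2)
  expect_true(p1$continuousData)
  expect_false(b1$continuousData)
})

test_that("parametric bootstrap of the empty network stays near zero", {
  set.seed(35)
  net <- networkModel(matrix(0, 5, 5))
  pb <- parametricBoot(net, n = 300, nBoots = 30, seed = 3)
  expect_lt(median(abs(pb$edges)), 0.02)
})

test_that("edge CI table orders by sample weight with bootMean tiebreak", {
  set.seed(36)
  d <- smallOrdinalData(n = 150)
  bt <- nonparametricBoot(d, nBoots = 40, seed = 5)
  ci <- edgeCITable(bt)
  expect_true(all(diff(ci$sample) <= 0))
  ties <- split(ci$bootMean, ci$sample)
  for (g in ties) expect_true(all(diff(g) <= 0))
  # CI at the extreme attainable alpha spans the replicate range
  ciX <- edgeCITable(bt, alpha = minAlpha(bt$nBoots))
  for (r in seq_len(nrow(ciX))) {
    e <- ciX$edge[r]
    expect_equal(ciX$lower[r], min(bt$edges[, e]))
    expect_equal(ciX$upper[r], max(bt$edges[, e]))
  }
  expect_error(edgeCITable(bt, alpha = 0.001), "2/nBoots")
})

test_that("difference test flags zero-width tied CIs as not significant", {
  set.seed(37)
  W <- ringWeights(4, 0.3)
  d <- smallOrdinalData(n = 60)
  bt <- nonparametricBoot(d, estimator = constantEstimator(W),
                          nBoots = 50, seed = 1)
  dt <- differenceTest(bt, "strength", 1, 2)
  expect_equal(c(dt$lower, dt$upper), c(0, 0))
  expect_false(dt$significant)
})

test_that("difference tests are paired and mirror-symmetric", {
  set.seed(38)
  d <- smallOrdinalData(n = 150)
  bt <- nonparametricBoot(d, nBoots = 60, seed = 2)
  ab <- differenceTest(bt, "strength", "V1", "V3")
  ba <- differenceTest(bt, "strength", "V3", "V1")
  expect_equal(ab$lower, -ba$upper)
  expect_equal(ab$upper, -ba$lower)
  expect_equal(ab$significant, ba$significant)
  # edge variant accepts edge names
  e <- bt$edgeNames[1]
  dt <- differenceTest(bt, "edge", e, bt$edgeNames[2])
  expect_s3_class(dt, "differenceTest")
  expect_error(differenceTest(bt, "strength", "V1", "V1"), "must differ")
  expect_error(differenceTest(bt, "strength", "V1", "nope"), "unknown")
})

test_that("CIs are nested across alpha levels", {
  set.seed(39)
  d <- smallOrdinalData(n = 150)
  bt <- nonparametricBoot(d, nBoots = 60, seed = 4)
  for (pair in list(c(1, 2), c(2, 4))) {
    d1 <- differenceTest(bt, "strength", pair[1], pair[2], alpha = 0.05)
    d2 <- differenceTest(bt, "strength", pair[1], pair[2], alpha = 0.2)
    expect_lte(d1$lower, d2$lower)
    expect_gte(d1$upper, d2$upper)
  }
})

test_that("all-pairs difference matrix reports the analytic test count", {
  set.seed(40)
  d <- smallOrdinalData(n = 150)
  bt <- nonparametricBoot(d, nBoots = 60, seed = 6)
  dm <- differenceMatrix(bt, "strength")
  expect_equal(dm$nTests, choose(4, 2))
  expect_true(isSymmetric(dm$significant))
  # a 17-node network admits choose(17,2) = 136 pairwise strength tests
  expect_equal(choose(17, 2), 136)
  f <- tempfile(fileext = ".json")
  writeDifferenceMatrix(dm, f, json = TRUE)
  j <- jsonlite::read_json(f)
  expect_equal(j$kind, "strength")
  expect_equal(j$nTests, 6)
})

test_that("excess estimator failures abort with a diagnostic", {
  set.seed(41)
  d <- smallOrdinalData(n = 60)
  # succeeds on the initial full-data fit, fails inside the loop
  calls <- 0
  flaky <- function(data, ...) {
    calls <<- calls + 1
    if (calls == 1) return(constantEstimator(ringWeights(4, 0.3))(data))
    stop("boom")
  }
  expect_error(nonparametricBoot(d, estimator = flaky, nBoots = 10,
                                 seed = 1),
               "replicates failed")
})
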