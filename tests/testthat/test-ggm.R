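test_that("bivariate partial correlation equals the marginal correlation", {
  m <- matrix(c(1, 0.3, 0.3, 1), 2)
  net <- samplePcor(m)
  expect_equal(net$weights[1, 2], 0.3, tolerance = 1e-12)
  expect_equal(unname(diag(net$weights)), c(0, 0))
})

test_that("three-variable partial correlations match the closed form", {
  r12 <- 0.5; r13 <- 0.5; r23 <- 0.25
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- r12
  m[1, 3] <- m[3, 1] <- r13
  m[2, 3] <- m[3, 2] <- r23
  net <- samplePcor(m)
  # partial of 2,3 given 1: (r23 - r12*r13) / sqrt((1-r12^2)(1-r13^2))
  expect_equal(net$weights[2, 3],
               (r23 - r12 * r13) / sqrt((1 - r12^2) * (1 - r13^2)),
               tolerance = 1e-12)
  expect_equal(net$weights[2, 3], 0)
  expect_equal(unname(samplePcor(diag(4))$weights), matrix(0, 4, 4))
  expect_error(samplePcor(matrix(1, 3, 3)), "singular")
})

test_that("ebicScore matches an independently coded formula", {
  set.seed(11)
  A <- matrix(rnorm(9), 3)
  S <- cov2cor(crossprod(A) + diag(3))
  Th <- solve(S)
  n <- 120
  for (gamma in c(0, 0.25, 0.5)) {
    # independent oracle: direct evaluation of the definition
    E <- sum(abs(Th[upper.tri(Th)]) > 1e-10)
    ll <- n / 2 * (determinant(Th)$modulus[1] - sum(diag(S %*% Th)))
    oracle <- -2 * ll + E * log(n) + 4 * E * gamma * log(3)
    expect_equal(ebicScore(Th, S, n, gamma), oracle, tolerance = 1e-8)
  }
  # gamma = 0 reduces to BIC-penalized deviance; diagonal precision E = 0
  Thd <- diag(c(1, 2, 3))
  ll <- n / 2 * (determinant(Thd)$modulus[1] - sum(diag(S %*% Thd)))
  expect_equal(ebicScore(Thd, S, n, 0.5), -2 * ll, tolerance = 1e-8)
  expect_error(ebicScore(-diag(3), S, n), "positive definite")
})

test_that("EBIC strictly increases in gamma when edges are present", {
  set.seed(12)
  A <- matrix(rnorm(16), 4)
  S <- cov2cor(crossprod(A) + diag(4))
  Th <- solve(S)
  g <- seq(0, 1, by = 0.25)
  v <- vapply(g, function(x) ebicScore(Th, S, 100, x), 0)
  expect_true(all(diff(v) > 0))
})

test_that("glasso at the grid maximum gives the empty graph", {
  set.seed(13)
  d <- smallOrdinalData()
  est <- estimateCorrelations(d)
  lmax <- max(abs(est$matrix[upper.tri(est$matrix)]))
  net <- estimateGGM(est, lambda = lmax)
  expect_equal(unname(net$weights), matrix(0, 4, 4))
  # and the path endpoint has zero edges
  path <- estimateGGM(est)
  expect_equal(path$meta$ebic$edges[1], 0L)
  expect_true(all(diff(path$meta$lambdaGrid) < 0))
})

test_that("glasso in the unregularized limit matches direct inversion", {
  set.seed(14)
  for (i in 1:5) {
    A <- matrix(rnorm(25), 5)
    S <- cov2cor(crossprod(A) + diag(5))
    net0 <- estimateGGM(S, n = 500, lambda = 0)
    ref <- samplePcor(S)
    expect_equal(unname(net0$weights), unname(ref$weights),
                 tolerance = 1e-4)
  }
})

test_that("selected model minimizes EBIC along the path", {
  set.seed(15)
  net <- chainNetwork(8, 0.25, 0.5)
  d <- simulateDataset(net, 400, levels = 4)
  fit <- estimateGGM(d)
  tab <- fit$meta$ebic
  expect_equal(which.min(tab$ebic), fit$meta$selected)
  expect_equal(tab$lambda[fit$meta$selected], fit$meta$lambda)
  # estimates are symmetric with zero diagonal, |w| < 1
  expect_equal(fit$weights, t(fit$weights))
  expect_equal(unname(diag(fit$weights)), rep(0, 8))
  expect_true(all(abs(fit$weights) < 1))
  # densest solution has at least as many edges as the selected one
  expect_gte(tab$edges[nrow(tab)], tab$edges[fit$meta$selected])
})

test_that("EBIC selection keeps every strong true edge at large n", {
  # the selected model always contains the true ring; the price of the
  # likelihood-optimal penalty is a few near-zero spurious edges
  set.seed(19)
  extras <- replicate(5, {
    net <- chainNetwork(10, 0.25, 0.5)
    d <- simulateDataset(net, 2500, 4)
    g <- estimateGGM(d)
    tr <- unname(net$weights != 0)
    es <- unname(abs(g$weights) > 1e-10)
    expect_true(all(es[tr]))                      # full recall
    expect_lt(max(abs(g$weights[!tr])), 0.08)     # extras are weak
    sum(es & !tr) / 2
  })
  expect_lte(mean(extras), 6)
})

test_that("n <= p triggers a warning but estimation proceeds", {
  set.seed(16)
  net <- chainNetwork(10, 0.2, 0)
  d <- simulateDataset(net, 150, levels = 0)
  est <- estimateCorrelations(d)
  est$n <- 9
  expect_warning(fit <- estimateGGM(est), "n <= p")
  expect_s3_class(fit, "networkModel")
})

test_that("pcorToCor round-trips through samplePcor", {
  expect_equal(unname(pcorToCor(networkModel(matrix(0, 3, 3)))), diag(3))
  w <- matrix(c(0, 0.3, 0.3, 0), 2)
  expect_equal(pcorToCor(networkModel(w))[1, 2], 0.3, tolerance = 1e-12)
  set.seed(17)
  for (i in 1:5) {
    net <- rewireNetwork(chainNetwork(10, 0.25, 0.5), 0.3)
    S <- pcorToCor(net)
    back <- samplePcor(S)
    expect_equal(unname(back$weights), unname(net$weights),
                 tolerance = 1e-8)
  }
  bad <- matrix(0.9, 4, 4)
  diag(bad) <- 0
  expect_error(pcorToCor(networkModel(bad)), "Gaussian representation")
})

test_that("parameter count is p thresholds plus p(p-1)/2 associations", {
  expect_identical(paramCount(10), 55L)
  expect_identical(paramCount(20), 210L)
  expect_identical(paramCount(50), 1275L)
  expect_identical(paramCount(1), 1L)
  expect_error(paramCount(0))
})

test_that("networks round-trip through edge-list CSV and GraphML", {
  set.seed(18)
  net <- rewireNetwork(chainNetwork(7, 0.25, 0.5), 0.4)
  f1 <- tempfile(fileext = ".csv")
  writeEdgeList(net, f1)
  b1 <- readEdgeList(f1, labels = net$labels)
  expect_equal(b1$weights, net$weights, tolerance = 1e-12)
  f2 <- tempfile(fileext = ".graphml")
  writeGraphML(net, f2)
  b2 <- readGraphML(f2)
  expect_equal(b2$weights[net$labels, net$labels], net$weights,
               tolerance = 1e-12)
})

test_that("networkModel validates its invariants", {
  expect_error(networkModel(matrix(1:9, 3)), "symmetric")
  m <- diag(3) * 0.5
  expect_error(networkModel(m), "zero diagonal")
  m2 <- matrix(0, 3, 3)
  m2[1, 2] <- m2[2, 1] <- 1.5
  expect_error(networkModel(m2), "below 1")
})
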