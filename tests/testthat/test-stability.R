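test_that("drop level 0 reproduces the full-sample centralities exactly", {
  set.seed(51)
  d <- smallOrdinalData(n = 120)
  cdb <- caseDropBoot(d, levels = 0, nBoots = 5, seed = 1)
  # identical data -> identical network; correlations are exactly 1
  # wherever they are defined (an index that is constant across nodes,
  # e.g. betweenness in a near-ring, has no correlation and records 0)
  expect_true(all(cdb$records$cor[!cdb$records$undefined] > 1 - 1e-12))
  expect_true(any(!cdb$records$undefined))
})

test_that("a constant estimator records undefined correlations as 0", {
  set.seed(52)
  d <- smallOrdinalData(n = 120)
  cdb <- caseDropBoot(d, estimator = constantEstimator(ringWeights(4, 0.3)),
                      levels = c(0.1, 0.3), nBoots = 10, seed = 1)
  expect_true(all(cdb$records$cor == 0))
  expect_true(all(cdb$records$undefined))
  cs <- suppressWarnings(csCoefficient(cdb))
  expect_equal(cs$cs, rep(0, 3))
})

test_that("case-dropping bootstrap is deterministic given the seed", {
  set.seed(53)
  d <- smallOrdinalData(n = 150)
  c1 <- caseDropBoot(d, levels = c(0.1, 0.5), nBoots = 8, seed = 11)
  c2 <- caseDropBoot(d, levels = c(0.1, 0.5), nBoots = 8, seed = 11)
  expect_identical(c1$records, c2$records)
})

test_that("drop levels leaving too few cases are refused", {
  d <- smallOrdinalData(n = 30)
  expect_error(caseDropBoot(d, levels = 0.95, nBoots = 4), "fewer than")
})

test_that("CS is the largest drop level meeting the certainty criterion", {
  # hand-built replicate table: qualifying proportion crosses 0.95
  # between levels 0.3 and 0.4
  levels <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  nPer <- 40
  mk <- function(lv) {
    prop <- c(1, 1, 0.975, 0.9, 0.5)[match(lv, levels)]
    cors <- c(rep(0.9, round(prop * nPer)),
              rep(0.1, nPer - round(prop * nPer)))
    data.frame(level = lv, rep = seq_len(nPer), index = "strength",
               cor = cors, undefined = FALSE, stringsAsFactors = FALSE)
  }
  fake <- structure(list(levels = levels, nPer = nPer,
                         records = do.call(rbind, lapply(levels, mk)),
                         original = NULL, seed = 1,
                         corMethod = "pearson", dropNodes = FALSE,
                         failures = 0L),
                    class = "caseDropResult")
  cs <- csCoefficient(fake)
  expect_equal(cs$cs, 0.3)
  # all-qualify and none-qualify boundaries
  fakeAll <- fake
  fakeAll$records$cor <- 1
  expect_equal(csCoefficient(fakeAll)$cs, max(levels))
  fakeNone <- fake
  fakeNone$records$cor <- 0
  expect_equal(csCoefficient(fakeNone)$cs, 0)
})

test_that("CS is non-increasing in the correlation threshold", {
  set.seed(54)
  d <- smallOrdinalData(n = 200)
  cdb <- caseDropBoot(d, levels = seq(0.1, 0.6, by = 0.1), nBoots = 120,
                      seed = 9)
  for (ix in c("strength", "closeness", "betweenness")) {
    prev <- Inf
    for (thr in c(0.3, 0.5, 0.7, 0.9)) {
      cs <- suppressWarnings(csCoefficient(cdb, corThreshold = thr))
      v <- cs$cs[cs$index == ix]
      expect_lte(v, prev)
      prev <- v
    }
  }
})

test_that("non-monotone qualifying proportions warn but use the maximum", {
  levels <- c(0.1, 0.2, 0.3)
  nPer <- 40
  mk <- function(lv, prop) {
    k <- round(prop * nPer)
    data.frame(level = lv, rep = seq_len(nPer), index = "strength",
               cor = c(rep(0.9, k), rep(0.1, nPer - k)),
               undefined = FALSE, stringsAsFactors = FALSE)
  }
  fake <- structure(list(levels = levels, nPer = nPer,
                         records = rbind(mk(0.1, 1), mk(0.2, 0.8),
                                         mk(0.3, 1)),
                         original = NULL, seed = 1,
                         corMethod = "pearson", dropNodes = FALSE,
                         failures = 0L),
                    class = "caseDropResult")
  expect_warning(cs <- csCoefficient(fake), "non-monotone")
  expect_equal(cs$cs, 0.3)
})

test_that("few replicates per level triggers the noise warning", {
  set.seed(55)
  d <- smallOrdinalData(n = 120)
  cdb <- caseDropBoot(d, levels = c(0.1, 0.3), nBoots = 6, seed = 2)
  expect_warning(csCoefficient(cdb), "noisy")
})

test_that("node-dropping runs through the same path on columns", {
  set.seed(56)
  net <- chainNetwork(6, 0.3, 0)
  d <- simulateDataset(net, 250, levels = 4)
  cdb <- caseDropBoot(d, levels = c(0.2, 0.4), nBoots = 10, seed = 3,
                      dropNodes = TRUE)
  expect_true(cdb$dropNodes)
  expect_true(all(cdb$records$cor >= -1 & cdb$records$cor <= 1))
  expect_equal(nrow(cdb$records), 2 * 5 * 3)  # levels x reps x indices
})

test_that("per-level summary and CS export are well formed", {
  set.seed(57)
  d <- smallOrdinalData(n = 150)
  cdb <- caseDropBoot(d, levels = c(0.1, 0.4), nBoots = 40, seed = 4)
  s <- summary(cdb)
  expect_equal(nrow(s), 2 * 3)
  expect_true(all(c("level", "index", "meanCor", "propAbove") %in%
                    names(s)))
  f1 <- tempfile(fileext = ".csv")
  writeStabilitySummary(cdb, f1)
  expect_equal(nrow(read.csv(f1)), 6)
  cs <- suppressWarnings(csCoefficient(cdb))
  f2 <- tempfile(fileext = ".json")
  writeCS(cs, f2)
  j <- jsonlite::read_json(f2)
  expect_equal(j$corThreshold, 0.7)
  expect_length(j$cs, 3)
})
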