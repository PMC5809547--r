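#' Type-6 quantile
#'
#' Quantile estimate with plotting position `h = (n + 1) * prob`
#' (Hyndman-Fan type 6), clamped to the smallest/largest order statistic
#' when `h` falls outside `[1, n]`. This estimator gives bootstrap
#' confidence intervals of proper width (the default type 7 produces
#' intervals that are too narrow), and at `prob = alpha / 2` with
#' `alpha = 2 / n` it returns the sample extremes.
#'
#' @param values Non-empty numeric vector of finite values.
#' @param prob Probability (vectorized), in `[0, 1]`.
#' @return Quantile value(s).
#' @export
#' @examples
#' quantileType6(1:10, 0.5)  # 5.5
quantileType6 <- function(values, prob) {
  if (length(values) == 0) stop("'values' must be non-empty")
  if (any(!is.finite(values))) stop("'values' must be finite")
  if (any(prob < 0 | prob > 1)) stop("'prob' must be in [0, 1]")
  x <- sort(values)
  n <- length(x)
  vapply(prob, function(pr) {
    h <- (n + 1) * pr
    if (h <= 1) return(x[1])
    if (h >= n) return(x[n])
    fl <- floor(h)
    x[fl] + (h - fl) * (x[fl + 1] - x[fl])
  }, numeric(1))
}

#' Smallest attainable bootstrap alpha
#'
#' With `nBoots` bootstrap samples, the widest CI that can be formed spans
#' the two most extreme bootstrap values, corresponding to
#' `alpha = 2 / nBoots`; no smaller significance level is attainable.
#'
#' @param nBoots Number of bootstrap samples (`>= 2`).
#' @return The minimum alpha.
#' @export
#' @examples
#' minAlpha(1000)  # 0.002
minAlpha <- function(nBoots) {
  if (length(nBoots) != 1 || is.na(nBoots) || nBoots < 2)
    stop("'nBoots' must be at least 2")
  2 / nBoots
}

#' Number of all-pairs edge-difference tests
#'
#' A p-node network has `choose(p, 2)` possible edges; testing all pairs of
#' edge weights against each other requires `choose(choose(p, 2), 2)`
#' tests.
#'
#' @param p Node count.
#' @return Number of pairwise edge-difference tests.
#' @export
#' @examples
#' edgeDiffCount(20)  # 17955
edgeDiffCount <- function(p) {
  m <- choose(p, 2)
  choose(m, 2)
}

#' Bonferroni-corrected significance level
#'
#' Divides `alpha` by the number of tests. Provided as an analytic
#' utility only: bootstrapped CIs cannot reach such extreme levels (see
#' [minAlpha()]), so corrected bootstrap difference testing is not
#' offered.
#'
#' @param alpha Nominal significance level.
#' @param nTests Number of tests.
#' @return The corrected level.
#' @export
bonferroniAlpha <- function(alpha = 0.05, nTests) alpha / nTests

# Bootstrap CI between type-6 quantiles alpha/2 and 1 - alpha/2. At the
# minimum attainable alpha (2/n) the CI is the range of the replicates:
# the plotting position h = (n+1)/n then still lies between the two most
# extreme values, but the interval is defined as spanning them.
bootCI <- function(values, alpha) {
  n <- length(values)
  if (alpha <= 2 / n + 1e-12) return(range(values))
  quantileType6(values, c(alpha / 2, 1 - alpha / 2))
}

upperTriNames <- function(labels) {
  p <- length(labels)
  idx <- which(upper.tri(diag(p)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  paste(labels[idx[, 1]], labels[idx[, 2]], sep = "--")
}

upperTriVec <- function(W) {
  idx <- which(upper.tri(W), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  W[idx]
}

newBootstrapResult <- function(type, sampleNetwork, edges, strength,
                               closeness, betweenness, seed, failures,
                               continuousData = FALSE) {
  structure(list(type = type, nBoots = nrow(edges),
                 sampleNetwork = sampleNetwork,
                 sampleCentrality = centralityTable(sampleNetwork),
                 edges = edges, strength = strength, closeness = closeness,
                 betweenness = betweenness,
                 edgeNames = colnames(edges),
                 labels = sampleNetwork$labels, seed = seed,
                 failures = failures, continuousData = continuousData),
            class = "bootstrapResult")
}

bootLoop <- function(nBoots, drawReplicate, maxFailRatio, what) {
  net1 <- NULL
  failures <- 0L
  maxFails <- ceiling(maxFailRatio * nBoots)
  out <- vector("list", nBoots)
  for (b in seq_len(nBoots)) {
    repeat {
      net1 <- tryCatch(drawReplicate(), error = function(e) e)
      if (!inherits(net1, "error")) break
      failures <- failures + 1L
      if (failures > maxFails)
        stop("more than ", round(100 * maxFailRatio),
             "% of ", what, " replicates failed; last error: ",
             conditionMessage(net1))
    }
    out[[b]] <- net1
  }
  list(nets = out, failures = failures)
}

collectStats <- function(nets, labels) {
  en <- upperTriNames(labels)
  edges <- t(vapply(nets, function(nt) upperTriVec(nt$weights),
                    numeric(length(en))))
  colnames(edges) <- en
  cent <- lapply(nets, function(nt) centralityMatrix(nt$weights))
  p <- length(labels)
  mk <- function(row) {
    m <- t(vapply(cent, function(cm) cm[row, ], numeric(p)))
    colnames(m) <- labels
    m
  }
  list(edges = edges, strength = mk(1), closeness = mk(2),
       betweenness = mk(3))
}

#' Nonparametric bootstrap of a network estimator
#'
#' Resamples the rows of the data with replacement `nBoots` times,
#' re-runs the estimator on every resample, and records the edge weights
#' and centrality indices of each replicate network. Replicates on which
#' the estimator fails are redrawn with fresh resamples (keeping `nBoots`
#' as specified, which preserves the `2 / nBoots` bound of [minAlpha()]);
#' the failure count is reported, and more than `maxFailRatio` failures
#' abort with a diagnostic.
#'
#' @param data An [ordinalDataset()] (or coercible).
#' @param estimator Function mapping a dataset to a `networkModel`;
#'   defaults to [estimateGGM()].
#' @param nBoots Number of bootstrap samples.
#' @param seed Optional integer seed; identical seeds give identical
#'   results.
#' @param maxFailRatio Abort threshold for the fraction of failed
#'   replicates.
#' @param ... Passed on to `estimator`.
#' @return An object of class `bootstrapResult` holding the sample network
#'   and statistics plus one row per replicate.
#' @export
nonparametricBoot <- function(data, estimator = estimateGGM, nBoots = 1000,
                              seed = NULL, maxFailRatio = 0.1, ...) {
  data <- asDataset(data)
  if (nBoots < 2) stop("'nBoots' must be at least 2")
  sampleNetwork <- estimator(data, ...)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data$values)
  lp <- bootLoop(nBoots, function() {
    estimator(dsRows(data, sample.int(n, n, replace = TRUE)), ...)
  }, maxFailRatio, "nonparametric bootstrap")
  st <- collectStats(lp$nets, sampleNetwork$labels)
  newBootstrapResult("nonparametric", sampleNetwork, st$edges, st$strength,
                     st$closeness, st$betweenness, seed, lp$failures)
}

#' Parametric bootstrap of a network estimator
#'
#' Draws `n` multivariate-normal cases from the correlation structure
#' implied by the network ([pcorToCor()]) for each replicate and
#' re-estimates. The replicated data are continuous, which is an
#' important difference from ordinal data: when the network was estimated
#' from polychoric correlations, prefer the nonparametric bootstrap. The
#' result carries a `continuousData` flag as a reminder. Regularized
#' (lasso) estimates are also shrunk toward zero on average, which biases
#' parametric replication; see the package vignette.
#'
#' @param network A `networkModel`.
#' @param n Cases per replicate.
#' @param nBoots Number of bootstrap samples.
#' @param estimator Function mapping a dataset to a `networkModel`.
#' @inheritParams nonparametricBoot
#' @return A `bootstrapResult` with type `"parametric"`.
#' @export
parametricBoot <- function(network, n, nBoots = 1000, seed = NULL,
                           estimator = estimateGGM, maxFailRatio = 0.1,
                           ...) {
  if (nBoots < 2) stop("'nBoots' must be at least 2")
  Sigma <- pcorToCor(network)
  if (!is.null(seed)) set.seed(seed)
  lp <- bootLoop(nBoots, function() {
    X <- MASS::mvrnorm(n, rep(0, nrow(Sigma)), Sigma)
    colnames(X) <- network$labels
    estimator(ordinalDataset(X, level = "continuous"), ...)
  }, maxFailRatio, "parametric bootstrap")
  st <- collectStats(lp$nets, network$labels)
  newBootstrapResult("parametric", network, st$edges, st$strength,
                     st$closeness, st$betweenness, seed, lp$failures,
                     continuousData = TRUE)
}

#' @export
print.bootstrapResult <- function(x, ...) {
  cat("bootstrapResult (", x$type, "): ", x$nBoots, " replicates, ",
      length(x$labels), " nodes\n", sep = "")
  if (x$failures > 0)
    cat("  redrawn replicates after estimator failure:", x$failures, "\n")
  if (x$continuousData)
    cat("  note: replicates use continuous multivariate-normal data\n")
  cat("  minimum attainable alpha:", minAlpha(x$nBoots), "\n")
  invisible(x)
}

#' Bootstrapped confidence intervals for edge weights
#'
#' Per edge: the sample value, the bootstrap mean and the
#' `1 - alpha` bootstrap CI between type-6 quantiles `alpha/2` and
#' `1 - alpha/2` of the replicate values. Rows are ordered by sample
#' weight, ties broken by bootstrap mean. These intervals show the
#' accuracy of edge-weight estimates and support comparing edges to one
#' another; they are deliberately not reported as edge-vs-zero
#' significance tests (the lasso already performed model selection).
#'
#' @param result A `bootstrapResult`.
#' @param alpha Significance level; must be at least `2 / nBoots`.
#' @return Data frame with columns `edge`, `sample`, `bootMean`, `lower`,
#'   `upper`.
#' @export
edgeCITable <- function(result, alpha = 0.05) {
  if (alpha < minAlpha(result$nBoots))
    stop("alpha = ", alpha, " is below the attainable minimum 2/nBoots = ",
         minAlpha(result$nBoots))
  sampleW <- upperTriVec(result$sampleNetwork$weights)
  bm <- colMeans(result$edges)
  ci <- apply(result$edges, 2, bootCI, alpha = alpha)
  out <- data.frame(edge = result$edgeNames, sample = sampleW,
                    bootMean = bm, lower = ci[1, ], upper = ci[2, ],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$sample, -out$bootMean), ]
  rownames(out) <- NULL
  out
}

bootStatMatrix <- function(result, kind) {
  switch(kind,
         edge = result$edges,
         strength = result$strength,
         closeness = result$closeness,
         betweenness = result$betweenness,
         stop("unknown statistic kind: ", kind))
}

resolveId <- function(id, nms, kind) {
  if (is.numeric(id)) {
    if (id < 1 || id > length(nms)) stop("invalid ", kind, " index: ", id)
    return(as.integer(id))
  }
  j <- match(as.character(id), nms)
  if (is.na(j)) stop("unknown ", kind, " id: ", id)
  j
}

#' Bootstrapped difference test
#'
#' Tests whether two edge weights or two centrality indices differ, by
#' taking the paired difference of their bootstrap values within each
#' replicate and forming a type-6 bootstrap CI around the differences.
#' The null hypothesis of equality is rejected when 0 lies outside the
#' CI; a zero-width interval at exactly 0 (frequent under the lasso,
#' which ties estimates at zero) counts as containing 0 and is therefore
#' not significant. No correction for multiple testing is applied, and no
#' bootstrap p-values are computed; decisions are CI-based only.
#'
#' @param result A `bootstrapResult`.
#' @param kind `"edge"`, `"strength"`, `"closeness"` or `"betweenness"`.
#' @param idA,idB Edge names (`"A--B"`), node labels, or indices;
#'   `idA != idB`.
#' @param alpha Significance level (at least `2 / nBoots`).
#' @return An object of class `differenceTest`: list with the CI bounds,
#'   alpha and the significance flag.
#' @export
differenceTest <- function(result, kind = c("edge", "strength", "closeness",
                                            "betweenness"),
                           idA, idB, alpha = 0.05) {
  kind <- match.arg(kind)
  if (alpha < minAlpha(result$nBoots))
    stop("alpha = ", alpha, " is below the attainable minimum 2/nBoots = ",
         minAlpha(result$nBoots))
  M <- bootStatMatrix(result, kind)
  nms <- colnames(M)
  a <- resolveId(idA, nms, kind)
  b <- resolveId(idB, nms, kind)
  if (a == b) stop("'idA' and 'idB' must differ")
  d <- M[, a] - M[, b]
  ci <- bootCI(d, alpha)
  structure(list(kind = kind, idA = nms[a], idB = nms[b],
                 lower = ci[1], upper = ci[2], alpha = alpha,
                 significant = !(ci[1] <= 0 && ci[2] >= 0)),
            class = "differenceTest")
}

#' @export
print.differenceTest <- function(x, ...) {
  cat("bootstrapped difference test (", x$kind, "): ", x$idA, " vs ",
      x$idB, "\n", sep = "")
  cat(sprintf("  %g%% CI of difference: (%.4f, %.4f) -> %s\n",
              100 * (1 - x$alpha), x$lower, x$upper,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' All-pairs bootstrapped difference tests
#'
#' Runs [differenceTest()] for every pair of edges or nodes and returns
#' the boolean significance matrix plus the analytic test count. No
#' multiple-testing correction is applied (Bonferroni-corrected bootstrap
#' testing is unattainable at realistic replicate counts; see
#' [minAlpha()] and [bonferroniAlpha()]).
#'
#' @inheritParams differenceTest
#' @param onlyNonZero For `kind = "edge"`, restrict to edges that are
#'   nonzero in the sample network.
#' @return List with elements `kind`, `alpha`, `significant` (symmetric
#'   logical matrix), `nTests` and `nSignificant`.
#' @export
differenceMatrix <- function(result, kind = c("edge", "strength",
                                              "closeness", "betweenness"),
                             alpha = 0.05, onlyNonZero = FALSE) {
  kind <- match.arg(kind)
  if (alpha < minAlpha(result$nBoots))
    stop("alpha = ", alpha, " is below the attainable minimum 2/nBoots = ",
         minAlpha(result$nBoots))
  M <- bootStatMatrix(result, kind)
  if (kind == "edge" && onlyNonZero) {
    keep <- abs(upperTriVec(result$sampleNetwork$weights)) > 1e-10
    M <- M[, keep, drop = FALSE]
  }
  m <- ncol(M)
  sig <- matrix(FALSE, m, m, dimnames = list(colnames(M), colnames(M)))
  if (m > 1) {
    for (a in seq_len(m - 1)) {
      for (b in (a + 1):m) {
        ci <- bootCI(M[, a] - M[, b], alpha)
        s <- !(ci[1] <= 0 && ci[2] >= 0)
        sig[a, b] <- s
        sig[b, a] <- s
      }
    }
  }
  list(kind = kind, alpha = alpha, significant = sig,
       nTests = choose(m, 2), nSignificant = sum(sig[upper.tri(sig)]))
}

#' Write a CI table to CSV
#'
#' @param table Data frame from [edgeCITable()].
#' @param path Output file path.
#' @export
writeCITable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write an all-pairs difference matrix
#'
#' CSV of the boolean significance matrix; with `json = TRUE` a compact
#' JSON object `{kind, alpha, pairs}` instead.
#'
#' @param dm Result of [differenceMatrix()].
#' @param path Output file path.
#' @param json Write JSON instead of CSV.
#' @export
writeDifferenceMatrix <- function(dm, path, json = FALSE) {
  if (json) {
    sig <- dm$significant
    idx <- which(upper.tri(sig) & sig, arr.ind = TRUE)
    pairs <- lapply(seq_len(nrow(idx)), function(r)
      list(a = rownames(sig)[idx[r, 1]], b = colnames(sig)[idx[r, 2]]))
    jsonlite::write_json(list(kind = dm$kind, alpha = dm$alpha,
                              nTests = dm$nTests,
                              nSignificant = dm$nSignificant,
                              pairs = pairs),
                         path, auto_unbox = TRUE)
  } else {
    utils::write.csv(as.data.frame(dm$significant), path, row.names = TRUE)
  }
  invisible(path)
}
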