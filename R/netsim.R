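#' Chain (ring) network
#'
#' Builds the closed chain used throughout the simulation studies: node i
#' is connected to its two ring neighbours, all edge weights have the same
#' magnitude, and `ceiling(propNegative * nEdges)` randomly chosen edges
#' are negated. With constant `|w|` every node is topologically equivalent,
#' so all centrality indices are exactly equal across nodes — the
#' equal-centrality null model. An open-chain option exists
#' (`closed = FALSE`) but the closed ring is the default.
#'
#' @param p Node count (`>= 3`).
#' @param weight Edge-weight magnitude (0.25 or 0.3 in the validation
#'   studies).
#' @param propNegative Proportion of edges given a negative sign.
#' @param seed Optional integer seed (sign placement is random).
#' @param closed Closed ring (default) or open chain.
#' @return A `networkModel` whose implied precision is verified positive
#'   definite.
#' @export
chainNetwork <- function(p = 10, weight = 0.25, propNegative = 0.5,
                         seed = NULL, closed = TRUE) {
  if (p < 3) stop("'p' must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  labels <- paste0("V", seq_len(p))
  W <- matrix(0, p, p, dimnames = list(labels, labels))
  edges <- cbind(seq_len(p - 1), 2:p)
  if (closed) edges <- rbind(edges, c(p, 1))
  nNeg <- ceiling(propNegative * nrow(edges))
  signs <- rep(1, nrow(edges))
  if (nNeg > 0) signs[sample.int(nrow(edges), nNeg)] <- -1
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]
    j <- edges[e, 2]
    W[i, j] <- W[j, i] <- signs[e] * weight
  }
  K <- -W
  diag(K) <- 1
  if (inherits(tryCatch(chol(K), error = function(e) e), "error"))
    stop("chain network has no Gaussian representation (|weight| too large)")
  networkModel(W, labels = labels,
               meta = list(method = "chain", weight = weight,
                           propNegative = propNegative, closed = closed))
}

#' Watts-Strogatz rewiring of a network
#'
#' Each edge is independently selected for rewiring with probability
#' `prob`; a selected edge keeps its first endpoint and weight (including
#' sign) and its other endpoint is reassigned uniformly among nodes that
#' create neither a self-loop nor a duplicate edge. Edge count and the
#' multiset of weights are preserved. The rewired network must remain a
#' valid partial correlation structure (positive-definite implied
#' precision); invalid draws are redrawn in full, up to `maxRetries`
#' times.
#'
#' @param network A `networkModel` (typically a [chainNetwork()]).
#' @param prob Per-edge rewiring probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param maxRetries Bound on full redraws after positive-definiteness
#'   failures.
#' @return A `networkModel`.
#' @export
rewireNetwork <- function(network, prob, seed = NULL, maxRetries = 100) {
  if (prob < 0 || prob > 1) stop("'prob' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  W0 <- network$weights
  p <- nrow(W0)
  idx <- which(upper.tri(W0) & W0 != 0, arr.ind = TRUE)
  for (attempt in seq_len(maxRetries)) {
    W <- matrix(0, p, p, dimnames = dimnames(W0))
    elist <- idx
    for (e in seq_len(nrow(elist))) {
      i <- elist[e, 1]
      j <- elist[e, 2]
      if (stats::runif(1) < prob) {
        # keep endpoint i; exclude i itself, the current partner, and any
        # node already adjacent to i (no self-loops, no duplicate edges)
        taken <- unique(c(i, j, elist[-e, 2][elist[-e, 1] == i],
                          elist[-e, 1][elist[-e, 2] == i]))
        cand <- setdiff(seq_len(p), taken)
        if (length(cand) > 0)
          elist[e, ] <- sort(c(i, cand[sample.int(length(cand), 1)]))
      }
    }
    for (e in seq_len(nrow(elist)))
      W[elist[e, 1], elist[e, 2]] <- W[elist[e, 2], elist[e, 1]] <-
        W0[idx[e, 1], idx[e, 2]]
    K <- -W
    diag(K) <- 1
    if (!inherits(tryCatch(chol(K), error = function(e) e), "error")) {
      meta <- network$meta
      meta$rewired <- prob
      return(networkModel(W, labels = network$labels, meta = meta))
    }
  }
  stop("rewiring failed to produce a positive-definite network after ",
       maxRetries, " retries")
}

#' Simulate (ordinal) data from a partial correlation network
#'
#' Draws `n` multivariate-normal cases from the correlation implied by the
#' network ([pcorToCor()]). With `levels > 0` each variable is then made
#' ordinal: `levels - 1` thresholds are drawn i.i.d. standard normal,
#' sorted, and categories `0 .. levels - 1` assigned by interval — a
#' strictly monotone transform of the latent values. Thresholds are
#' redrawn for a variable whenever some category ends up unobserved
#' (polychoric estimation needs every category present). `levels = 0`
#' skips ordinalization and returns continuous data.
#'
#' @param network A `networkModel`.
#' @param n Number of cases.
#' @param levels Number of ordinal categories (default 4); 0 for
#'   continuous output.
#' @param seed Optional integer seed.
#' @param maxRedraws Bound on threshold redraws per variable.
#' @return An [ordinalDataset()].
#' @export
simulateDataset <- function(network, n, levels = 4, seed = NULL,
                            maxRedraws = 1000) {
  if (!is.null(seed)) set.seed(seed)
  Sigma <- pcorToCor(network)
  X <- MASS::mvrnorm(n, rep(0, nrow(Sigma)), Sigma)
  colnames(X) <- network$labels
  if (levels == 0)
    return(ordinalDataset(X, level = "continuous"))
  if (levels < 2) stop("'levels' must be 0 or at least 2")
  for (j in seq_len(ncol(X))) {
    for (tr in seq_len(maxRedraws)) {
      th <- sort(stats::rnorm(levels - 1))
      cats <- findInterval(X[, j], th)
      if (length(unique(cats)) == levels) break
      if (tr == maxRedraws)
        stop("could not draw thresholds with all categories present for ",
             "variable ", network$labels[j], " (n too small?)")
    }
    X[, j] <- cats
  }
  ordinalDataset(X, level = "ordinal")
}

#' Simulation design for the validation studies
#'
#' Bundles all condition parameters of the simulation studies: chain
#' networks of `p` nodes with weight magnitude `weight` and
#' `propNegative` negative edges, rewired with each probability in
#' `rewiring`, sampled at each size in `n`, made ordinal with `levels`
#' categories, and analysed with `nBoots` bootstrap samples per dataset.
#' `scale = "desk"` (default) uses scaled-down settings that run on a
#' single desktop core — 100 replicates per condition and 200 bootstrap
#' samples; `scale = "full"` uses 1000 replicates and 1000 bootstrap
#' samples per dataset.
#'
#' @param p Node count.
#' @param weight Edge-weight magnitude.
#' @param propNegative Proportion of negative edges.
#' @param rewiring Vector of rewiring probabilities.
#' @param n Vector of sample sizes.
#' @param replicates Datasets per condition (overrides the scale preset).
#' @param levels Ordinal categories.
#' @param nBoots Bootstrap samples per dataset (overrides the scale
#'   preset).
#' @param alpha Significance level(s) for the difference-test studies.
#' @param dropLevels Drop-proportion grid for the CS study.
#' @param gamma EBIC hyperparameter used for estimation.
#' @param seed Integer seed for the whole study.
#' @param scale `"desk"` or `"full"` preset.
#' @return An object of class `simulationDesign`.
#' @export
simulationDesign <- function(p = 10, weight = 0.25, propNegative = 0.5,
                             rewiring = c(0, 0.1, 0.5, 1),
                             n = c(100, 250, 500, 1000, 2500, 5000),
                             replicates = NULL, levels = 4, nBoots = NULL,
                             alpha = 0.05,
                             dropLevels = seq(0.1, 0.75, length.out = 10),
                             gamma = 0.5, seed = 1,
                             scale = c("desk", "full")) {
  scale <- match.arg(scale)
  if (is.null(replicates)) replicates <- if (scale == "desk") 100 else 1000
  if (is.null(nBoots)) nBoots <- if (scale == "desk") 200 else 1000
  stopifnot(replicates >= 1, all(rewiring >= 0 & rewiring <= 1),
            all(propNegative >= 0 & propNegative <= 1), all(n > 0))
  structure(list(p = p, weight = weight, propNegative = propNegative,
                 rewiring = rewiring, n = n, replicates = replicates,
                 levels = levels, nBoots = nBoots, alpha = alpha,
                 dropLevels = dropLevels, gamma = gamma, seed = seed,
                 scale = scale),
            class = "simulationDesign")
}

#' @export
print.simulationDesign <- function(x, ...) {
  cat("simulationDesign (", x$scale, " scale): p = ", x$p, ", |w| = ",
      x$weight, ", ", 100 * x$propNegative, "% negative edges\n", sep = "")
  cat("  rewiring:", paste(x$rewiring, collapse = ", "),
      " n:", paste(x$n, collapse = ", "), "\n")
  cat("  replicates per condition:", x$replicates,
      " bootstrap samples:", x$nBoots, " seed:", x$seed, "\n")
  invisible(x)
}

#' Expected number of simulated datasets of a study
#'
#' CS and centrality-difference studies enumerate rewiring x sample-size
#' conditions; the edge-difference study enumerates sample sizes only.
#'
#' @param design A [simulationDesign()].
#' @param study Study name.
#' @return Integer dataset count.
#' @export
studyDatasetCount <- function(design, study = c("cs", "edge_diff",
                                                "centrality_diff")) {
  study <- match.arg(study)
  base <- if (study == "edge_diff") length(design$n)
    else length(design$rewiring) * length(design$n)
  as.integer(base * design$replicates)
}

simulateOne <- function(design, rw, n, maxRetries = 20) {
  for (tr in seq_len(maxRetries)) {
    net <- chainNetwork(design$p, design$weight, design$propNegative)
    if (rw > 0) net <- rewireNetwork(net, rw)
    dat <- tryCatch(simulateDataset(net, n, design$levels),
                    error = function(e) e)
    if (!inherits(dat, "error")) return(list(net = net, dat = dat))
  }
  stop("failed to simulate a dataset after ", maxRetries, " attempts")
}

#' Run a validation study
#'
#' Executes one of the three simulation studies end-to-end — per dataset:
#' simulate from a (possibly rewired) chain network, estimate the
#' regularized partial correlation network from polychoric correlations,
#' bootstrap, and test:
#'
#' * `"cs"`: case-dropping bootstrap and CS coefficient per index; the
#'   result records the CS distribution per condition.
#' * `"edge_diff"`: nonparametric bootstrap and all-pairs difference
#'   tests among edges nonzero in the *true* network, at each `alpha`;
#'   requires a design with `rewiring = 0` and `propNegative = 0` (every
#'   true edge shares the same weight, so all differences are null).
#' * `"centrality_diff"`: nonparametric bootstrap and all-pairs
#'   difference tests for each centrality index at `alpha[1]`.
#'
#' Datasets on which estimation fails are redrawn (counted in
#' `failures`). The full run is deterministic given `design$seed`.
#'
#' @param design A [simulationDesign()].
#' @param study `"cs"`, `"edge_diff"` or `"centrality_diff"`.
#' @param verbose Print progress per condition.
#' @return An object of class `simulationResult` with per-replicate
#'   `records` and the design.
#' @export
runStudy <- function(design, study = c("cs", "edge_diff",
                                       "centrality_diff"),
                     verbose = FALSE) {
  study <- match.arg(study)
  if (study == "edge_diff" &&
      (any(design$rewiring != 0) || design$propNegative != 0))
    stop("the edge-difference study requires rewiring = 0 and ",
         "propNegative = 0 (all true edges equal)")
  set.seed(design$seed)
  rewirings <- if (study == "edge_diff") 0 else design$rewiring
  recs <- list()
  failures <- 0L
  estArgs <- list(gamma = design$gamma)
  for (rw in rewirings) {
    for (nn in design$n) {
      if (verbose)
        message("study ", study, ": rewiring ", rw, ", n ", nn)
      for (rep in seq_len(design$replicates)) {
        sim <- simulateOne(design, rw, nn)
        res <- tryCatch(
          studyReplicate(design, study, sim, rw, nn, rep, estArgs),
          error = function(e) e)
        while (inherits(res, "error")) {
          failures <- failures + 1L
          if (failures > ceiling(0.25 * studyDatasetCount(design, study)))
            stop("too many failed study replicates; last error: ",
                 conditionMessage(res))
          sim <- simulateOne(design, rw, nn)
          res <- tryCatch(
            studyReplicate(design, study, sim, rw, nn, rep, estArgs),
            error = function(e) e)
        }
        recs[[length(recs) + 1L]] <- res
      }
    }
  }
  structure(list(study = study, design = design,
                 records = do.call(rbind, recs), failures = failures),
            class = "simulationResult")
}

studyReplicate <- function(design, study, sim, rw, nn, rep, estArgs) {
  est <- function(d) do.call(estimateGGM, c(list(d), estArgs))
  if (study == "cs") {
    cdb <- caseDropBoot(sim$dat, estimator = est,
                        levels = design$dropLevels,
                        nBoots = design$nBoots)
    cs <- suppressWarnings(csCoefficient(cdb))
    return(data.frame(study = study, rewiring = rw, n = nn, rep = rep,
                      index = cs$index, value = cs$cs,
                      stringsAsFactors = FALSE))
  }
  bt <- nonparametricBoot(sim$dat, estimator = est,
                          nBoots = design$nBoots)
  if (study == "edge_diff") {
    trueEdges <- which(abs(upperTriVec(sim$net$weights)) > 1e-10)
    M <- bt$edges[, trueEdges, drop = FALSE]
    out <- lapply(design$alpha, function(al) {
      nr <- pairRejections(M, al)
      data.frame(study = study, rewiring = rw, n = nn, rep = rep,
                 index = "edge", alpha = al,
                 nPairs = unname(nr["pairs"]),
                 nRejected = unname(nr["rejected"]),
                 value = unname(nr["rejected"] / nr["pairs"]),
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, out))
  }
  al <- design$alpha[1]
  out <- lapply(c("strength", "closeness", "betweenness"), function(ix) {
    nr <- pairRejections(bootStatMatrix(bt, ix), al)
    data.frame(study = study, rewiring = rw, n = nn, rep = rep,
               index = ix, alpha = al, nPairs = unname(nr["pairs"]),
               nRejected = unname(nr["rejected"]),
               value = unname(nr["rejected"] / nr["pairs"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# count significant all-pairs paired-difference CIs on a replicate matrix
pairRejections <- function(M, alpha) {
  m <- ncol(M)
  rej <- 0L
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) {
      ci <- bootCI(M[, a] - M[, b], alpha)
      if (!(ci[1] <= 0 && ci[2] >= 0)) rej <- rej + 1L
    }
  }
  c(pairs = choose(m, 2), rejected = rej)
}

#' @export
print.simulationResult <- function(x, ...) {
  cat("simulationResult (", x$study, "): ", nrow(x$records),
      " records, ", x$failures, " redrawn datasets\n", sep = "")
  invisible(x)
}

#' Summarize a validation study
#'
#' For the difference-test studies: per-condition rejection rate with its
#' Monte-Carlo standard error (computed over datasets, the independent
#' replication unit). For the CS study: per-condition median CS and the
#' proportions below the 0.25/0.5 interpretation bands.
#'
#' @param object A `simulationResult`.
#' @param ... Unused.
#' @return Data frame of per-condition summaries.
#' @export
summary.simulationResult <- function(object, ...) {
  r <- object$records
  if (object$study == "cs") {
    sp <- split(r, list(r$rewiring, r$n, r$index), drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(g)
      data.frame(rewiring = g$rewiring[1], n = g$n[1], index = g$index[1],
                 medianCS = stats::median(g$value),
                 propBelow25 = mean(g$value < 0.25),
                 propBelow50 = mean(g$value < 0.5),
                 replicates = nrow(g), stringsAsFactors = FALSE)))
  } else {
    sp <- split(r, list(r$rewiring, r$n, r$index, r$alpha), drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(g)
      data.frame(rewiring = g$rewiring[1], n = g$n[1], index = g$index[1],
                 alpha = g$alpha[1], rate = mean(g$value),
                 mcse = stats::sd(g$value) / sqrt(nrow(g)),
                 replicates = nrow(g), stringsAsFactors = FALSE)))
  }
  out <- out[order(out$rewiring, out$n, out$index), ]
  rownames(out) <- NULL
  out
}

#' Write study records as tidy CSV
#'
#' The seed and the full design are embedded as `#`-prefixed JSON header
#' lines, so every result file is self-describing.
#'
#' @param result A `simulationResult`.
#' @param path Output file path.
#' @export
writeStudy <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  dj <- jsonlite::toJSON(result$design[setdiff(names(result$design), "")],
                         auto_unbox = TRUE, digits = NA)
  writeLines(paste0("# study: ", result$study), con)
  writeLines(paste0("# seed: ", result$design$seed), con)
  writeLines(paste0("# design: ", dj), con)
  utils::write.table(result$records, con, sep = ",", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}
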