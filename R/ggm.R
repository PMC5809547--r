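#' Construct a network model
#'
#' A `networkModel` stores the symmetric zero-diagonal matrix of edge
#' weights (partial correlations) of a Gaussian graphical model together
#' with node labels and estimation metadata.
#'
#' @param weights Symmetric p x p numeric matrix with zero diagonal and all
#'   absolute entries below 1.
#' @param labels Node names; defaults to the matrix dimnames or `V1..Vp`.
#' @param meta List of estimation metadata (selected lambda, gamma, lambda
#'   grid, n, method tag).
#' @return An object of class `networkModel`.
#' @export
networkModel <- function(weights, labels = NULL, meta = list()) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop("'weights' must be a square matrix")
  if (max(abs(weights - t(weights))) > 1e-8)
    stop("'weights' must be symmetric")
  weights <- (weights + t(weights)) / 2
  if (any(abs(diag(weights)) > 1e-10))
    stop("'weights' must have a zero diagonal")
  diag(weights) <- 0
  if (any(abs(weights) >= 1))
    stop("partial correlations must have absolute value below 1")
  p <- nrow(weights)
  if (is.null(labels)) labels <- rownames(weights)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  if (length(labels) != p) stop("'labels' must have one entry per node")
  if (!is.null(meta$lambdaGrid) && length(meta$lambdaGrid) > 1 &&
      any(diff(meta$lambdaGrid) >= 0))
    stop("stored lambda grid must be strictly decreasing")
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels, meta = meta),
            class = "networkModel")
}

#' @export
print.networkModel <- function(x, ...) {
  p <- length(x$labels)
  e <- sum(abs(x$weights[upper.tri(x$weights)]) > 1e-10)
  cat("networkModel: ", p, " nodes, ", e, "/", choose(p, 2),
      " nonzero edges\n", sep = "")
  if (!is.null(x$meta$lambda))
    cat("  glasso lambda = ", signif(x$meta$lambda, 4),
        ", EBIC gamma = ", x$meta$gamma, ", n = ", x$meta$n, "\n", sep = "")
  invisible(x)
}

#' Extract the edge-weight matrix of a network
#'
#' @param network A `networkModel`.
#' @return The symmetric zero-diagonal weight matrix.
#' @export
netWeights <- function(network) network$weights

#' Unregularized partial correlations from a correlation matrix
#'
#' Inverts the correlation matrix and standardizes the negated precision
#' entries: `w_ij = -k_ij / sqrt(k_ii * k_jj)`.
#'
#' @param corr A `correlationEstimate` or a positive-definite correlation
#'   matrix.
#' @return A `networkModel` of saturated (non-sparse) partial correlations.
#' @export
samplePcor <- function(corr) {
  est <- if (inherits(corr, "correlationEstimate")) corr else NULL
  m <- if (is.null(est)) corr else est$matrix
  K <- tryCatch(solve(m), error = function(e)
    stop("correlation matrix is singular"))
  d <- 1 / sqrt(diag(K))
  W <- -K * (d %o% d)
  diag(W) <- 0
  networkModel((W + t(W)) / 2, labels = colnames(m),
               meta = list(method = "pcor", n = if (!is.null(est)) est$n))
}

#' Extended BIC of a Gaussian precision matrix
#'
#' Computes `-2 * l(Theta) + E * log(n) + 4 * E * gamma * log(p)` where
#' `l` is the Gaussian log-likelihood `n/2 * (log det Theta -
#' trace(S Theta))` (constant terms dropped) and `E` is the number of
#' nonzero off-diagonal entries in the upper triangle. With `gamma = 0`
#' this reduces to the ordinary BIC-penalized deviance.
#'
#' @param precision Positive-definite p x p precision matrix.
#' @param corr Correlation (or covariance) matrix `S`, or a
#'   `correlationEstimate`.
#' @param n Sample size.
#' @param gamma EBIC hyperparameter, `>= 0`.
#' @return The EBIC value (scalar).
#' @export
ebicScore <- function(precision, corr, n, gamma = 0.5) {
  S <- if (inherits(corr, "correlationEstimate")) corr$matrix else corr
  if (n <= 0) stop("'n' must be positive")
  if (gamma < 0) stop("'gamma' must be non-negative")
  ch <- tryCatch(chol(precision), error = function(e) NULL)
  if (is.null(ch)) stop("'precision' must be positive definite")
  p <- nrow(S)
  ll <- n / 2 * (2 * sum(log(diag(ch))) - sum(S * precision))
  E <- sum(abs(precision[upper.tri(precision)]) > 1e-10)
  -2 * ll + E * log(n) + 4 * E * gamma * log(p)
}

#' Estimate a regularized Gaussian graphical model
#'
#' Runs the graphical lasso over a log-spaced penalty grid from
#' `lambda_max` (the smallest penalty producing an empty graph, i.e. the
#' largest absolute off-diagonal input correlation) down to
#' `lambdaRatio * lambda_max`, scores every solution with the extended BIC
#' ([ebicScore()]), and returns the EBIC-minimizing network as partial
#' correlations. Ordinal data are routed through polychoric correlations
#' ([estimateCorrelations()]); non-positive-definite inputs are repaired
#' with [nearestPD()].
#'
#' @param x An [ordinalDataset()] (or matrix/data frame of raw scores), a
#'   `correlationEstimate`, or a correlation matrix (then `n` is required).
#' @param n Sample size; only needed when `x` is a plain correlation
#'   matrix.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param nLambda Number of penalty values on the grid.
#' @param lambdaRatio Ratio of the smallest to the largest penalty.
#' @param lambda Optional fixed penalty; bypasses the path/EBIC selection.
#' @param tol Convergence tolerance of the glasso inner solver.
#' @param ... Passed to [estimateCorrelations()] when `x` is raw data.
#' @return A `networkModel`; `meta$ebic` holds the per-lambda selection
#'   table (lambda, log-likelihood, edge count, EBIC) and `meta$lambda` the
#'   selected penalty.
#' @export
estimateGGM <- function(x, n = NULL, gamma = 0.5, nLambda = 100,
                        lambdaRatio = 0.01, lambda = NULL, tol = 1e-4, ...) {
  if (inherits(x, "correlationEstimate")) {
    S <- x$matrix
    if (is.null(n)) n <- x$n
    inputMethod <- x$method
  } else if (is.matrix(x) && isSymmetric(unname(x), tol = 1e-8) &&
             all(abs(diag(x) - 1) < 1e-8) && !is.null(n)) {
    S <- x
    inputMethod <- "matrix"
  } else {
    est <- estimateCorrelations(x, computeThresholds = FALSE, ...)
    S <- est$matrix
    n <- est$n
    inputMethod <- est$method
  }
  if (is.null(n) || is.na(n)) stop("sample size 'n' is required")
  p <- nrow(S)
  if (n <= p)
    warning("n <= p: estimates rely entirely on regularization",
            call. = FALSE)
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-8) S <- nearestPD(S)
  labels <- colnames(S)
  if (!is.null(lambda)) {
    fit <- .cppGlassoSingle(S, max(lambda, 1e-10), min(tol, 1e-8), 1000L)
    W <- fit$pcor
    W[abs(W) < 1e-10] <- 0
    return(networkModel(W, labels = labels,
                        meta = list(lambda = lambda, gamma = gamma, n = n,
                                    inputMethod = inputMethod,
                                    method = "glasso-fixed")))
  }
  path <- .cppGlassoPath(S, n, gamma, as.integer(nLambda), lambdaRatio,
                         tol, 200L)
  W <- path$pcor
  W[abs(W) < 1e-10] <- 0
  sel <- path$selected
  networkModel(W, labels = labels,
               meta = list(lambda = path$lambda[sel], gamma = gamma,
                           lambdaGrid = as.numeric(path$lambda),
                           selected = sel, n = n,
                           inputMethod = inputMethod, method = "EBICglasso",
                           ebic = data.frame(lambda = as.numeric(path$lambda),
                                             loglik = as.numeric(path$loglik),
                                             edges = as.integer(path$edges),
                                             ebic = as.numeric(path$ebic))))
}

#' Correlation matrix implied by a partial correlation network
#'
#' Builds the implied precision matrix (unit diagonal, off-diagonal
#' `-w_ij`), inverts it and rescales to unit diagonal. Round-tripping the
#' result through [samplePcor()] recovers the input weights, and the
#' result is the multivariate-normal correlation used by the parametric
#' bootstrap and the data simulator.
#'
#' @param network A `networkModel` (or weight matrix).
#' @return The implied p x p correlation matrix.
#' @export
pcorToCor <- function(network) {
  W <- if (inherits(network, "networkModel")) network$weights else network
  K <- -W
  diag(K) <- 1
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) stop("network has no Gaussian representation")
  S <- chol2inv(ch)
  S <- stats::cov2cor(S)
  dimnames(S) <- dimnames(W)
  (S + t(S)) / 2
}

#' Number of free parameters of a p-node Gaussian graphical model
#'
#' One threshold per node plus one pairwise association per node pair:
#' `p + p * (p - 1) / 2`.
#'
#' @param p Node count (`>= 1`).
#' @return Integer parameter count.
#' @export
#' @examples
#' paramCount(10)  # 55
paramCount <- function(p) {
  if (any(p < 1)) stop("'p' must be at least 1")
  as.integer(p + p * (p - 1) / 2)
}

#' Write a network as a weighted edge list (CSV)
#'
#' Columns `node_i, node_j, weight`, one row per nonzero edge (upper
#' triangle).
#'
#' @param network A `networkModel`.
#' @param path Output file path.
#' @export
writeEdgeList <- function(network, path) {
  W <- network$weights
  idx <- which(upper.tri(W) & abs(W) > 1e-10, arr.ind = TRUE)
  df <- data.frame(node_i = network$labels[idx[, 1]],
                   node_j = network$labels[idx[, 2]],
                   weight = W[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a network from a weighted edge list (CSV)
#'
#' @param path File written by [writeEdgeList()].
#' @param labels Optional full node set (keeps isolated nodes); defaults to
#'   the nodes appearing in the file.
#' @return A `networkModel`.
#' @export
readEdgeList <- function(path, labels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(labels))
    labels <- sort(unique(c(as.character(df$node_i),
                            as.character(df$node_j))))
  p <- length(labels)
  W <- matrix(0, p, p, dimnames = list(labels, labels))
  for (r in seq_len(nrow(df))) {
    i <- match(as.character(df$node_i[r]), labels)
    j <- match(as.character(df$node_j[r]), labels)
    W[i, j] <- W[j, i] <- df$weight[r]
  }
  networkModel(W, labels = labels, meta = list(method = "imported"))
}

#' Write a network in GraphML format
#'
#' @param network A `networkModel`.
#' @param path Output file path.
#' @export
writeGraphML <- function(network, path) {
  g <- igraph::graph_from_adjacency_matrix(network$weights,
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- network$labels
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a network from GraphML
#'
#' @param path File written by [writeGraphML()].
#' @return A `networkModel`.
#' @export
readGraphML <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  networkModel((W + t(W)) / 2, labels = igraph::V(g)$name,
               meta = list(method = "imported"))
}
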