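#' Estimate thresholds of an ordinal variable
#'
#' First step of two-step polychoric estimation: the K-1 thresholds of a
#' K-category ordinal variable are the standard-normal quantiles of the
#' cumulative category proportions. Thresholds depend only on the category
#' ordering, so they are invariant to any strictly monotone relabeling.
#'
#' @param column Vector of ordinal scores (missing values are dropped).
#' @return Numeric vector of K-1 strictly increasing thresholds.
#' @export
#' @examples
#' estimateThresholds(c(0, 0, 1, 1))  # single threshold at 0
estimateThresholds <- function(column) {
  v <- column[!is.na(column)]
  tab <- table(v)
  if (length(tab) < 2L)
    stop("degenerate variable: fewer than 2 observed categories")
  cum <- cumsum(as.numeric(tab)) / length(v)
  stats::qnorm(cum[-length(cum)])
}

#' Repair a symmetric matrix to positive definiteness
#'
#' Clips eigenvalues at `pdFloor` and rescales the result back to unit
#' diagonal. Matrices that are already positive definite (smallest
#' eigenvalue at or above the floor) are returned unchanged.
#'
#' @param m Symmetric matrix.
#' @param pdFloor Smallest admissible eigenvalue after repair.
#' @return A symmetric positive-definite matrix with unit diagonal.
#' @export
nearestPD <- function(m, pdFloor = 1e-6) {
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      !isTRUE(all.equal(m, t(m), tolerance = 1e-8, check.attributes = FALSE)))
    stop("'m' must be a symmetric square matrix")
  m <- (m + t(m)) / 2
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) >= pdFloor)
    return(m)
  out <- m
  # rescaling to unit diagonal can push the smallest eigenvalue slightly
  # back under the floor, so clip a little above it and iterate
  for (it in 1:100) {
    e <- eigen(out, symmetric = TRUE)
    if (min(e$values) >= pdFloor) break
    v <- pmax(e$values, pdFloor * 1.1)
    out <- stats::cov2cor(e$vectors %*% (v * t(e$vectors)))
    out <- (out + t(out)) / 2
  }
  dimnames(out) <- dimnames(m)
  out
}

# two-step polyserial correlation: ordinal codes y (0-based), continuous x
polyserialPair <- function(x, y, rhoMax = 0.999) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(unique(y)) < 2L || stats::sd(x) == 0)
    stop("degenerate variable pair in polyserial estimation")
  z <- (x - mean(x)) / stats::sd(x)
  tau <- estimateThresholds(y)
  bounds <- c(-Inf, tau, Inf)
  k <- match(y, sort(unique(y)))  # 1-based category index
  nll <- function(r) {
    s <- sqrt(1 - r^2)
    up <- stats::pnorm((bounds[k + 1] - r * z) / s)
    lo <- stats::pnorm((bounds[k] - r * z) / s)
    -sum(log(pmax(up - lo, 1e-12)))
  }
  stats::optimize(nll, c(-rhoMax, rhoMax), tol = 1e-7)$minimum
}

#' Estimate a correlation matrix for network input
#'
#' Computes the correlation matrix used as input to Gaussian graphical
#' model estimation. Method dispatch per pair of variables: ordinal-ordinal
#' pairs use the two-step maximum-likelihood polychoric correlation
#' (thresholds fixed at their marginal estimates, then a one-dimensional
#' likelihood maximization for the latent correlation), continuous pairs
#' use the product-moment correlation, and mixed pairs use the two-step
#' polyserial correlation. The result is passed through [nearestPD()].
#'
#' Contingency tables containing an empty cell receive a continuity
#' constant of 0.5 added to every cell before likelihood evaluation
#' (disable with `correction = FALSE`); this prevents boundary estimates
#' at plus/minus 1.
#'
#' @param data An [ordinalDataset()], matrix or data frame.
#' @param method `"auto"` dispatches per pair on the declared measurement
#'   level; `"pearson"` forces product-moment correlations throughout.
#' @param missing `"pairwise"` (default) uses pairwise-complete
#'   observations; `"listwise"` drops incomplete rows first.
#' @param correction Apply the 0.5 continuity constant to tables with
#'   empty cells.
#' @param rhoMax Boundary clamp for the latent correlation search.
#' @param pdFloor Eigenvalue floor passed to [nearestPD()].
#' @param computeThresholds Attach per-variable threshold vectors to the
#'   result. The thresholds are not needed for network estimation itself,
#'   so callers in tight resampling loops disable this.
#' @return An object of class `correlationEstimate`: list with elements
#'   `matrix`, `thresholds` (per ordinal variable), `n` (effective sample
#'   size), `method` and `labels`.
#' @export
estimateCorrelations <- function(data, method = c("auto", "pearson"),
                                 missing = c("pairwise", "listwise"),
                                 correction = TRUE, rhoMax = 0.999,
                                 pdFloor = 1e-6, computeThresholds = TRUE) {
  method <- match.arg(method)
  missing <- match.arg(missing)
  data <- asDataset(data)
  if (missing == "listwise") {
    keep <- stats::complete.cases(data$values)
    if (sum(keep) < 3L) stop("fewer than 3 complete cases")
    data <- dsRows(data, keep)
  }
  p <- ncol(data$values)
  n <- nrow(data$values)
  labels <- data$labels
  ordc <- data$level == "ordinal"
  if (method == "pearson" || !any(ordc)) {
    R <- stats::cor(data$values, use = "pairwise.complete.obs")
    usedMethod <- "pearson"
  } else if (all(ordc)) {
    res <- .cppPolychoricMatrix(data$codes, correction, rhoMax)
    if (length(res$fail_i))
      stop("polychoric estimation failed to converge for pair(s): ",
           paste(labels[res$fail_i], labels[res$fail_j],
                 sep = "--", collapse = ", "))
    R <- res$rho
    usedMethod <- "polychoric"
  } else {
    R <- diag(p)
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        if (ordc[i] && ordc[j]) {
          r <- .cppPolychoricPair(data$codes[, i], data$codes[, j],
                                  correction, rhoMax)
          if (isTRUE(r$degenerate) || !isTRUE(r$converged))
            stop("polychoric estimation failed for pair ",
                 labels[i], "--", labels[j])
          R[i, j] <- R[j, i] <- r$rho
        } else if (!ordc[i] && !ordc[j]) {
          R[i, j] <- R[j, i] <- stats::cor(data$values[, i], data$values[, j],
                                           use = "pairwise.complete.obs")
        } else {
          xo <- if (ordc[i]) j else i
          yo <- if (ordc[i]) i else j
          R[i, j] <- R[j, i] <- polyserialPair(data$values[, xo],
                                               data$values[, yo], rhoMax)
        }
      }
    }
    usedMethod <- "mixed"
  }
  dimnames(R) <- list(labels, labels)
  R <- nearestPD(R, pdFloor)
  thresholds <- if (computeThresholds) lapply(seq_len(p), function(j) {
    if (ordc[j] && usedMethod != "pearson")
      estimateThresholds(data$values[, j]) else NULL
  }) else vector("list", p)
  names(thresholds) <- labels
  structure(list(matrix = R, thresholds = thresholds, n = n,
                 method = usedMethod, labels = labels),
            class = "correlationEstimate")
}

#' @export
print.correlationEstimate <- function(x, ...) {
  cat("correlationEstimate (", x$method, "), ", length(x$labels),
      " variables, n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Write a correlation matrix to CSV
#'
#' @param est A `correlationEstimate` (or plain matrix).
#' @param path Output file path.
#' @export
writeCorrelations <- function(est, path) {
  m <- if (inherits(est, "correlationEstimate")) est$matrix else est
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Read a correlation matrix from CSV
#'
#' @param path File written by [writeCorrelations()].
#' @param n Sample size to attach (required for model selection downstream).
#' @return A `correlationEstimate` with method `"imported"`.
#' @export
readCorrelations <- function(path, n = NA_integer_) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  structure(list(matrix = (m + t(m)) / 2,
                 thresholds = setNames(vector("list", ncol(m)), colnames(m)),
                 n = n, method = "imported", labels = colnames(m)),
            class = "correlationEstimate")
}
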