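# Independent brute-force oracles and small fixture builders.

# all simple paths from s to t (node index vectors)
allSimplePaths <- function(W, s, t) {
  p <- nrow(W)
  out <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == t) {
      out[[length(out) + 1]] <<- path
      return()
    }
    for (v in seq_len(p)) {
      if (W[u, v] != 0 && !(v %in% path)) walk(c(path, v))
    }
  }
  walk(s)
  out
}

pathLength <- function(W, path) {
  if (length(path) < 2) return(0)
  sum(1 / abs(W[cbind(path[-length(path)], path[-1])]))
}

# distances by exhaustive path enumeration (p <= 6)
bruteDistances <- function(W) {
  p <- nrow(W)
  D <- matrix(Inf, p, p)
  diag(D) <- 0
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      paths <- allSimplePaths(W, s, t)
      if (length(paths))
        D[s, t] <- D[t, s] <- min(vapply(paths, pathLength, 0, W = W))
    }
  }
  D
}

# betweenness by exhaustive enumeration: fractional credit over tied
# shortest paths, endpoints excluded, each unordered pair counted once
bruteBetweenness <- function(W, tol = 1e-9) {
  p <- nrow(W)
  btw <- numeric(p)
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      paths <- allSimplePaths(W, s, t)
      if (!length(paths)) next
      lens <- vapply(paths, pathLength, 0, W = W)
      sp <- paths[lens <= min(lens) + tol]
      for (pa in sp) {
        inner <- pa[-c(1, length(pa))]
        btw[inner] <- btw[inner] + 1 / length(sp)
      }
    }
  }
  btw
}

# random sparse weighted network (possibly disconnected)
randomNetwork <- function(p, density = 0.5, wRange = c(0.1, 0.6),
                          signs = TRUE) {
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (stats::runif(1) < density) {
        w <- stats::runif(1, wRange[1], wRange[2])
        if (signs && stats::runif(1) < 0.5) w <- -w
        W[i, j] <- W[j, i] <- w
      }
    }
  }
  dimnames(W) <- list(paste0("V", 1:p), paste0("V", 1:p))
  W
}

ringWeights <- function(p, w = 0.25) {
  W <- matrix(0, p, p, dimnames = list(paste0("V", 1:p), paste0("V", 1:p)))
  for (i in seq_len(p)) {
    j <- i %% p + 1
    W[i, j] <- W[j, i] <- w
  }
  W
}

# small ordinal dataset with strong enough edges for EBIC selection to
# keep them at modest n
smallOrdinalData <- function(n = 200, seed = 42) {
  set.seed(seed)
  net <- chainNetwork(4, 0.4, 0, closed = FALSE)
  simulateDataset(net, n, levels = 4)
}

# estimator stub returning a fixed network regardless of the data
constantEstimator <- function(W) {
  force(W)
  function(data, ...) networkModel(W)
}
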