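#' Shortest-path distances on a weighted network
#'
#' Present edges get length `1 / |w_ij|` (stronger edges are shorter);
#' absent edges have no direct connection. Entries are all-pairs
#' shortest-path distances, `Inf` for unreachable pairs, 0 on the
#' diagonal. The absolute-value convention makes distances invariant to
#' edge signs, so ring networks with constant `|w|` have fully symmetric
#' distance structure.
#'
#' @param network A `networkModel` or weight matrix.
#' @return p x p distance matrix.
#' @export
shortestPathDistances <- function(network) {
  W <- if (inherits(network, "networkModel")) network$weights else network
  D <- .cppDistances(W)
  dimnames(D) <- dimnames(W)
  D
}

#' Centrality indices of a weighted network
#'
#' Computes the three standard weighted-graph centrality indices per node:
#' *strength* (sum of absolute edge weights), *closeness* (inverse of the
#' summed shortest-path distance to all other nodes; 0 when any node is
#' unreachable) and *betweenness* (number of node pairs whose shortest
#' path passes through the node, with fractional credit for tied shortest
#' paths and endpoints excluded). Each index is also z-standardized across
#' nodes (population SD; a zero-SD index yields z = 0).
#'
#' @param network A `networkModel` or weight matrix (p >= 2 nodes).
#' @return A data frame of class `centralityTable` with columns `node`,
#'   `strength`, `closeness`, `betweenness` and their `z_` versions.
#' @export
centralityTable <- function(network) {
  W <- if (inherits(network, "networkModel")) network$weights else network
  if (nrow(W) < 2L) stop("centrality requires at least 2 nodes")
  labels <- rownames(W)
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(W)))
  ct <- .cppCentrality(W)
  zscore <- function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s > 0) (x - mean(x)) / s else rep(0, length(x))
  }
  out <- data.frame(node = labels,
                    strength = ct$strength,
                    closeness = ct$closeness,
                    betweenness = ct$betweenness,
                    z_strength = zscore(ct$strength),
                    z_closeness = zscore(ct$closeness),
                    z_betweenness = zscore(ct$betweenness),
                    stringsAsFactors = FALSE)
  class(out) <- c("centralityTable", "data.frame")
  out
}

# fast internal path: 3 x p matrix of raw centralities
centralityMatrix <- function(W) {
  ct <- .cppCentrality(W)
  rbind(strength = ct$strength, closeness = ct$closeness,
        betweenness = ct$betweenness)
}

#' Write a centrality table to CSV
#'
#' @param table A `centralityTable`.
#' @param path Output file path.
#' @export
writeCentrality <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
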