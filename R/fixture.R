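#' Synthetic PTSD-like demo dataset
#'
#' Generates a synthetic 17-variable ordinal dataset (4 categories per
#' item, scored 0-3) that mimics the qualitative features of a
#' trauma-symptom questionnaire: a positive-manifold latent partial
#' correlation structure built as a ring with random shortcut edges,
#' plus three deliberately strong item pairs that dominate the network.
#' The generator makes no claim of numeric equivalence to any real
#' clinical dataset; it exists so the full workflow (estimate ->
#' bootstrap -> case-drop -> CS -> difference tests) can be demonstrated
#' and tested without gated data.
#'
#' @param n Number of cases (default 359).
#' @param seed Integer seed.
#' @param nShortcuts Number of random shortcut edges added to the ring.
#' @return An [ordinalDataset()] with variables `S1 .. S17`.
#' @export
ptsdFixture <- function(n = 359, seed = 1, nShortcuts = 16) {
  set.seed(seed)
  p <- 17
  labels <- paste0("S", seq_len(p))
  W <- matrix(0, p, p, dimnames = list(labels, labels))
  for (i in seq_len(p)) {
    j <- i %% p + 1
    W[i, j] <- W[j, i] <- 0.2
  }
  # three dominant symptom pairs
  strong <- rbind(c(16, 17), c(3, 4), c(5, 11))
  for (r in seq_len(nrow(strong)))
    W[strong[r, 1], strong[r, 2]] <- W[strong[r, 2], strong[r, 1]] <- 0.35
  added <- 0L
  while (added < nShortcuts) {
    ij <- sort(sample.int(p, 2))
    if (W[ij[1], ij[2]] == 0 && abs(ij[1] - ij[2]) > 1) {
      W[ij[1], ij[2]] <- W[ij[2], ij[1]] <- stats::runif(1, 0.08, 0.18)
      added <- added + 1L
    }
  }
  K <- -W
  diag(K) <- 1
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 0.05) W <- W * 0.9  # keep comfortably Gaussian-representable
  net <- networkModel(W, labels = labels,
                      meta = list(method = "synthetic-fixture"))
  dat <- simulateDataset(net, n, levels = 4)
  # relabel categories as 0..3 scores (they already are 0-based)
  dat$labels <- labels
  colnames(dat$values) <- labels
  dat
}
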