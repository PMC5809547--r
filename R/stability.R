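#' Case-dropping (m-out-of-n) subset bootstrap
#'
#' Re-estimates the network on random subsets of the data, per drop level:
#' with drop proportion `l`, each replicate keeps `ceiling((1 - l) * n)`
#' randomly chosen rows (without replacement), re-runs the estimator and
#' correlates the subset centrality indices with those of the full-sample
#' network. Decreasing correlations under increasing drop proportions
#' indicate that the order of centralities is unstable. The total
#' `nBoots` replicates are divided evenly over the drop levels.
#'
#' With `dropNodes = TRUE` columns (nodes) are dropped instead of rows
#' through the identical code path; correlations then compare the subset
#' centralities with the original centralities of the retained nodes.
#' Node-dropping is harder to interpret (dropping half the nodes yields an
#' entirely different network) and is provided as a minor option only.
#'
#' Replicates whose subset centralities have zero variance (e.g. a
#' constant estimated network) have an undefined correlation; these are
#' conservatively recorded as 0, so degenerate estimates count against
#' stability rather than hiding it. Estimator failures are redrawn with
#' fresh subsets.
#'
#' @param data An [ordinalDataset()] (or coercible).
#' @param estimator Function mapping a dataset to a `networkModel`.
#' @param levels Drop proportions in `[0, 1)`; every level must leave at
#'   least `p + 1` cases. The default spans 0.1 to 0.75 in 10 steps.
#' @param nBoots Total number of subset replicates over all levels.
#' @param seed Optional integer seed.
#' @param corMethod Correlation between original and subset centrality
#'   vectors: product-moment (`"pearson"`, default) or `"spearman"`.
#' @param dropNodes Drop columns (nodes) instead of rows (cases).
#' @param maxFailRatio Abort threshold for the fraction of failed
#'   replicates.
#' @param ... Passed on to `estimator`.
#' @return An object of class `caseDropResult`: replicate records (drop
#'   level, replicate, index, correlation), the original centralities, and
#'   bookkeeping fields.
#' @export
caseDropBoot <- function(data, estimator = estimateGGM,
                         levels = seq(0.1, 0.75, length.out = 10),
                         nBoots = 1000, seed = NULL,
                         corMethod = c("pearson", "spearman"),
                         dropNodes = FALSE, maxFailRatio = 0.1, ...) {
  corMethod <- match.arg(corMethod)
  data <- asDataset(data)
  levels <- sort(unique(as.numeric(levels)))
  if (any(levels < 0 | levels >= 1))
    stop("drop levels must lie in [0, 1)")
  n <- nrow(data$values)
  p <- ncol(data$values)
  if (!dropNodes) {
    kept <- ceiling((1 - levels) * n)
    if (any(kept < p + 1))
      stop("drop level(s) ", paste(levels[kept < p + 1], collapse = ", "),
           " leave fewer than p + 1 = ", p + 1, " cases")
  } else if (any(ceiling((1 - levels) * p) < 3))
    stop("node-dropping level(s) leave fewer than 3 nodes")
  sampleNetwork <- estimator(data, ...)
  orig <- centralityMatrix(sampleNetwork$weights)
  colnames(orig) <- sampleNetwork$labels
  indices <- rownames(orig)
  nPer <- max(1L, floor(nBoots / length(levels)))
  if (!is.null(seed)) set.seed(seed)
  failures <- 0L
  maxFails <- ceiling(maxFailRatio * nPer * length(levels))
  recs <- vector("list", length(levels) * nPer)
  k <- 0L
  for (lv in levels) {
    m <- if (dropNodes) ceiling((1 - lv) * p) else ceiling((1 - lv) * n)
    for (b in seq_len(nPer)) {
      repeat {
        sub <- if (dropNodes) {
          idx <- sort(sample.int(p, m, replace = FALSE))
          dsCols(data, idx)
        } else {
          idx <- sample.int(n, m, replace = FALSE)
          dsRows(data, idx)
        }
        nt <- tryCatch(estimator(sub, ...), error = function(e) e)
        if (!inherits(nt, "error")) break
        failures <- failures + 1L
        if (failures > maxFails)
          stop("more than ", round(100 * maxFailRatio),
               "% of case-dropping replicates failed; last error: ",
               conditionMessage(nt))
      }
      cm <- centralityMatrix(nt$weights)
      ref <- if (dropNodes) orig[, idx, drop = FALSE] else orig
      cr <- vapply(seq_along(indices), function(r) {
        a <- ref[r, ]
        bb <- cm[r, ]
        if (stats::sd(a) == 0 || stats::sd(bb) == 0) return(NA_real_)
        stats::cor(a, bb, method = corMethod)
      }, numeric(1))
      k <- k + 1L
      recs[[k]] <- data.frame(level = lv, rep = b, index = indices,
                              cor = ifelse(is.na(cr), 0, cr),
                              undefined = is.na(cr),
                              stringsAsFactors = FALSE)
    }
  }
  structure(list(levels = levels, nPer = nPer,
                 records = do.call(rbind, recs[seq_len(k)]),
                 original = sampleNetwork, seed = seed,
                 corMethod = corMethod, dropNodes = dropNodes,
                 failures = failures),
            class = "caseDropResult")
}

#' @export
print.caseDropResult <- function(x, ...) {
  cat("caseDropResult: ", length(x$levels), " drop levels x ", x$nPer,
      " replicates (", if (x$dropNodes) "node" else "case",
      "-dropping)\n", sep = "")
  invisible(x)
}

#' Per-level stability summary
#'
#' Mean correlation, 2.5/97.5 centiles and the proportion of replicates
#' reaching the correlation threshold, per drop level and centrality
#' index.
#'
#' @param object A `caseDropResult`.
#' @param corThreshold Correlation threshold used for the qualifying
#'   proportion.
#' @param ... Unused.
#' @return Data frame (level, index, meanCor, q2.5, q97.5, propAbove).
#' @export
summary.caseDropResult <- function(object, corThreshold = 0.7, ...) {
  r <- object$records
  out <- do.call(rbind, lapply(split(r, list(r$level, r$index)), function(g) {
    data.frame(level = g$level[1], index = g$index[1],
               meanCor = mean(g$cor),
               q2.5 = stats::quantile(g$cor, 0.025, names = FALSE),
               q97.5 = stats::quantile(g$cor, 0.975, names = FALSE),
               propAbove = mean(g$cor >= corThreshold),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$index, out$level), ]
  rownames(out) <- NULL
  out
}

#' Correlation-stability (CS) coefficient
#'
#' The CS coefficient is the maximum proportion of cases that can be
#' dropped such that, with probability `certainty` (default 95%), the
#' correlation between the original centralities and the subset
#' centralities is at least `corThreshold` (default 0.7). Per index it is
#' the largest tested drop level whose empirical qualifying proportion
#' reaches `certainty`, or 0 when no level qualifies. Values are only as
#' fine-grained as the tested drop grid.
#'
#' Simulation evidence suggests the CS coefficient should not be below
#' 0.25, and preferably above 0.5, before centrality differences are
#' interpreted; these cutoffs are indicative bands, not hard rules, and
#' are attached to the result for printing.
#'
#' When the qualifying proportion is non-monotone over levels (possible
#' with Monte-Carlo noise), the largest qualifying level is still used,
#' with a warning naming the smaller levels that failed.
#'
#' @param result A `caseDropResult`.
#' @param corThreshold Correlation threshold (default 0.7).
#' @param certainty Required probability (default 0.95).
#' @return An object of class `csCoefficient`: data frame (index, cs) with
#'   the thresholds and interpretation bands as attributes.
#' @export
csCoefficient <- function(result, corThreshold = 0.7, certainty = 0.95) {
  r <- result$records
  if (result$nPer < 20)
    warning("fewer than 20 replicates per drop level; the CS coefficient ",
            "will be noisy", call. = FALSE)
  indices <- unique(r$index)
  cs <- vapply(indices, function(ix) {
    g <- r[r$index == ix, ]
    prop <- vapply(result$levels, function(lv)
      mean(g$cor[g$level == lv] >= corThreshold), numeric(1))
    ok <- which(prop >= certainty)
    if (!length(ok)) return(0)
    top <- max(ok)
    if (any(prop[seq_len(top)] < certainty))
      warning("index '", ix, "': qualifying proportion is non-monotone ",
              "across drop levels (levels ",
              paste(result$levels[setdiff(seq_len(top), ok)],
                    collapse = ", "), " fail)", call. = FALSE)
    result$levels[top]
  }, numeric(1))
  out <- data.frame(index = indices, cs = cs, stringsAsFactors = FALSE)
  structure(out, class = c("csCoefficient", "data.frame"),
            corThreshold = corThreshold, certainty = certainty,
            bands = c(minimum = 0.25, preferred = 0.5))
}

#' @export
print.csCoefficient <- function(x, ...) {
  cat(sprintf("CS(cor = %g, certainty = %g):\n", attr(x, "corThreshold"),
              attr(x, "certainty")))
  for (r in seq_len(nrow(x))) {
    band <- if (x$cs[r] >= 0.5) "stable"
      else if (x$cs[r] >= 0.25) "interpret with care"
      else "unstable"
    cat(sprintf("  %-12s %.3g  (%s)\n", x$index[r], x$cs[r], band))
  }
  cat("  bands: below 0.25 unstable, above 0.5 preferred (indicative only)\n")
  invisible(x)
}

#' Write the per-level stability summary to CSV
#'
#' @param result A `caseDropResult`.
#' @param path Output file path.
#' @param corThreshold Threshold for the qualifying proportion column.
#' @export
writeStabilitySummary <- function(result, path, corThreshold = 0.7) {
  utils::write.csv(summary(result, corThreshold = corThreshold), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a CS-coefficient summary as JSON
#'
#' @param cs A `csCoefficient`.
#' @param path Output file path.
#' @export
writeCS <- function(cs, path) {
  jsonlite::write_json(list(corThreshold = attr(cs, "corThreshold"),
                            certainty = attr(cs, "certainty"),
                            cs = as.list(stats::setNames(cs$cs, cs$index))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
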