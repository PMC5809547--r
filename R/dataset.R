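#' Construct an ordinal/continuous dataset
#'
#' Wraps a rectangular table of scores (rows = cases, columns = variables)
#' together with a declared measurement level per column. Ordinal columns
#' are integer-coded internally so that downstream polychoric estimation and
#' bootstrap resampling avoid repeated factor conversions.
#'
#' A column is auto-detected as ordinal when it is integer-valued with at
#' most `maxOrdinalLevels` distinct observed values; the rule can be
#' overridden per column through `level`.
#'
#' @param x A numeric matrix or data frame (rows = cases, columns =
#'   variables). Missing values may be coded `NA`.
#' @param level Optional character vector (`"ordinal"` / `"continuous"`),
#'   either length one (recycled) or one entry per column. `NULL`
#'   auto-detects.
#' @param labels Optional variable names; defaults to column names or
#'   `V1..Vp`.
#' @param maxOrdinalLevels Maximum number of distinct integer values for a
#'   column to be auto-detected as ordinal.
#' @return An object of class `ordinalDataset` with elements `values`,
#'   `labels`, `level` and (internal) `codes`.
#' @export
ordinalDataset <- function(x, level = NULL, labels = NULL,
                           maxOrdinalLevels = 10) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix or data frame")
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) stop("need at least 2 cases (rows)")
  if (p < 2L) stop("need at least 2 variables (columns)")
  if (is.null(labels)) labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  if (length(labels) != p) stop("'labels' must have one entry per column")
  if (is.null(level)) {
    level <- vapply(seq_len(p), function(j) {
      v <- x[, j]
      v <- v[is.finite(v)]
      u <- unique(v)
      if (length(u) <= maxOrdinalLevels && all(u == round(u)))
        "ordinal" else "continuous"
    }, character(1))
  } else {
    level <- as.character(level)
    if (length(level) == 1L) level <- rep(level, p)
    if (length(level) != p)
      stop("'level' must have length 1 or one entry per column")
    opts <- c("ordinal", "continuous")
    level <- opts[pmatch(level, opts, duplicates.ok = TRUE)]
    if (anyNA(level))
      stop("'level' entries must be \"ordinal\" or \"continuous\"")
  }
  for (j in seq_len(p)) {
    v <- x[, j][!is.na(x[, j])]
    if (length(unique(v)) < 2L)
      stop("degenerate variable: column '", labels[j], "' is constant")
  }
  codes <- matrix(NA_integer_, n, p)
  for (j in seq_len(p)) {
    if (level[j] == "ordinal") {
      u <- sort(unique(x[, j][!is.na(x[, j])]))
      codes[, j] <- match(x[, j], u) - 1L
    }
  }
  structure(list(values = x, labels = labels, level = level, codes = codes),
            class = "ordinalDataset")
}

#' @export
print.ordinalDataset <- function(x, ...) {
  cat("ordinalDataset:", nrow(x$values), "cases x", ncol(x$values),
      "variables\n")
  cat("  ordinal:", sum(x$level == "ordinal"),
      " continuous:", sum(x$level == "continuous"), "\n")
  cat("  variables:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.ordinalDataset <- function(x) dim(x$values)

# row subset without revalidation (bootstrap hot path)
dsRows <- function(data, idx) {
  structure(list(values = data$values[idx, , drop = FALSE],
                 labels = data$labels, level = data$level,
                 codes = data$codes[idx, , drop = FALSE]),
            class = "ordinalDataset")
}

# column subset (node-dropping bootstrap)
dsCols <- function(data, idx) {
  structure(list(values = data$values[, idx, drop = FALSE],
                 labels = data$labels[idx], level = data$level[idx],
                 codes = data$codes[, idx, drop = FALSE]),
            class = "ordinalDataset")
}

asDataset <- function(x, ...) {
  if (inherits(x, "ordinalDataset")) x else ordinalDataset(x, ...)
}

#' Read a dataset from a delimited text file
#'
#' Reads a CSV or TSV file with a header row of variable names. Empty cells
#' and the string `"NA"` are treated as missing.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` picks `\t` for `.tsv` files and `,`
#'   otherwise.
#' @inheritParams ordinalDataset
#' @return An [ordinalDataset()].
#' @export
readDataset <- function(path, sep = NULL, level = NULL,
                        maxOrdinalLevels = 10) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), check.names = FALSE)
  ordinalDataset(df, level = level, maxOrdinalLevels = maxOrdinalLevels)
}

#' Write a dataset to CSV
#'
#' @param data An [ordinalDataset()].
#' @param path Output file path.
#' @export
writeDataset <- function(data, path) {
  data <- asDataset(data)
  df <- as.data.frame(data$values)
  names(df) <- data$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
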