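#' Standardize ecosystem functions to a common 0-1 scale
#'
#' Functions flagged with sign -1 (e.g. the relative abundance of fungal
#' plant pathogens, where *less* is better) are multiplied by -1 first, then
#' every function is min-max standardized across samples, so each column
#' spans exactly \[0, 1\].
#'
#' @param ft a [function_table()].
#' @return Numeric matrix, samples x functions, all entries in \[0, 1\].
#' @export
standardize_functions <- function(ft) {
  stopifnot(inherits(ft, "function_table"))
  vals <- sweep(ft$values, 2, ft$sign, "*")
  out <- vals
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    if (max(x) == min(x)) {
      stop("function '", colnames(vals)[j],
           "' is constant across samples and cannot be standardized")
    }
    out[, j] <- (x - min(x)) / (max(x) - min(x))
  }
  out
}

#' Averaging multifunctionality index
#'
#' The per-sample arithmetic mean of the standardized functions.
#'
#' @param std standardized function matrix from [standardize_functions()].
#' @return Numeric vector in \[0, 1\], one value per sample.
#' @export
averaging_index <- function(std) {
  stopifnot(is.matrix(std))
  rowMeans(std)
}

#' Service-weighted multifunctionality index
#'
#' Functions are first averaged within each ecosystem-service group, and the
#' four group means are then averaged, so each service contributes equally to
#' the index regardless of how many functions represent it. When all groups
#' have equal size this coincides exactly with [averaging_index()].
#'
#' @param std standardized function matrix.
#' @param groups named character vector mapping each function (column) to a
#'   service group; every group must be non-empty.
#' @return Numeric vector in \[0, 1\].
#' @export
weighted_index <- function(std, groups) {
  stopifnot(is.matrix(std))
  miss <- setdiff(colnames(std), names(groups))
  if (length(miss)) stop("functions without a service group: ", paste(miss, collapse = ", "))
  groups <- groups[colnames(std)]
  gs <- unique(groups)
  gm <- vapply(gs, function(g) {
    rowMeans(std[, groups == g, drop = FALSE])
  }, numeric(nrow(std)))
  rowMeans(gm)
}

#' Principal-coordinate multifunctionality index
#'
#' Classical scaling (principal coordinate analysis) of the Euclidean
#' distance matrix of the standardized functions. Axis 1 scores are the
#' index; because ordination sign is arbitrary, the axis is flipped if
#' needed so that it correlates non-negatively with the averaging index.
#' Further axes and the eigenvalues are returned for inspection.
#'
#' @param std standardized function matrix, >= 3 samples.
#' @param k number of axes to keep (default 2).
#' @return List with `scores` (axis-1 vector), `axes` (samples x k matrix),
#'   `eigenvalues`, `prop_explained`.
#' @export
multidimensional_index <- function(std, k = 2) {
  stopifnot(is.matrix(std))
  if (nrow(std) < 3) stop("need at least 3 samples for a principal-coordinate index")
  d <- stats::dist(std)
  if (all(d == 0)) stop("all samples have identical function profiles; ordination is degenerate")
  fit <- stats::cmdscale(d, k = min(k, nrow(std) - 1), eig = TRUE)
  ax1 <- fit$points[, 1]
  avg <- averaging_index(std)
  if (stats::cor(ax1, avg) < 0) {
    ax1 <- -ax1
    fit$points[, 1] <- ax1
  }
  pos <- fit$eig[fit$eig > 0]
  list(scores = ax1, axes = fit$points, eigenvalues = fit$eig,
       prop_explained = if (length(pos)) pos / sum(pos) else numeric(0))
}

#' All multifunctionality indices for a function table
#'
#' @param ft a [function_table()].
#' @return Object of class `multifunctionality_result`: `sample_ids`,
#'   `standardized_functions`, `averaging`, `weighted`, `multidimensional`
#'   (axis-1 scores), `eigenvalues`.
#' @export
multifunctionality <- function(ft) {
  std <- standardize_functions(ft)
  mdi <- multidimensional_index(std)
  structure(list(sample_ids = rownames(std),
                 standardized_functions = std,
                 averaging = averaging_index(std),
                 weighted = weighted_index(std, ft$service_group),
                 multidimensional = mdi$scores,
                 eigenvalues = mdi$eigenvalues),
            class = "multifunctionality_result")
}
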