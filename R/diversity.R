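#' Per-sample richness
#'
#' Richness is the number of phylotypes observed (count > 0) in a sample.
#' All-zero columns contribute nothing, so tables that retain empty columns
#' (e.g. after rarefaction or class subsetting) give the intended values.
#'
#' @param table a [community_table()].
#' @return Named integer vector, one value per sample.
#' @export
richness <- function(table) {
  stopifnot(inherits(table, "community_table"))
  rowSums(table$counts > 0)
}

#' Min-max standardization to \[0, 1\]
#'
#' STD = (X - Xmin) / (Xmax - Xmin) across samples, so the smallest value
#' maps to 0 and the largest to 1.
#'
#' @param x numeric vector, length >= 2, not constant.
#' @return Object of class `std_vector` with fields `X`, `X_min`, `X_max`,
#'   `STD`.
#' @export
minmax_standardize <- function(x) {
  if (length(x) < 2) stop("need at least two values to standardize")
  if (anyNA(x) || any(!is.finite(x))) stop("cannot standardize non-finite values")
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    stop("cannot min-max standardize a constant vector (X_max == X_min); ",
         "the variable carries no contrast across samples")
  }
  structure(list(X = x, X_min = lo, X_max = hi, STD = (x - lo) / (hi - lo)),
            class = "std_vector")
}

#' Multidiversity: mean standardized richness across organism groups
#'
#' Each group's (sub)community richness is min-max standardized across
#' samples, then the per-sample mean over groups is taken. Standardization is
#' done within each group x subcommunity combination, so rare richness is
#' scaled against the rare richness range only.
#'
#' @param per_group_richness list of per-sample richness vectors (one per
#'   organism group, equal lengths, typically four).
#' @return Numeric vector in \[0, 1\], one value per sample.
#' @export
multidiversity <- function(per_group_richness) {
  stopifnot(is.list(per_group_richness), length(per_group_richness) >= 1)
  n <- unique(vapply(per_group_richness, length, integer(1)))
  if (length(n) != 1) stop("richness vectors have mismatched lengths")
  std <- vapply(per_group_richness, function(r) minmax_standardize(r)$STD,
                numeric(n))
  rowMeans(std)
}

#' Richness and multidiversity per subcommunity
#'
#' Convenience wrapper building the full diversity table: per-group,
#' per-subcommunity richness, its standardized version, and the
#' multidiversity index for each requested class label (plus `"all"` for the
#' whole community).
#'
#' @param tables named list of [community_table()]s (one per organism group),
#'   samples aligned.
#' @param classes named list of matching [abundance_classes()].
#' @param labels class labels to evaluate; `"all"` means the whole table.
#' @return List with `richness` (samples x group.label matrix),
#'   `multidiversity` (samples x label matrix), `sample_ids`.
#' @export
diversity_table <- function(tables, classes,
                            labels = c("rare", "abundant", "all")) {
  stopifnot(length(tables) >= 1, identical(names(tables), names(classes)))
  ids <- sample_ids(tables[[1]])
  rich <- list()
  md <- matrix(NA_real_, length(ids), length(labels),
               dimnames = list(ids, labels))
  for (lab in labels) {
    per_group <- lapply(names(tables), function(g) {
      tb <- if (lab == "all") tables[[g]] else
        suppressWarnings(subset_community(tables[[g]], classes[[g]], lab))
      richness(tb)
    })
    names(per_group) <- names(tables)
    for (g in names(tables)) rich[[paste(g, lab, sep = ".")]] <- per_group[[g]]
    md[, lab] <- multidiversity(per_group)
  }
  list(sample_ids = ids,
       richness = do.call(cbind, rich),
       multidiversity = md)
}
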