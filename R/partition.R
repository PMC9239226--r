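#' Abundance threshold scheme
#'
#' Phylotypes are classified on their dataset-level relative abundance within
#' an organism group: above `abundant_min` they are "abundant", below
#' `rare_max` "rare", otherwise "intermediate". Inequalities are strict, so a
#' phylotype sitting exactly on a threshold is intermediate.
#'
#' @param abundant_min fraction above which a phylotype is abundant
#'   (default 0.005, i.e. 0.5%).
#' @param rare_max fraction below which a phylotype is rare
#'   (default 0.0005, i.e. 0.05%).
#' @param name scheme label.
#' @return An object of class `threshold_scheme`.
#' @export
threshold_scheme <- function(abundant_min = 0.005, rare_max = 0.0005,
                             name = "default") {
  if (!(rare_max > 0 && rare_max < abundant_min && abundant_min < 1)) {
    stop("need 0 < rare_max < abundant_min < 1")
  }
  structure(list(abundant_min = abundant_min, rare_max = rare_max, name = name),
            class = "threshold_scheme")
}

#' The three standard threshold schemes
#'
#' The primary definition (abundant > 0.5%, rare < 0.05%) plus the two
#' sensitivity definitions (1%/0.1% and 0.1%/0.01%) used to check robustness
#' of the partition.
#'
#' @return List of three [threshold_scheme()]s.
#' @export
alternative_schemes <- function() {
  list(threshold_scheme(0.005, 0.0005, "0.5%/0.05%"),
       threshold_scheme(0.01, 0.001, "1%/0.1%"),
       threshold_scheme(0.001, 0.0001, "0.1%/0.01%"))
}

#' Classify phylotypes into abundant / intermediate / rare
#'
#' Classification is computed once on the dataset-level relative abundance of
#' each phylotype within its organism group (phylotype total / group grand
#' total) and is then fixed: per-sample quantities for the classes are derived
#' from this single labeling, not re-computed per sample.
#'
#' @param table a [community_table()].
#' @param scheme a [threshold_scheme()].
#' @return An object of class `abundance_classes` with `phylotype_ids`,
#'   `dataset_relabund`, `label` (factor abundant/intermediate/rare),
#'   `scheme`, `group`.
#' @export
classify_phylotypes <- function(table, scheme = threshold_scheme()) {
  stopifnot(inherits(table, "community_table"), inherits(scheme, "threshold_scheme"))
  rel <- relative_abundance(table, "dataset")
  label <- ifelse(rel > scheme$abundant_min, "abundant",
                  ifelse(rel < scheme$rare_max, "rare", "intermediate"))
  structure(list(phylotype_ids = names(rel),
                 dataset_relabund = rel,
                 label = factor(label, levels = c("abundant", "intermediate", "rare")),
                 scheme = scheme,
                 group = table$group),
            class = "abundance_classes")
}

#' @export
print.abundance_classes <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("<abundance_classes> %s (%s): %d abundant, %d intermediate, %d rare\n",
              x$group, x$scheme$name, tab[["abundant"]], tab[["intermediate"]],
              tab[["rare"]]))
  invisible(x)
}

#' Subset a community table to one abundance class
#'
#' @param table the [community_table()] the classes were derived from.
#' @param classes an [abundance_classes()].
#' @param label `"abundant"`, `"intermediate"` or `"rare"`.
#' @return A `community_table` holding only the requested columns, counts
#'   unchanged (all-zero columns retained). A warning is issued if the class
#'   is empty.
#' @export
subset_community <- function(table, classes, label) {
  stopifnot(inherits(table, "community_table"), inherits(classes, "abundance_classes"))
  if (!label %in% levels(classes$label)) stop("unknown class label: ", label)
  if (!identical(phylotype_ids(table), classes$phylotype_ids)) {
    stop("classes were not derived from this table (phylotype ids differ)")
  }
  keep <- classes$label == label
  if (!any(keep)) {
    warning("no '", label, "' phylotypes in the ", table$group,
            " table under scheme ", classes$scheme$name)
  }
  out <- table
  out$counts <- table$counts[, keep, drop = FALSE]
  out
}

#' Export a classification as a TSV data frame
#'
#' @param classes an [abundance_classes()].
#' @param path optional file; when given, written as TSV.
#' @return Data frame (phylotype, group, relabund, label, scheme), invisibly
#'   when written.
#' @export
classification_frame <- function(classes, path = NULL) {
  df <- data.frame(phylotype_id = classes$phylotype_ids,
                   group = classes$group,
                   dataset_relabund = as.numeric(classes$dataset_relabund),
                   label = as.character(classes$label),
                   scheme = classes$scheme$name,
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
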