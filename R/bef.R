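#' Ordinary least-squares biodiversity-function regression
#'
#' Fits `mf ~ diversity` by OLS and reports the raw slope, the standardized
#' slope (fit on z-scored x and y, so for simple regression it equals the
#' Pearson correlation), R-squared and the two-sided slope p-value.
#'
#' @param diversity predictor vector (e.g. multidiversity).
#' @param mf response vector (e.g. a multifunctionality index).
#' @return Object of class `regression_result`: `slope`,
#'   `standardized_slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
bef_regression <- function(diversity, mf) {
  if (length(diversity) != length(mf)) stop("diversity and mf must have equal length")
  ok <- is.finite(diversity) & is.finite(mf)
  x <- diversity[ok]; y <- mf[ok]
  if (length(x) < 3) stop("need at least 3 finite observations")
  if (stats::sd(x) == 0) stop("zero-variance predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  std_slope <- if (stats::sd(y) == 0) 0 else
    unname(stats::coef(fit)[2]) * stats::sd(x) / stats::sd(y)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 standardized_slope = std_slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> slope = %.4g (std %.3f), R2 = %.3f, P = %.3g, n = %d\n",
              x$slope, x$standardized_slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Spearman correlations between group diversities and single functions
#'
#' For every (organism group x subcommunity) diversity vector and every
#' standardized ecosystem function, the Spearman rank correlation and its
#' two-sided p-value are computed; a significance mask flags pairs at
#' p < `alpha`. Constant diversity vectors give undefined (NA) entries that
#' are excluded from the mask.
#'
#' @param div named list of per-sample diversity (richness) vectors.
#' @param functions standardized function matrix (samples x functions).
#' @param alpha significance level for the mask (default 0.05).
#' @return List with matrices `rho`, `p`, and logical `significant`.
#' @export
diversity_function_correlations <- function(div, functions, alpha = 0.05) {
  stopifnot(is.list(div), is.matrix(functions))
  X <- do.call(cbind, div)
  if (nrow(X) != nrow(functions)) stop("samples misaligned")
  sp <- spearman_matrix(X, functions)
  sig <- !is.na(sp$rho) & !is.na(sp$p) & sp$p < alpha
  list(rho = sp$rho, p = sp$p, significant = sig)
}

# internal constructor so summaries can be tested on crafted inputs
new_support_table <- function(phylotypes, rho, p, p_cut = 0.01) {
  supports <- !is.na(rho) & !is.na(p) & rho > 0 & p < p_cut
  structure(list(phylotypes = phylotypes,
                 functions = colnames(rho),
                 rho = rho, p = p, supports = supports,
                 n_functions_supported = rowSums(supports),
                 p_cut = p_cut),
            class = "support_table")
}

#' Screen for supporting phylotypes
#'
#' A phylotype "supports" an ecosystem function when its per-sample relative
#' abundance is positively and significantly (two-sided p < `p_cut`,
#' default 0.01, uncorrected as in the screen this reproduces) Spearman
#' correlated with that function. Phylotypes observed in fewer than
#' `prevalence_min` of samples are excluded beforehand to avoid zero-inflated
#' rank statistics.
#'
#' @param table a [community_table()] for one organism group.
#' @param classes matching [abundance_classes()] (labels are carried along
#'   for rare/abundant aggregation).
#' @param functions standardized function matrix, samples aligned with
#'   `table`.
#' @param p_cut raw p-value threshold (default 0.01).
#' @param prevalence_min minimum occupancy fraction (default 0.1).
#' @return Object of class `support_table`: `phylotypes` (data frame with
#'   id, group, label), `rho`, `p`, logical `supports`,
#'   `n_functions_supported`.
#' @export
supporting_phylotypes <- function(table, classes, functions, p_cut = 0.01,
                                  prevalence_min = 0.1) {
  stopifnot(inherits(table, "community_table"), is.matrix(functions))
  if (nrow(table$counts) != nrow(functions)) stop("samples misaligned")
  prev <- colMeans(table$counts > 0)
  keep <- prev >= prevalence_min
  if (!any(keep)) stop("no phylotype passes the prevalence filter (",
                       prevalence_min, ")")
  message(sprintf("support screen (%s): %d of %d phylotypes pass prevalence >= %g",
                  table$group, sum(keep), length(keep), prevalence_min))
  rel <- relative_abundance(table, "per_sample")[, keep, drop = FALSE]
  sp <- spearman_matrix(rel, functions)
  idx <- match(colnames(rel), classes$phylotype_ids)
  phylotypes <- data.frame(phylotype_id = colnames(rel),
                           group = table$group,
                           label = as.character(classes$label[idx]),
                           stringsAsFactors = FALSE)
  rownames(sp$rho) <- rownames(sp$p) <- colnames(rel)
  new_support_table(phylotypes, sp$rho, sp$p, p_cut)
}

#' Combine support tables from several organism groups
#'
#' @param sts list of [supporting_phylotypes()] results with identical
#'   function sets.
#' @return A single `support_table`.
#' @export
combine_support_tables <- function(sts) {
  stopifnot(length(sts) >= 1)
  fns <- sts[[1]]$functions
  for (st in sts) stopifnot(identical(st$functions, fns))
  new_support_table(do.call(rbind, lapply(sts, `[[`, "phylotypes")),
                    do.call(rbind, lapply(sts, `[[`, "rho")),
                    do.call(rbind, lapply(sts, `[[`, "p")),
                    sts[[1]]$p_cut)
}

#' Summaries of a support screen
#'
#' Aggregates a [supporting_phylotypes()] result the way the headline
#' analyses use it: the abundance-class composition of each function's
#' supporters; the same pooled by ecosystem-service group; the fraction of
#' each subcommunity's members that support at least one function; and, per
#' abundance class, the OLS relationship between each function's support
#' proportion and the mean number of functions its supporters support.
#'
#' @param st a `support_table`.
#' @param service_group optional named map function -> service group enabling
#'   the pooled-by-service summary.
#' @return List with data frames `per_function`, `per_service_group`
#'   (when `service_group` given), `per_class`, and `breadth_regression`
#'   (one [bef_regression()] per abundance class present, or NULL when
#'   degenerate).
#' @export
support_summary <- function(st, service_group = NULL) {
  stopifnot(inherits(st, "support_table"))
  lab <- st$phylotypes$label
  sup <- st$supports
  per_function <- do.call(rbind, lapply(seq_along(st$functions), function(j) {
    s <- sup[, j]
    n_sup <- sum(s)
    data.frame(function_id = st$functions[j],
               n_supporting = n_sup,
               prop_rare = if (n_sup) sum(s & lab == "rare") / n_sup else 0,
               prop_abundant = if (n_sup) sum(s & lab == "abundant") / n_sup else 0,
               empty = n_sup == 0,
               stringsAsFactors = FALSE)
  }))
  per_service_group <- NULL
  if (!is.null(service_group)) {
    sg <- service_group[st$functions]
    per_service_group <- do.call(rbind, lapply(unique(sg), function(g) {
      s <- sup[, sg == g, drop = FALSE]
      tot <- sum(s)
      data.frame(service_group = g,
                 n_support_events = tot,
                 prop_rare = if (tot) sum(s[lab == "rare", , drop = FALSE]) / tot else 0,
                 prop_abundant = if (tot) sum(s[lab == "abundant", , drop = FALSE]) / tot else 0,
                 empty = tot == 0,
                 stringsAsFactors = FALSE)
    }))
  }
  per_class <- do.call(rbind, lapply(c("abundant", "intermediate", "rare"), function(cl) {
    members <- lab == cl
    data.frame(label = cl,
               n_phylotypes = sum(members),
               prop_supporting = if (any(members))
                 mean(st$n_functions_supported[members] >= 1) else 0,
               empty = !any(members),
               stringsAsFactors = FALSE)
  }))
  breadth_regression <- lapply(c("abundant", "rare"), function(cl) {
    members <- lab == cl
    if (!any(members)) return(NULL)
    prop <- colMeans(sup[members, , drop = FALSE])
    meanfun <- vapply(seq_along(st$functions), function(j) {
      s <- sup[, j] & members
      if (!any(s)) return(NA_real_)
      mean(st$n_functions_supported[s])
    }, numeric(1))
    ok <- is.finite(meanfun)
    if (sum(ok) < 3 || stats::sd(prop[ok]) == 0) return(NULL)
    bef_regression(prop[ok], meanfun[ok])
  })
  names(breadth_regression) <- c("abundant", "rare")
  list(per_function = per_function,
       per_service_group = per_service_group,
       per_class = per_class,
       breadth_regression = breadth_regression)
}

#' Compare support breadth between abundant and rare supporters
#'
#' Two-sided Wilcoxon rank-sum test on the number of functions supported,
#' restricted to phylotypes that support at least one function, comparing
#' the abundant against the rare class.
#'
#' @param st a `support_table`.
#' @return List with `mean_abundant`, `mean_rare`, `n_abundant`, `n_rare`,
#'   `statistic` (Wilcoxon W), `p_value`.
#' @export
compare_support_breadth <- function(st) {
  stopifnot(inherits(st, "support_table"))
  supp <- st$n_functions_supported >= 1
  a <- st$n_functions_supported[supp & st$phylotypes$label == "abundant"]
  r <- st$n_functions_supported[supp & st$phylotypes$label == "rare"]
  if (length(a) == 0 || length(r) == 0) {
    stop("need at least one supporting phylotype in each of the abundant and rare classes")
  }
  if (length(unique(c(a, r))) == 1) {
    # all breadths identical: no evidence of any difference
    return(list(mean_abundant = mean(a), mean_rare = mean(r),
                n_abundant = length(a), n_rare = length(r),
                statistic = length(a) * length(r) / 2, p_value = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, r, alternative = "two.sided",
                                            exact = FALSE, correct = TRUE))
  list(mean_abundant = mean(a), mean_rare = mean(r),
       n_abundant = length(a), n_rare = length(r),
       statistic = unname(wt$statistic), p_value = wt$p.value)
}
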